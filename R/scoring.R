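# SFS decomposition: perpendicular distance A to the deterioration axis,
# along-axis coordinate ell, remaining distance B = 100 - ell to the
# maximum-deterioration point, and SFS = 100 - (A + B) = ell - A.

#' Decompose a subject into off-axis and along-axis distances
#'
#' In standardized space with unit vector `u` along the deterioration axis,
#' the subject's coordinates split into the orthogonal projection onto `u`
#' (the along-axis coordinate) and the perpendicular residual. Both are
#' reported in score units (standardized distance times the frame scale).
#'
#' @param porosity cortical porosity (%), vectorized.
#' @param density trabecular density (mg HA/cm^3), vectorized.
#' @param frame a [ref_frame].
#' @return data.frame with columns `A` (perpendicular distance, >= 0), `ell`
#'   (along-axis coordinate, signed) and `side` (+1 above the axis — cortical
#'   deficit dominant — and -1 below; 0 on the axis; diagnostic only).
#' @export
sfs_decompose <- function(porosity, density, frame) {
  z <- standardize(porosity, density, frame)
  u <- axis_unit_vector(frame$slope)
  ell_std <- z$zx * u[1] + z$zy * u[2]
  rx <- z$zx - ell_std * u[1]
  ry <- z$zy - ell_std * u[2]
  # signed perpendicular coordinate along v = (-u_y, u_x), the "above U" side
  perp <- -z$zx * u[2] + z$zy * u[1]
  data.frame(A = frame$scale * sqrt(rx^2 + ry^2),
             ell = frame$scale * ell_std,
             side = sign(perp))
}

#' Compute the structural fragility score
#'
#' `SFS = 100 - (A + B)` with `B = 100 - ell`, so `SFS = ell - A`: the score
#' increases moving along the deterioration axis toward Z (100 at Z, 0 at the
#' premenopausal centroid O) and decreases with distance off the axis. The
#' score is not clamped: negative values indicate structure better than the
#' premenopausal mean or far off-axis, values above 100 indicate
#' deterioration beyond Z.
#'
#' @inheritParams sfs_decompose
#' @return data.frame with columns `A`, `B`, `ell`, `sfs`, `quadrant`, `side`.
#' @export
sfs_score <- function(porosity, density, frame) {
  d <- sfs_decompose(porosity, density, frame)
  d$B <- 100 - d$ell
  d$sfs <- 100 - (d$A + d$B)
  d$quadrant <- sfs_quadrant(porosity, density, frame)
  d[, c("A", "B", "ell", "sfs", "quadrant", "side")]
}

#' Classify the trait quadrant relative to the premenopausal centroid
#'
#' Quadrants relative to O: I = high porosity, high density; II = low
#' porosity, high density; III = low porosity, low density; IV = high
#' porosity, low density (the bone-loss-consistent combination). Exact ties
#' count as "low".
#'
#' @inheritParams sfs_decompose
#' @return character vector with values in `c("I", "II", "III", "IV")`.
#' @export
sfs_quadrant <- function(porosity, density, frame) {
  validate_frame(frame)
  hi_por <- porosity > frame$o_x
  hi_den <- density > frame$o_y
  ifelse(hi_por & hi_den, "I",
         ifelse(!hi_por & hi_den, "II",
                ifelse(!hi_por, "III", "IV")))
}

#' Score every subject in a cohort
#'
#' @param cohort a [cohort_table].
#' @param frame a [ref_frame].
#' @return data.frame keyed by `subject_id` with the [sfs_score()] columns.
#' @export
score_cohort <- function(cohort, frame) {
  stopifnot(is.data.frame(cohort))
  if (nrow(cohort) == 0L) {
    warning("scoring an empty cohort")
    return(data.frame(subject_id = character(), A = numeric(), B = numeric(),
                      ell = numeric(), sfs = numeric(), quadrant = character(),
                      side = numeric(), stringsAsFactors = FALSE))
  }
  res <- sfs_score(cohort$cortical_porosity_pct,
                   cohort$trabecular_density_mghacm3, frame)
  cbind(data.frame(subject_id = cohort$subject_id, stringsAsFactors = FALSE), res)
}
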