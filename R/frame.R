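# Reference geometry: premenopausal centroid O, deterioration axis U,
# maximum-deterioration point Z, and the score scale.
#
# All geometry lives in standardized space: raw coordinates are centered at O
# and divided by the premenopausal SDs, which makes porosity (%) and
# trabecular density (mg HA/cm^3) commensurable and every downstream score
# invariant to unit conventions.

#' Construct a reference frame
#'
#' The frame holds the premenopausal trait centroid `O = (o_x, o_y)` and SDs
#' `(s_x, s_y)`, the slope of the deterioration axis U in standardized space
#' (negative: porosity up, density down), the along-axis coordinate `ell_z`
#' of the maximum-deterioration point Z, and the scale mapping one
#' standardized distance unit to score units (`scale * ell_z = 100`, so a
#' subject at O scores 0 and a subject at Z scores 100).
#'
#' @param o_x,o_y premenopausal mean cortical porosity (%) and trabecular
#'   density (mg HA/cm^3).
#' @param s_x,s_y premenopausal sample SDs of the two traits (> 0).
#' @param slope slope of U in standardized space (< 0).
#' @param ell_z along-axis coordinate of Z in standardized units (> 0).
#' @return an object of class `ref_frame`.
#' @export
ref_frame <- function(o_x, o_y, s_x, s_y, slope, ell_z) {
  frame <- structure(
    list(o_x = o_x, o_y = o_y, s_x = s_x, s_y = s_y,
         slope = slope, ell_z = ell_z, scale = 100 / ell_z),
    class = "ref_frame")
  validate_frame(frame)
}

validate_frame <- function(frame) {
  stopifnot(inherits(frame, "ref_frame"))
  num_ok <- vapply(frame, function(v) is.numeric(v) && length(v) == 1L &&
                     is.finite(v), logical(1))
  if (!all(num_ok)) stop("frame fields must be finite scalars")
  if (frame$s_x <= 0 || frame$s_y <= 0) stop("premenopausal SDs must be > 0")
  if (frame$slope >= 0) stop("deterioration-axis slope must be < 0")
  if (frame$ell_z <= 0) stop("ell_z must be > 0")
  if (abs(frame$scale * frame$ell_z - 100) > 1e-9) {
    stop("scale is inconsistent with ell_z (scale * ell_z must equal 100)")
  }
  frame
}

# Unit vector along U in standardized space.
axis_unit_vector <- function(slope) {
  c(1, slope) / sqrt(1 + slope^2)
}

#' Map raw trait values to standardized coordinates
#'
#' @param porosity cortical porosity (%), vectorized.
#' @param density trabecular density (mg HA/cm^3), vectorized.
#' @param frame a [ref_frame].
#' @return list with numeric vectors `zx`, `zy`.
#' @export
standardize <- function(porosity, density, frame) {
  validate_frame(frame)
  list(zx = (porosity - frame$o_x) / frame$s_x,
       zy = (density - frame$o_y) / frame$s_y)
}

#' Map standardized coordinates back to raw trait units
#'
#' Inverse of [standardize()].
#'
#' @param zx,zy standardized coordinates.
#' @param frame a [ref_frame].
#' @return list with numeric vectors `porosity`, `density`.
#' @export
destandardize <- function(zx, zy, frame) {
  validate_frame(frame)
  list(porosity = zx * frame$s_x + frame$o_x,
       density = zy * frame$s_y + frame$o_y)
}

#' Fit the premenopausal centroid and SDs
#'
#' `O` is the arithmetic mean of each trait in the premenopausal reference
#' sample; the SDs (sample, n-1 denominator) define the standardization.
#'
#' @param premeno a [cohort_table] with cohort label
#'   `premenopausal_reference` and at least 3 subjects.
#' @return list with `o_x`, `o_y`, `s_x`, `s_y`.
#' @export
fit_centroid <- function(premeno) {
  stopifnot(inherits(premeno, "cohort_table"))
  if (!all(premeno$cohort == "premenopausal_reference")) {
    stop("fit_centroid expects a premenopausal_reference cohort")
  }
  if (nrow(premeno) < 3L) stop("need at least 3 premenopausal subjects to estimate SDs")
  s_x <- stats::sd(premeno$cortical_porosity_pct)
  s_y <- stats::sd(premeno$trabecular_density_mghacm3)
  if (s_x == 0 || s_y == 0) stop("zero variance in a reference trait")
  list(o_x = mean(premeno$cortical_porosity_pct),
       o_y = mean(premeno$trabecular_density_mghacm3),
       s_x = s_x, s_y = s_y)
}

#' Fit the deterioration-axis slope
#'
#' The axis U is the average of the slopes of the lines from O to each
#' fracture-reference subject, computed in standardized space. Points with
#' |zx| below `eps` contribute an unstable ratio and are excluded (their
#' count is returned as a diagnostic). The method presumes the fracture
#' cohort is displaced toward quadrant IV (high porosity, low density), so a
#' non-negative mean slope is an error.
#'
#' @param centroid list with `o_x`, `o_y`, `s_x`, `s_y` (from [fit_centroid()]).
#' @param fracture_ref a [cohort_table] of fracture-reference subjects.
#' @param eps exclusion threshold on |zx| (standardized).
#' @param min_points minimum usable points (default 2).
#' @return the mean slope (scalar, < 0) with attributes `n_used` and
#'   `n_excluded`.
#' @export
fit_axis <- function(centroid, fracture_ref, eps = 1e-8, min_points = 2L) {
  stopifnot(inherits(fracture_ref, "cohort_table"))
  zx <- (fracture_ref$cortical_porosity_pct - centroid$o_x) / centroid$s_x
  zy <- (fracture_ref$trabecular_density_mghacm3 - centroid$o_y) / centroid$s_y
  usable <- abs(zx) > eps
  if (sum(usable) < min_points) {
    stop("fewer than ", min_points, " fracture-reference points usable for slope fitting")
  }
  slope <- mean(zy[usable] / zx[usable])
  if (slope >= 0) stop("axis does not point toward deterioration (slope >= 0)")
  structure(slope, n_used = sum(usable), n_excluded = sum(!usable))
}

#' Locate the maximum-deterioration point Z
#'
#' Z is the point along U at the largest orthogonal projection of any
#' fracture-reference subject onto U: the maximal observed deterioration.
#' Its along-axis coordinate `ell_z` fixes the score scale (`100 / ell_z`).
#'
#' @param centroid list with `o_x`, `o_y`, `s_x`, `s_y`.
#' @param slope fitted axis slope (< 0).
#' @param fracture_ref a [cohort_table] of fracture-reference subjects.
#' @return `ell_z` (scalar, > 0).
#' @export
locate_z <- function(centroid, slope, fracture_ref) {
  stopifnot(inherits(fracture_ref, "cohort_table"), nrow(fracture_ref) > 0L)
  u <- axis_unit_vector(slope)
  zx <- (fracture_ref$cortical_porosity_pct - centroid$o_x) / centroid$s_x
  zy <- (fracture_ref$trabecular_density_mghacm3 - centroid$o_y) / centroid$s_y
  ell_z <- max(zx * u[1] + zy * u[2])
  if (ell_z <= 0) {
    stop("no fracture-reference point projects into the deterioration direction")
  }
  ell_z
}

#' Fit the full reference frame
#'
#' Composes [fit_centroid()] on the premenopausal sample with [fit_axis()]
#' and [locate_z()] on the fracture-reference sample. Deterministic and
#' invariant to record order.
#'
#' @param premeno premenopausal [cohort_table].
#' @param fracture_ref fracture-reference [cohort_table].
#' @return a [ref_frame] with an `axis_diagnostics` attribute giving the
#'   number of points used/excluded in the slope average.
#' @export
fit_frame <- function(premeno, fracture_ref) {
  centroid <- fit_centroid(premeno)
  slope <- fit_axis(centroid, fracture_ref)
  ell_z <- locate_z(centroid, as.numeric(slope), fracture_ref)
  frame <- ref_frame(centroid$o_x, centroid$o_y, centroid$s_x, centroid$s_y,
                     as.numeric(slope), ell_z)
  attr(frame, "axis_diagnostics") <- list(n_used = attr(slope, "n_used"),
                                          n_excluded = attr(slope, "n_excluded"))
  frame
}

#' Write a reference frame to YAML
#'
#' Floats are serialized with 17 significant digits so the reload is
#' bit-exact.
#'
#' @param frame a [ref_frame].
#' @param path output file path.
#' @export
write_frame <- function(frame, path) {
  validate_frame(frame)
  keys <- c("o_x", "o_y", "s_x", "s_y", "slope", "ell_z", "scale")
  writeLines(sprintf("%s: %.17g", keys, unlist(frame[keys])), path)
  invisible(path)
}

#' Read a reference frame from YAML
#'
#' @param path path to a frame YAML written by [write_frame()].
#' @return a [ref_frame].
#' @export
read_frame <- function(path) {
  vals <- yaml::read_yaml(path)
  keys <- c("o_x", "o_y", "s_x", "s_y", "slope", "ell_z")
  missing_keys <- setdiff(c(keys, "scale"), names(vals))
  if (length(missing_keys) > 0L) {
    stop("frame file missing key(s): ", paste(missing_keys, collapse = ", "))
  }
  frame <- do.call(ref_frame, lapply(vals[keys], as.numeric))
  if (abs(frame$scale - as.numeric(vals$scale)) > 1e-9 * frame$scale) {
    stop("frame file scale is inconsistent with ell_z")
  }
  frame
}

#' @export
print.ref_frame <- function(x, ...) {
  cat("<ref_frame>\n")
  cat(sprintf("  O = (%.3f %%, %.3f mg HA/cm^3); SD = (%.3f, %.3f)\n",
              x$o_x, x$o_y, x$s_x, x$s_y))
  cat(sprintf("  axis slope (standardized) = %.4f; ell_z = %.4f; scale = %.4f\n",
              x$slope, x$ell_z, x$scale))
  invisible(x)
}
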