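# Threshold-based fracture discrimination: percentile thresholds, 2x2
# tables (built from data or reconstructed from printed sensitivity and
# specificity), exact binomial CIs, Woolf odds-ratio intervals, and
# replicate-precision RMS-CV.

#' Percentile threshold
#'
#' Linear-interpolation quantile on the sorted order statistics at index
#' `p/100 * (n - 1)` (the default `type = 7` convention of
#' [stats::quantile()]); this is the convention used for all percentile cuts
#' in the package.
#'
#' @param values numeric sample, length >= 2.
#' @param p percent in (0, 100).
#' @return the threshold (scalar).
#' @export
percentile_threshold <- function(values, p) {
  stopifnot(is.numeric(values), length(p) == 1L, p > 0, p < 100)
  values <- values[!is.na(values)]
  if (length(values) < 2L) stop("need at least 2 values for a percentile threshold")
  stats::quantile(values, probs = p / 100, type = 7, names = FALSE)
}

#' Classification thresholds for the four traits
#'
#' Direction of "positive" (at-risk) follows the deterioration direction of
#' each trait: high porosity (>= cut), low trabecular density (<= cut), low
#' femoral-neck BMD T-score (<= cut), high SFS (>= cut). Boundary equality
#' counts as positive.
#'
#' @param porosity_cut cortical porosity cut (%).
#' @param density_cut trabecular density cut (mg HA/cm^3).
#' @param bmd_cut femoral-neck BMD T-score cut (SD).
#' @param sfs_cut SFS cut (score units).
#' @return an object of class `sfs_thresholds`.
#' @export
sfs_thresholds <- function(porosity_cut, density_cut, bmd_cut = -2.5, sfs_cut) {
  th <- list(porosity_cut = porosity_cut, density_cut = density_cut,
             bmd_cut = bmd_cut, sfs_cut = sfs_cut)
  if (!all(vapply(th, function(v) is.numeric(v) && length(v) == 1L && is.finite(v),
                  logical(1)))) {
    stop("all thresholds must be finite scalars")
  }
  structure(th, class = "sfs_thresholds")
}

#' Derive thresholds from a scored reference cohort
#'
#' The percentile cuts are computed on the premenopausal reference by
#' default: 90th centile of cortical porosity, 5th centile of trabecular
#' density, 90th centile of SFS, with the conventional -2.5 SD cut for the
#' BMD T-score.
#'
#' @param scored_reference data.frame with columns `cortical_porosity_pct`,
#'   `trabecular_density_mghacm3`, `sfs` (a scored reference cohort).
#' @param porosity_p,density_p,sfs_p percentiles for the three cuts.
#' @param bmd_cut absolute T-score cut.
#' @return an [sfs_thresholds] object.
#' @export
thresholds_from_reference <- function(scored_reference, porosity_p = 90,
                                      density_p = 5, sfs_p = 90,
                                      bmd_cut = -2.5) {
  sfs_thresholds(
    porosity_cut = percentile_threshold(scored_reference$cortical_porosity_pct, porosity_p),
    density_cut = percentile_threshold(scored_reference$trabecular_density_mghacm3, density_p),
    bmd_cut = bmd_cut,
    sfs_cut = percentile_threshold(scored_reference$sfs, sfs_p))
}

#' 2x2 contingency table of classifier vs fracture status
#'
#' @param tp,fn,fp,tn nonnegative integer counts; cases are `tp + fn`,
#'   controls `fp + tn`, and both margins must be >= 1.
#' @return an object of class `contingency_table`.
#' @export
contingency_table <- function(tp, fn, fp, tn) {
  cells <- c(tp = unname(tp), fn = unname(fn), fp = unname(fp), tn = unname(tn))
  if (any(!is.finite(cells)) || any(cells < 0) || any(cells != round(cells))) {
    stop("contingency cells must be nonnegative integers")
  }
  if (tp + fn < 1 || fp + tn < 1) stop("need at least one case and one control")
  cells <- stats::setNames(as.integer(round(cells)), names(cells))
  structure(as.list(cells), class = "contingency_table")
}

trait_column <- function(trait) {
  switch(trait,
         porosity = "cortical_porosity_pct",
         density = "trabecular_density_mghacm3",
         bmd = "fn_bmd_tscore",
         sfs = "sfs",
         stop("unknown trait: ", trait))
}

trait_positive <- function(scored, trait, thresholds) {
  col <- trait_column(trait)
  v <- scored[[col]]
  if (is.null(v)) stop("trait column '", col, "' absent from scored cohort")
  if (anyNA(v)) {
    stop("missing ", col, " for subject_id ",
         paste(scored$subject_id[is.na(v)], collapse = ", "))
  }
  switch(trait,
         porosity = v >= thresholds$porosity_cut,
         density = v <= thresholds$density_cut,
         bmd = v <= thresholds$bmd_cut,
         sfs = v >= thresholds$sfs_cut)
}

#' Build a 2x2 table from a scored cohort
#'
#' @param scored data.frame carrying `fracture` plus the trait columns
#'   (a [cohort_table] joined with [score_cohort()] output).
#' @param trait one of `"porosity"`, `"density"`, `"bmd"`, `"sfs"`.
#' @param thresholds an [sfs_thresholds].
#' @param exclude_positive_on optional second trait; subjects positive on it
#'   are removed from the index trait's positives before counting (the
#'   reclassification reading of "after accounting for" the other predictor).
#' @return a [contingency_table].
#' @export
build_table <- function(scored, trait, thresholds, exclude_positive_on = NULL) {
  if (anyNA(scored$fracture)) {
    stop("missing fracture status for subject_id ",
         paste(scored$subject_id[is.na(scored$fracture)], collapse = ", "))
  }
  pos <- trait_positive(scored, trait, thresholds)
  if (!is.null(exclude_positive_on)) {
    pos <- pos & !trait_positive(scored, exclude_positive_on, thresholds)
  }
  frac <- as.logical(scored$fracture)
  contingency_table(tp = sum(pos & frac), fn = sum(!pos & frac),
                    fp = sum(pos & !frac), tn = sum(!pos & !frac))
}

#' Reconstruct a 2x2 table from printed sensitivity and specificity
#'
#' Inverts rounded sensitivity/specificity and group sizes back to integer
#' counts (`tp = round(sens * n_cases)` etc., rounding half away from zero),
#' which allows exact recomputation of odds ratios published only as
#' sensitivity/specificity summaries.
#'
#' @param sensitivity,specificity proportions in `[0, 1]`.
#' @param n_cases,n_controls group sizes (>= 1).
#' @return a [contingency_table].
#' @export
reconstruct_table <- function(sensitivity, specificity, n_cases, n_controls) {
  stopifnot(sensitivity >= 0, sensitivity <= 1, specificity >= 0, specificity <= 1,
            n_cases >= 1, n_controls >= 1)
  half_away <- function(x) sign(x) * floor(abs(x) + 0.5)
  tp <- half_away(sensitivity * n_cases)
  tn <- half_away(specificity * n_controls)
  contingency_table(tp = tp, fn = n_cases - tp, fp = n_controls - tn, tn = tn)
}

#' Odds ratio with Woolf confidence interval and Wald test
#'
#' `OR = (tp * tn) / (fn * fp)`; the 95% CI is log-normal (Woolf) with
#' `SE = sqrt(1/tp + 1/fn + 1/fp + 1/tn)` and the two-sided p-value is the
#' Wald test of `log(OR) = 0`. With `correction = TRUE`, 0.5 is added to
#' every cell (Haldane–Anscombe) when any cell is zero.
#'
#' @param table a [contingency_table].
#' @param correction apply the 0.5 continuity correction to zero-cell tables.
#' @param conf_level confidence level (default 0.95).
#' @return list with `or`, `ci_low`, `ci_high`, `p`, `se_log_or`.
#' @export
odds_ratio <- function(table, correction = FALSE, conf_level = 0.95) {
  stopifnot(inherits(table, "contingency_table"))
  cells <- unlist(table[c("tp", "fn", "fp", "tn")])
  if (any(cells == 0)) {
    if (!correction) stop("zero cell in 2x2 table; use correction = TRUE")
    cells <- cells + 0.5
  }
  or <- (cells["tp"] * cells["tn"]) / (cells["fn"] * cells["fp"])
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(or = unname(or),
       ci_low = unname(exp(log(or) - z * se)),
       ci_high = unname(exp(log(or) + z * se)),
       p = unname(2 * stats::pnorm(-abs(log(or) / se))),
       se_log_or = unname(se))
}

#' Sensitivity and specificity with exact binomial CIs
#'
#' Point estimates `tp/(tp+fn)` and `tn/(fp+tn)` with 95% Clopper–Pearson
#' intervals in the beta-quantile formulation (lower bound exactly 0 at zero
#' successes, upper exactly 1 at n successes).
#'
#' @param table a [contingency_table].
#' @param conf_level confidence level (default 0.95).
#' @return list of two lists `sensitivity` and `specificity`, each with
#'   `est`, `ci_low`, `ci_high` (proportions).
#' @export
sens_spec <- function(table, conf_level = 0.95) {
  stopifnot(inherits(table, "contingency_table"))
  cp <- function(x, n) {
    alpha <- 1 - conf_level
    list(est = x / n,
         ci_low = if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1),
         ci_high = if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x))
  }
  list(sensitivity = cp(table$tp, table$tp + table$fn),
       specificity = cp(table$tn, table$fp + table$tn))
}

#' Root-mean-square coefficient of variation
#'
#' Precision of replicate measurements: per subject, the coefficient of
#' variation `sd/mean` (sample SD, n-1); reported as
#' `sqrt(mean(cv^2)) * 100` percent.
#'
#' @param replicates list of numeric vectors, one per subject, each with at
#'   least 2 replicate measurements and a positive mean.
#' @return RMS-CV in percent (scalar).
#' @export
rms_cv <- function(replicates) {
  stopifnot(is.list(replicates), length(replicates) >= 1L)
  cvs <- vapply(replicates, function(v) {
    if (length(v) < 2L) stop("each subject needs >= 2 replicates")
    m <- mean(v)
    if (!is.finite(m) || m <= 0) stop("nonpositive replicate mean")
    stats::sd(v) / m
  }, numeric(1))
  sqrt(mean(cvs^2)) * 100
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, 2,
              dimnames = list(c("cases", "controls"), c("positive", "negative")))
  print(m)
  invisible(x)
}
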