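# Whole-cohort diagnostic evaluation: per-trait thresholds, 2x2 tables,
# sensitivity/specificity, odds ratios, and "after accounting for" variants.

trait_pairs_default <- list(bmd = "sfs", sfs = "bmd")

summarize_table <- function(table, correction = FALSE) {
  ss <- sens_spec(table)
  or <- tryCatch(odds_ratio(table, correction = correction),
                 error = function(e) NULL)
  list(table = table[c("tp", "fn", "fp", "tn")],
       sensitivity = ss$sensitivity,
       specificity = ss$specificity,
       odds_ratio = or)
}

#' Evaluate threshold-based fracture discrimination in a scored cohort
#'
#' For each requested trait: the threshold applied, the 2x2 table against
#' fracture status, sensitivity and specificity with exact binomial CIs, and
#' the odds ratio with Woolf CI and Wald p. For trait pairs named in
#' `adjust_for`, two "after accounting for the other predictor" variants are
#' reported: `adjusted_logistic`, the trait's OR from a joint logistic model
#' containing both binary indicators, and `adjusted_reclassified`, the 2x2
#' statistics after removing subjects positive on the other trait from the
#' index trait's positives.
#'
#' @param scored data.frame with `fracture`, the trait columns, and `sfs`
#'   (a [cohort_table] joined with [score_cohort()] output).
#' @param thresholds an [sfs_thresholds].
#' @param traits traits to evaluate.
#' @param adjust_for named list mapping an index trait to the trait accounted
#'   for (default: BMD vs SFS both ways).
#' @param correction pass zero-cell correction through to [odds_ratio()].
#' @return nested list of class `sfs_evaluation`, JSON-serializable.
#' @export
evaluate_cohort <- function(scored, thresholds,
                            traits = c("porosity", "density", "bmd", "sfs"),
                            adjust_for = trait_pairs_default,
                            correction = FALSE) {
  stopifnot(inherits(thresholds, "sfs_thresholds"))
  out <- list()
  for (trait in traits) {
    cut <- thresholds[[paste0(trait, "_cut")]]
    entry <- c(list(threshold = cut),
               summarize_table(build_table(scored, trait, thresholds),
                               correction = correction))
    other <- adjust_for[[trait]]
    if (!is.null(other) && other %in% traits) {
      preds <- data.frame(index = as.integer(trait_positive(scored, trait, thresholds)),
                          other = as.integer(trait_positive(scored, other, thresholds)))
      names(preds) <- c(trait, other)
      adj_fit <- tryCatch(logistic_fit(scored$fracture, preds),
                          error = function(e) NULL)
      entry$adjusted_logistic <- if (!is.null(adj_fit)) {
        row <- adj_fit[adj_fit$term == trait, ]
        list(accounting_for = other, or = row$or, ci_low = row$ci_low,
             ci_high = row$ci_high, p = row$p)
      } else {
        list(accounting_for = other, error = "joint logistic fit failed")
      }
      entry$adjusted_reclassified <- c(
        list(accounting_for = other),
        summarize_table(build_table(scored, trait, thresholds,
                                    exclude_positive_on = other),
                        correction = correction))
    }
    out[[trait]] <- entry
  }
  structure(out, class = "sfs_evaluation")
}

#' Write an evaluation report as JSON
#'
#' @param evaluation an `sfs_evaluation` from [evaluate_cohort()].
#' @param path output path.
#' @export
write_evaluation <- function(evaluation, path) {
  jsonlite::write_json(unclass(evaluation), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a thresholds YAML
#'
#' Each trait key (`porosity`, `density`, `bmd`, `sfs`) maps either to
#' `cut: <absolute value>` or to `percentile: <p>`; percentile specs are
#' resolved against a scored reference cohort, which must be supplied (or
#' named by a top-level `reference:` path in the YAML).
#'
#' @param path thresholds YAML path.
#' @param reference optional scored reference data.frame for percentile cuts.
#' @return an [sfs_thresholds].
#' @export
read_thresholds <- function(path, reference = NULL) {
  spec_list <- yaml::read_yaml(path)
  if (is.null(reference) && !is.null(spec_list$reference)) {
    ref_tab <- read_cohort(spec_list$reference)
    stop_msg <- "thresholds reference must already contain an sfs column"
    if (!"sfs" %in% names(ref_tab)) stop(stop_msg)
    reference <- ref_tab
  }
  resolve <- function(trait) {
    entry <- spec_list[[trait]]
    if (is.null(entry)) stop("thresholds file missing trait: ", trait)
    if (!is.null(entry$cut)) return(as.numeric(entry$cut))
    if (!is.null(entry$percentile)) {
      if (is.null(reference)) stop("percentile threshold for '", trait,
                                   "' needs a reference cohort")
      return(percentile_threshold(reference[[trait_column(trait)]],
                                  as.numeric(entry$percentile)))
    }
    stop("threshold for '", trait, "' must give 'cut' or 'percentile'")
  }
  sfs_thresholds(porosity_cut = resolve("porosity"),
                 density_cut = resolve("density"),
                 bmd_cut = resolve("bmd"),
                 sfs_cut = resolve("sfs"))
}
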