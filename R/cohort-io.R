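# Subject-level cohort tables: reading, validation, writing.

COHORT_LEVELS <- c("premenopausal_reference", "fracture_reference", "evaluation")

# Canonical column set; extra columns are preserved untouched.
MANDATORY_COLUMNS <- c("subject_id", "age", "cortical_porosity_pct",
                       "trabecular_density_mghacm3", "cohort")
OPTIONAL_COLUMNS <- c("fn_bmd_tscore", "fracture")

#' Construct and validate a cohort table
#'
#' A cohort table is a `data.frame` of one row per subject carrying the two
#' HR-pQCT microarchitecture traits (cortical porosity in % of cortical
#' volume, trabecular density in mg HA/cm^3), age, an optional femoral-neck
#' BMD T-score, an optional fracture flag, and a cohort label. Validation
#' enforces the physical ranges of the traits and requires a fracture flag
#' wherever fracture status is analytically meaningful (evaluation and
#' fracture-reference cohorts).
#'
#' @param records data.frame with at least the columns `subject_id`, `age`,
#'   `cortical_porosity_pct`, `trabecular_density_mghacm3`, `cohort`;
#'   optionally `fn_bmd_tscore` and `fracture` (0/1 or logical). Extra
#'   columns are kept as-is.
#' @param label free-text label attached to the table.
#' @return the validated data.frame with class `cohort_table`, `fracture`
#'   coerced to logical, and a `label` attribute.
#' @export
cohort_table <- function(records, label = "") {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) stop("cohort table must be non-empty")
  missing_cols <- setdiff(MANDATORY_COLUMNS, names(records))
  if (length(missing_cols) > 0L) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (col in OPTIONAL_COLUMNS) {
    if (!col %in% names(records)) records[[col]] <- NA
  }
  records$subject_id <- as.character(records$subject_id)
  records$fracture <- validate_fracture_flag(records$fracture)
  dup <- records$subject_id[duplicated(records$subject_id)]
  if (length(dup) > 0L) {
    stop("duplicate subject_id: ", paste(unique(dup), collapse = ", "))
  }
  validate_records(records)
  structure(records, class = c("cohort_table", "data.frame"), label = label)
}

validate_fracture_flag <- function(x) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) {
    bad <- !is.na(x) & !x %in% c(0, 1)
    if (any(bad)) stop("fracture must be coded 0/1, got: ",
                       paste(unique(x[bad]), collapse = ", "))
    return(as.logical(x))
  }
  if (all(is.na(x))) return(as.logical(x))
  stop("fracture column must be logical or 0/1 numeric")
}

validate_records <- function(records) {
  check_field <- function(ok, field) {
    bad <- which(!ok)
    if (length(bad) > 0L) {
      stop("invalid ", field, " for subject_id ",
           paste(records$subject_id[bad], collapse = ", "))
    }
  }
  check_field(is.finite(records$age) & records$age > 0, "age")
  por <- records$cortical_porosity_pct
  check_field(is.finite(por) & por >= 0 & por <= 100, "cortical_porosity_pct")
  den <- records$trabecular_density_mghacm3
  check_field(is.finite(den) & den >= 0, "trabecular_density_mghacm3")
  check_field(records$cohort %in% COHORT_LEVELS, "cohort")
  needs_fracture <- records$cohort %in% c("evaluation", "fracture_reference")
  check_field(!needs_fracture | !is.na(records$fracture), "fracture")
  invisible(records)
}

#' Read a cohort CSV
#'
#' Reads a UTF-8 comma-separated table with the canonical header
#' (`subject_id, age, cortical_porosity_pct, trabecular_density_mghacm3,
#' fn_bmd_tscore, fracture, cohort`; the last three may carry empty strings
#' for missing values) and validates every row. Row order is preserved and
#' unknown extra columns are passed through.
#'
#' @param path file path to the CSV.
#' @param expected_cohort if non-NULL, every row's cohort label must equal it.
#' @return a [cohort_table].
#' @export
read_cohort <- function(path, expected_cohort = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         colClasses = c(subject_id = "character"))
  tab <- cohort_table(raw, label = basename(path))
  if (!is.null(expected_cohort)) {
    off <- tab$cohort != expected_cohort
    if (any(off)) {
      stop("expected cohort '", expected_cohort, "' but found '",
           paste(unique(tab$cohort[off]), collapse = "', '"), "'")
    }
  }
  tab
}

#' Write a scored cohort CSV
#'
#' Appends the per-subject score decomposition (`A`, `B`, `ell`, `sfs`,
#' `quadrant`) to the cohort columns and writes CSV with numeric fields at
#' full double precision, so a read/write cycle is lossless.
#'
#' @param cohort a [cohort_table].
#' @param scores data.frame as returned by [score_cohort()], keyed 1:1 to the
#'   cohort's `subject_id`.
#' @param path output file path.
#' @export
write_scored_cohort <- function(cohort, scores, path) {
  stopifnot(inherits(cohort, "cohort_table"), is.data.frame(scores))
  missing_ids <- setdiff(cohort$subject_id, scores$subject_id)
  if (length(missing_ids) > 0L) {
    stop("no score for subject_id ", paste(missing_ids, collapse = ", "))
  }
  idx <- match(cohort$subject_id, scores$subject_id)
  out <- as.data.frame(cohort)
  for (col in c("A", "B", "ell", "sfs")) out[[col]] <- scores[[col]][idx]
  out$quadrant <- scores$quadrant[idx]
  for (col in names(out)) {
    if (is.double(out[[col]])) {
      v <- out[[col]]
      out[[col]] <- ifelse(is.na(v), "", sprintf("%.17g", v))
    }
    if (is.logical(out[[col]])) {
      v <- out[[col]]
      out[[col]] <- ifelse(is.na(v), "", as.integer(v))
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> %d subjects%s\n", nrow(x),
              if (nzchar(attr(x, "label"))) paste0(" [", attr(x, "label"), "]") else ""))
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}
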