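# Unconditional logistic regression for fracture odds, with explicit
# degenerate-input handling (constant predictors, complete separation).

#' Logistic regression with per-coefficient odds ratios
#'
#' Maximum-likelihood logistic fit (iteratively reweighted least squares,
#' convergence tolerance 1e-10, at most 100 iterations) of a binary outcome
#' on one or more predictors, reporting Wald SEs from the inverse observed
#' information and per-coefficient odds ratios with 95% CIs. Used both for
#' crude ORs (single binary predictor, where `exp(coef)` equals the
#' cross-product ratio of the induced 2x2 table) and covariate-adjusted ORs
#' (several predictors jointly).
#'
#' @param outcomes logical (or 0/1) vector; needs at least one event and one
#'   non-event.
#' @param predictors data.frame (or matrix) of numeric/binary columns; no
#'   column may be constant.
#' @param conf_level confidence level for the Wald CIs.
#' @return data.frame with one row per term: `term`, `estimate`, `se`, `z`,
#'   `p`, `or`, `ci_low`, `ci_high`.
#' @export
logistic_fit <- function(outcomes, predictors, conf_level = 0.95) {
  y <- as.logical(outcomes)
  if (anyNA(y)) stop("missing outcome values")
  if (!any(y) || all(y)) stop("need at least one event and one non-event")
  x <- as.data.frame(predictors)
  if (ncol(x) == 0L || nrow(x) != length(y)) {
    stop("predictors must be a non-empty table with one row per outcome")
  }
  constant <- vapply(x, function(v) length(unique(v)) < 2L, logical(1))
  if (any(constant)) {
    stop("constant predictor column(s): ", paste(names(x)[constant], collapse = ", "))
  }
  dat <- cbind(data.frame(.y = as.integer(y)), x)
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = dat, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-10, maxit = 100)),
    warning = function(w) invokeRestart("muffleWarning"))
  coefs <- stats::coef(fit)
  if (anyNA(coefs)) stop("predictors are collinear; coefficients not identifiable")
  fitted_p <- stats::fitted(fit)
  separated <- any(abs(coefs[-1]) > 15) ||
    (max(fitted_p[!y]) < 1e-7 && min(fitted_p[y]) > 1 - 1e-7)
  if (separated) {
    stop("complete separation detected: the log-odds are not identifiable")
  }
  se <- sqrt(diag(stats::vcov(fit)))
  z <- coefs / se
  q <- stats::qnorm(1 - (1 - conf_level) / 2)
  data.frame(term = names(coefs),
             estimate = unname(coefs),
             se = unname(se),
             z = unname(z),
             p = unname(2 * stats::pnorm(-abs(z))),
             or = unname(exp(coefs)),
             ci_low = unname(exp(coefs - q * se)),
             ci_high = unname(exp(coefs + q * se)),
             row.names = NULL, stringsAsFactors = FALSE)
}
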