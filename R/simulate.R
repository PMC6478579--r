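# Synthetic cohorts: a premenopausal bivariate-Gaussian reference cloud, a
# fracture-derivation cohort displaced along a latent deterioration axis,
# and a postmenopausal evaluation cohort with age-correlated drift and
# logistic fracture assignment. The generator realizes the geometric
# assumption of the scoring method (deterioration = drift along one axis
# plus orthogonal noise), so parameter-recovery tests are interpretable.

#' Generator configuration
#'
#' Defaults describe a premenopausal distal-radius reference with cortical
#' porosity ~ N(36, 4) % and trabecular density ~ N(112, 30) mg HA/cm^3
#' (correlation -0.2), age-related deterioration of 1 standardized distance
#' unit per decade after 50 along a slope -1 axis, and a logistic fracture
#' model on the SFS. At the evaluation cohort's median age (62.5 y under
#' ages U(50, 75)) the implied typical porosity/density are about 39.5% and
#' 85.5 mg HA/cm^3.
#'
#' @param premeno_mean_porosity,premeno_sd_porosity premenopausal cortical
#'   porosity mean and SD (%).
#' @param premeno_mean_density,premeno_sd_density premenopausal trabecular
#'   density mean and SD (mg HA/cm^3).
#' @param premeno_corr trait correlation in (-1, 1).
#' @param aging_drift_per_decade mean drift along the deterioration axis per
#'   decade after age 50 (standardized units).
#' @param drift_sd subject-level SD of the drift (standardized units).
#' @param axis_slope_true latent axis slope in standardized space (< 0).
#' @param orthogonal_noise_sd SD of noise orthogonal to the axis
#'   (standardized units).
#' @param fracture_ref_shift extra displacement along the axis of the
#'   fracture-derivation cohort (standardized units).
#' @param fracture_intercept,fracture_beta logistic fracture model:
#'   `P(fracture) = plogis(intercept + beta * sfs)`.
#' @param age_range evaluation-cohort age range (years; uniform).
#' @param n_premeno,n_fracture_ref,n_cases,n_controls cohort sizes/quotas.
#' @param seed master seed; per-cohort streams are derived from it.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(premeno_mean_porosity = 36,
                             premeno_mean_density = 112,
                             premeno_sd_porosity = 4,
                             premeno_sd_density = 30,
                             premeno_corr = -0.2,
                             aging_drift_per_decade = 1.0,
                             drift_sd = 0.5,
                             axis_slope_true = -1.0,
                             orthogonal_noise_sd = 0.4,
                             fracture_ref_shift = 3.0,
                             fracture_intercept = -2.5,
                             fracture_beta = 0.04,
                             age_range = c(50, 75),
                             n_premeno = 324L,
                             n_fracture_ref = 33L,
                             n_cases = 99L,
                             n_controls = 105L,
                             seed = 1L) {
  config <- list(premeno_mean_porosity = premeno_mean_porosity,
                 premeno_mean_density = premeno_mean_density,
                 premeno_sd_porosity = premeno_sd_porosity,
                 premeno_sd_density = premeno_sd_density,
                 premeno_corr = premeno_corr,
                 aging_drift_per_decade = aging_drift_per_decade,
                 drift_sd = drift_sd,
                 axis_slope_true = axis_slope_true,
                 orthogonal_noise_sd = orthogonal_noise_sd,
                 fracture_ref_shift = fracture_ref_shift,
                 fracture_intercept = fracture_intercept,
                 fracture_beta = fracture_beta,
                 age_range = age_range,
                 n_premeno = as.integer(n_premeno),
                 n_fracture_ref = as.integer(n_fracture_ref),
                 n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 seed = as.integer(seed))
  stopifnot(config$premeno_sd_porosity > 0, config$premeno_sd_density > 0,
            abs(config$premeno_corr) < 1, config$axis_slope_true < 0,
            config$drift_sd >= 0, config$orthogonal_noise_sd >= 0,
            length(config$age_range) == 2L, diff(config$age_range) > 0,
            config$n_premeno >= 1L, config$n_fracture_ref >= 1L,
            config$n_cases >= 1L, config$n_controls >= 1L)
  structure(config, class = "generator_config")
}

# Derived per-stream seed, kept in 32-bit integer range.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 7919 + stream * 104729) %% 2147483647)
}

with_stream_seed <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(derive_seed(seed, stream))
  expr
}

premeno_sigma <- function(config) {
  sx <- config$premeno_sd_porosity
  sy <- config$premeno_sd_density
  r <- config$premeno_corr
  matrix(c(sx^2, r * sx * sy, r * sx * sy, sy^2), 2, 2)
}

in_range <- function(porosity, density) {
  porosity >= 0 & porosity <= 100 & density >= 0
}

# Redraw rows violating the physical trait ranges; error if acceptance is
# hopeless (< 1% after the first batch).
redraw_truncated <- function(n, draw_fun, max_rounds = 1000L) {
  out <- draw_fun(n)
  ok <- in_range(out$porosity, out$density)
  if (mean(ok) < 0.01) stop("truncation region accepts < 1% of draws; infeasible config")
  rounds <- 0L
  while (!all(ok) && rounds < max_rounds) {
    idx <- which(!ok)
    repl <- draw_fun(length(idx))
    for (nm in names(out)) out[[nm]][idx] <- repl[[nm]]
    ok <- in_range(out$porosity, out$density)
    rounds <- rounds + 1L
  }
  if (!all(ok)) stop("truncation redraw did not converge")
  out
}

#' Generate a premenopausal reference cohort
#'
#' Bivariate Gaussian draws with the configured means/SDs/correlation,
#' truncated to the physical trait ranges by redraw; ages uniform 20-40.
#'
#' @param config a [generator_config].
#' @param seed master seed (default `config$seed`).
#' @return a [cohort_table] with cohort `premenopausal_reference`.
#' @export
generate_premenopausal <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_premeno
  with_stream_seed(seed, 1L, {
    mu <- c(config$premeno_mean_porosity, config$premeno_mean_density)
    sigma <- premeno_sigma(config)
    draws <- redraw_truncated(n, function(m) {
      z <- MASS::mvrnorm(m, mu = mu, Sigma = sigma)
      z <- matrix(z, ncol = 2)
      list(porosity = z[, 1], density = z[, 2])
    })
    cohort_table(data.frame(
      subject_id = sprintf("pre%04d", seq_len(n)),
      age = stats::runif(n, 20, 40),
      cortical_porosity_pct = draws$porosity,
      trabecular_density_mghacm3 = draws$density,
      fn_bmd_tscore = NA_real_,
      fracture = NA,
      cohort = "premenopausal_reference",
      stringsAsFactors = FALSE), label = "synthetic premenopausal reference")
  })
}

# Raw-unit coordinates from standardized ones, using the generator's truth.
truth_destandardize <- function(config, zx, zy) {
  list(porosity = config$premeno_mean_porosity + zx * config$premeno_sd_porosity,
       density = config$premeno_mean_density + zy * config$premeno_sd_density)
}

#' Generate a postmenopausal evaluation cohort
#'
#' Each subject is a premenopausal-style draw displaced along the latent
#' deterioration axis by `aging_drift_per_decade * (age - 50)/10` (plus a
#' N(0, drift_sd) subject effect), with N(0, orthogonal_noise_sd) noise
#' orthogonal to the axis, mapped back to raw units and truncated by redraw.
#' A femoral-neck BMD T-score declining with axis drift is attached.
#' Fracture status is left unset (see [assign_fracture()]).
#'
#' @inheritParams generate_premenopausal
#' @param n number of subjects (defaults to `n_cases + n_controls`).
#' @return a [cohort_table] with cohort `evaluation` (fracture all FALSE
#'   placeholder).
#' @export
generate_postmenopausal <- function(config, seed = config$seed,
                                    n = config$n_cases + config$n_controls) {
  stopifnot(inherits(config, "generator_config"))
  u <- axis_unit_vector(config$axis_slope_true)
  v <- c(-u[2], u[1])
  mu <- c(config$premeno_mean_porosity, config$premeno_mean_density)
  sigma <- premeno_sigma(config)
  with_stream_seed(seed, 2L, {
    age <- stats::runif(n, config$age_range[1], config$age_range[2])
    draw <- function(idx) {
      m <- length(idx)
      base <- matrix(MASS::mvrnorm(m, mu = c(0, 0), Sigma = sigma), ncol = 2)
      zx0 <- base[, 1] / config$premeno_sd_porosity
      zy0 <- base[, 2] / config$premeno_sd_density
      ell <- config$aging_drift_per_decade * (age[idx] - 50) / 10 +
        stats::rnorm(m, 0, config$drift_sd)
      eta <- stats::rnorm(m, 0, config$orthogonal_noise_sd)
      zx <- zx0 + ell * u[1] + eta * v[1]
      zy <- zy0 + ell * u[2] + eta * v[2]
      raw <- truth_destandardize(config, zx, zy)
      raw$ell <- ell
      raw
    }
    draws <- draw(seq_len(n))
    ok <- in_range(draws$porosity, draws$density)
    if (mean(ok) < 0.01) stop("truncation region accepts < 1% of draws; infeasible config")
    rounds <- 0L
    while (!all(ok) && rounds < 1000L) {
      idx <- which(!ok)
      repl <- draw(idx)
      for (nm in names(draws)) draws[[nm]][idx] <- repl[[nm]]
      ok <- in_range(draws$porosity, draws$density)
      rounds <- rounds + 1L
    }
    if (!all(ok)) stop("truncation redraw did not converge")
    tscore <- -0.3 - 0.35 * draws$ell + stats::rnorm(n, 0, 0.8)
    cohort_table(data.frame(
      subject_id = sprintf("post%05d", seq_len(n)),
      age = age,
      cortical_porosity_pct = draws$porosity,
      trabecular_density_mghacm3 = draws$density,
      fn_bmd_tscore = tscore,
      fracture = FALSE,
      cohort = "evaluation",
      stringsAsFactors = FALSE), label = "synthetic postmenopausal")
  })
}

#' Generate a fracture-derivation cohort
#'
#' Points placed directly on the latent deterioration axis at along-axis
#' distance `fracture_ref_shift + drift * (age - 50)/10 + N(0, drift_sd)`
#' (ages uniform 50-90) with orthogonal noise only — the displaced,
#' quadrant-IV cloud from which the axis slope and the maximum-deterioration
#' point are derived.
#'
#' @inheritParams generate_premenopausal
#' @param n number of subjects (defaults to `n_fracture_ref`).
#' @return a [cohort_table] with cohort `fracture_reference`, fracture TRUE.
#' @export
generate_fracture_reference <- function(config, seed = config$seed,
                                        n = config$n_fracture_ref) {
  stopifnot(inherits(config, "generator_config"))
  u <- axis_unit_vector(config$axis_slope_true)
  v <- c(-u[2], u[1])
  with_stream_seed(seed, 3L, {
    age <- stats::runif(n, 50, 90)
    draw <- function(idx) {
      m <- length(idx)
      ell <- config$fracture_ref_shift +
        config$aging_drift_per_decade * (age[idx] - 50) / 10 +
        stats::rnorm(m, 0, config$drift_sd)
      eta <- stats::rnorm(m, 0, config$orthogonal_noise_sd)
      truth_destandardize(config, ell * u[1] + eta * v[1],
                          ell * u[2] + eta * v[2])
    }
    draws <- redraw_truncated(n, function(m) draw(seq_len(m)))
    cohort_table(data.frame(
      subject_id = sprintf("frac%04d", seq_len(n)),
      age = age,
      cortical_porosity_pct = draws$porosity,
      trabecular_density_mghacm3 = draws$density,
      fn_bmd_tscore = NA_real_,
      fracture = TRUE,
      cohort = "fracture_reference",
      stringsAsFactors = FALSE), label = "synthetic fracture reference")
  })
}

#' Assign fracture status from the logistic SFS model
#'
#' `fracture ~ Bernoulli(plogis(fracture_intercept + fracture_beta * sfs))`,
#' with the SFS computed under the supplied frame.
#'
#' @param cohort a [cohort_table] scoreable under `frame`.
#' @param frame a [ref_frame].
#' @param config a [generator_config].
#' @param seed master seed (default `config$seed`).
#' @return the cohort with `fracture` replaced by the simulated flags.
#' @export
assign_fracture <- function(cohort, frame, config, seed = config$seed) {
  stopifnot(inherits(cohort, "cohort_table"), inherits(config, "generator_config"))
  scores <- score_cohort(cohort, frame)
  p <- stats::plogis(config$fracture_intercept + config$fracture_beta * scores$sfs)
  with_stream_seed(seed, 4L, {
    cohort$fracture <- stats::rbinom(nrow(cohort), 1L, p) == 1L
  })
  cohort
}

#' Generate a full case-control study bundle
#'
#' Generates the premenopausal reference and fracture-derivation cohorts,
#' fits the reference frame on them, draws postmenopausal subjects in
#' batches with logistic fracture assignment until the case/control quotas
#' are met, and samples without replacement down to exactly `n_cases` cases
#' and `n_controls` controls.
#'
#' @param config a [generator_config].
#' @param seed master seed (default `config$seed`).
#' @param max_batches cap on quota-filling batches before erroring.
#' @return list with `premeno`, `fracture_ref`, `evaluation` (cohort tables),
#'   `frame` (the frame fitted on the generated reference cohorts), and
#'   `truth` (the generating parameters).
#' @export
generate_case_control <- function(config, seed = config$seed, max_batches = 25L) {
  stopifnot(inherits(config, "generator_config"))
  premeno <- generate_premenopausal(config, seed)
  fracture_ref <- generate_fracture_reference(config, seed)
  frame <- fit_frame(premeno, fracture_ref)
  quota <- c(cases = config$n_cases, controls = config$n_controls)
  batch_n <- max(4L * (config$n_cases + config$n_controls), 500L)
  pool <- NULL
  for (b in seq_len(max_batches)) {
    chunk <- generate_postmenopausal(config, seed = derive_seed(seed, 100L + b),
                                     n = batch_n)
    chunk <- assign_fracture(chunk, frame, config,
                             seed = derive_seed(seed, 200L + b))
    chunk$subject_id <- sprintf("b%02d_%s", b, chunk$subject_id)
    pool <- if (is.null(pool)) as.data.frame(chunk)
            else rbind(pool, as.data.frame(chunk))
    if (sum(pool$fracture) >= quota["cases"] &&
        sum(!pool$fracture) >= quota["controls"]) break
  }
  if (sum(pool$fracture) < quota["cases"] || sum(!pool$fracture) < quota["controls"]) {
    stop("case/control quota not reached after ", max_batches,
         " batches; fracture model too weak or quotas too large")
  }
  evaluation <- with_stream_seed(seed, 5L, {
    case_rows <- sample(which(pool$fracture), quota["cases"])
    control_rows <- sample(which(!pool$fracture), quota["controls"])
    pool[sort(c(case_rows, control_rows)), , drop = FALSE]
  })
  rownames(evaluation) <- NULL
  list(premeno = premeno,
       fracture_ref = fracture_ref,
       evaluation = cohort_table(evaluation, label = "synthetic case-control"),
       frame = frame,
       truth = unclass(config))
}

#' Write a simulated study to disk
#'
#' Writes `premeno.csv`, `fracture_ref.csv`, `evaluation.csv` and
#' `truth.json` (the generating parameters) into a directory.
#'
#' @param config a [generator_config].
#' @param out_dir output directory (created if absent).
#' @param seed master seed (default `config$seed`).
#' @return the output directory, invisibly.
#' @export
simulate_study <- function(config, out_dir, seed = config$seed) {
  bundle <- generate_case_control(config, seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_plain_cohort <- function(tab, name) {
    out <- as.data.frame(tab)
    for (col in names(out)) {
      if (is.double(out[[col]])) {
        out[[col]] <- ifelse(is.na(out[[col]]), "", sprintf("%.17g", out[[col]]))
      }
      if (is.logical(out[[col]])) {
        out[[col]] <- ifelse(is.na(out[[col]]), "", as.integer(out[[col]]))
      }
    }
    utils::write.csv(out, file.path(out_dir, name), row.names = FALSE,
                     quote = FALSE, na = "")
  }
  write_plain_cohort(bundle$premeno, "premeno.csv")
  write_plain_cohort(bundle$fracture_ref, "fracture_ref.csv")
  write_plain_cohort(bundle$evaluation, "evaluation.csv")
  jsonlite::write_json(bundle$truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
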