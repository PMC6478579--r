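test_that("percentile thresholds match a sort-and-interpolate oracle", {
  expect_equal(percentile_threshold(rep(7, 10), 35), 7)
  expect_equal(percentile_threshold(0:100, 90), 90)
  expect_error(percentile_threshold(3, 50), "at least 2")

  # independent oracle: linear interpolation at h = p/100 * (n-1)
  oracle <- function(x, p) {
    s <- sort(x); h <- p / 100 * (length(x) - 1)
    lo <- floor(h)
    s[lo + 1] + (h - lo) * (s[min(lo + 2, length(x))] - s[lo + 1])
  }
  set.seed(53)
  for (i in 1:25) {
    x <- rnorm(sample(5:200, 1))
    p <- runif(1, 1, 99)
    expect_equal(percentile_threshold(x, p), oracle(x, p), tolerance = 1e-12)
  }
})

test_that("2x2 tables from scored cohorts match a brute-force recount", {
  th <- sfs_thresholds(porosity_cut = 41, density_cut = 70, bmd_cut = -2.5,
                       sfs_cut = 20)
  scored <- data.frame(
    subject_id = sprintf("s%02d", 1:4),
    cortical_porosity_pct = c(45, 45, 30, 30),
    trabecular_density_mghacm3 = c(60, 60, 90, 90),
    fn_bmd_tscore = c(-3, -1, -1, -1),
    sfs = c(30, 25, 5, -10),
    fracture = c(TRUE, TRUE, FALSE, FALSE))
  tab <- build_table(scored, "sfs", th)
  expect_identical(unlist(tab[c("tp", "fn", "fp", "tn")]),
                   c(tp = 2L, fn = 0L, fp = 0L, tn = 2L))
  # a porosity cut below any attainable value classifies everyone positive
  all_pos <- build_table(scored, "porosity", sfs_thresholds(-1e9, 70, -2.5, 20))
  expect_identical(all_pos$fp, 2L)

  set.seed(59)
  n <- 300L
  rnd <- data.frame(
    subject_id = sprintf("r%03d", 1:n),
    cortical_porosity_pct = runif(n, 20, 60),
    trabecular_density_mghacm3 = runif(n, 30, 160),
    fn_bmd_tscore = rnorm(n, -1, 1),
    sfs = rnorm(n, 30, 25),
    fracture = rbinom(n, 1, 0.4) == 1)
  for (trait in c("porosity", "density", "bmd", "sfs")) {
    tab <- build_table(rnd, trait, th)
    col <- switch(trait, porosity = rnd$cortical_porosity_pct >= th$porosity_cut,
                  density = rnd$trabecular_density_mghacm3 <= th$density_cut,
                  bmd = rnd$fn_bmd_tscore <= th$bmd_cut,
                  sfs = rnd$sfs >= th$sfs_cut)
    expect_identical(tab$tp, sum(col & rnd$fracture))
    expect_identical(tab$tn, sum(!col & !rnd$fracture))
    expect_identical(tab$tp + tab$fn + tab$fp + tab$tn, n)
  }

  rnd$sfs[3] <- NA
  expect_error(build_table(rnd, "sfs", th), "r003")
})

test_that("tables reconstruct from rounded sensitivity and specificity", {
  t_bmd <- reconstruct_table(0.1010, 0.9810, 99, 105)
  expect_identical(unlist(t_bmd[c("tp", "fn", "fp", "tn")]),
                   c(tp = 10L, fn = 89L, fp = 2L, tn = 103L))
  t_sfs <- reconstruct_table(0.3540, 0.8950, 99, 105)
  expect_identical(unlist(t_sfs[c("tp", "fn", "fp", "tn")]),
                   c(tp = 35L, fn = 64L, fp = 11L, tn = 94L))
  t_perfect <- reconstruct_table(1, 1, 7, 9)
  expect_identical(unlist(t_perfect[c("tp", "fn", "fp", "tn")]),
                   c(tp = 7L, fn = 0L, fp = 0L, tn = 9L))
  # rounding is half away from zero
  expect_identical(reconstruct_table(0.5, 0.5, 1, 1)$tp, 1L)
})

test_that("odds ratios carry Woolf CIs and a Wald test", {
  or <- odds_ratio(contingency_table(10, 89, 2, 103))
  expect_equal(or$or, 1030 / 178, tolerance = 1e-12)
  expect_equal(or$se_log_or, sqrt(1 / 10 + 1 / 89 + 1 / 2 + 1 / 103),
               tolerance = 1e-12)

  sym <- odds_ratio(contingency_table(1, 1, 1, 1))
  expect_equal(sym$or, 1)
  expect_equal(sym$ci_low * sym$ci_high, 1, tolerance = 1e-12)
  expect_equal(sym$p, 1)

  expect_error(odds_ratio(contingency_table(0, 10, 5, 5)), "zero cell")
  corr <- odds_ratio(contingency_table(0, 10, 5, 5), correction = TRUE)
  expect_equal(corr$or, (0.5 * 5.5) / (10.5 * 5.5), tolerance = 1e-12)

  # swapping case/control labels inverts the OR and swaps CI bounds
  set.seed(61)
  for (i in 1:20) {
    cells <- rpois(4, 20) + 1
    a <- odds_ratio(contingency_table(cells[1], cells[2], cells[3], cells[4]))
    b <- odds_ratio(contingency_table(cells[3], cells[4], cells[1], cells[2]))
    expect_equal(a$or, 1 / b$or, tolerance = 1e-12)
    expect_equal(a$ci_low, 1 / b$ci_high, tolerance = 1e-12)
    expect_equal(a$p, b$p, tolerance = 1e-12)
  }
})

test_that("Clopper-Pearson intervals match the exact binomial oracle", {
  # independent oracle: stats::binom.test exact interval
  set.seed(67)
  cases <- rbind(c(10, 99), c(103, 105), c(0, 20), c(20, 20),
                 cbind(rbinom(10, 50, 0.3), 50))
  for (i in seq_len(nrow(cases))) {
    x <- cases[i, 1]; n <- cases[i, 2]
    got <- sens_spec(contingency_table(x, n - x, 1, 1))$sensitivity
    ref <- stats::binom.test(x, n)$conf.int
    expect_equal(got$est, x / n)
    expect_equal(got$ci_low, ref[1], tolerance = 1e-10)
    expect_equal(got$ci_high, ref[2], tolerance = 1e-10)
  }
  zero <- sens_spec(contingency_table(0, 12, 1, 1))$sensitivity
  expect_identical(zero$ci_low, 0)
  full <- sens_spec(contingency_table(12, 0, 1, 1))$sensitivity
  expect_identical(full$ci_high, 1)
})

test_that("exact binomial CIs bracket the estimate with >= 95% coverage", {
  set.seed(71)
  n <- 99; p <- 0.10; reps <- 1e4
  x <- rbinom(reps, n, p)
  lo <- ifelse(x == 0, 0, qbeta(0.025, x, n - x + 1))
  hi <- ifelse(x == n, 1, qbeta(0.975, x + 1, n - x))
  expect_true(all(lo <= x / n & x / n <= hi))
  coverage <- mean(lo <= p & p <= hi)
  # exact intervals are conservative; allow Monte-Carlo error below nominal
  expect_gte(coverage, 0.95 - 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("RMS-CV matches closed-form replicate examples", {
  expect_equal(rms_cv(list(c(5, 5, 5), c(2, 2))), 0)
  expect_equal(rms_cv(list(c(90, 100, 110))), 10)  # sd 10, mean 100
  # cv pair 3% and 4% -> sqrt((9 + 16)/2) = 3.5355%
  cv_of <- function(target) {
    # two replicates a, b with mean 1 and sd target: 1 +/- target/sqrt(2)
    c(1 + target / sqrt(2), 1 - target / sqrt(2))
  }
  expect_equal(rms_cv(list(cv_of(0.03), cv_of(0.04))), sqrt((9 + 16) / 2),
               tolerance = 1e-9)
  expect_error(rms_cv(list(c(1, 2), c(3))), ">= 2 replicates")
  expect_error(rms_cv(list(c(-1, 1))), "nonpositive")
})

test_that("logistic fits agree with cross-product ORs and flag degeneracies", {
  set.seed(73)
  for (i in 1:15) {
    tab <- matrix(rpois(4, 15) + 1, 2)  # tp, fp / fn, tn layout by column
    tp <- tab[1, 1]; fn <- tab[2, 1]; fp <- tab[1, 2]; tn <- tab[2, 2]
    y <- c(rep(TRUE, tp + fn), rep(FALSE, fp + tn))
    x <- c(rep(1, tp), rep(0, fn), rep(1, fp), rep(0, tn))
    fit <- logistic_fit(y, data.frame(exposed = x))
    expect_equal(fit$or[fit$term == "exposed"],
                 odds_ratio(contingency_table(tp, fn, fp, tn))$or,
                 tolerance = 1e-6)
  }

  # outcome split identically across predictor groups -> OR exactly 1
  y <- rep(c(TRUE, FALSE, TRUE, FALSE), times = c(5, 5, 5, 5))
  x <- rep(c(1, 1, 0, 0), times = c(5, 5, 5, 5))
  fit <- logistic_fit(y, data.frame(g = x))
  expect_equal(fit$or[fit$term == "g"], 1, tolerance = 1e-9)

  expect_error(logistic_fit(c(TRUE, TRUE), data.frame(x = 1:2)), "non-event")
  expect_error(logistic_fit(c(TRUE, FALSE), data.frame(x = c(1, 1))), "constant")
  sep_y <- rep(c(TRUE, FALSE), each = 20)
  sep_x <- c(rnorm(20, 10), rnorm(20, -10))
  expect_error(logistic_fit(sep_y, data.frame(x = sep_x)), "separation")
})
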