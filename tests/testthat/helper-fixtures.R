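# In-code fixtures shared across test files.

make_cohort <- function(porosity, density, cohort = "premenopausal_reference",
                        fracture = NA, age = 30, tscore = NA_real_) {
  n <- length(porosity)
  cohort_table(data.frame(
    subject_id = sprintf("s%03d", seq_len(n)),
    age = rep_len(age, n),
    cortical_porosity_pct = porosity,
    trabecular_density_mghacm3 = density,
    fn_bmd_tscore = rep_len(tscore, n),
    fracture = rep_len(fracture, n),
    cohort = rep_len(cohort, n),
    stringsAsFactors = FALSE))
}

# A frame with unit SDs at the origin of raw space shifted to (40, 120):
# slope -1, Z at standardized distance 2*sqrt(2) along the axis.
unit_frame <- function(slope = -1, ell_z = 2 * sqrt(2), o_x = 40, o_y = 120,
                       s_x = 1, s_y = 1) {
  ref_frame(o_x = o_x, o_y = o_y, s_x = s_x, s_y = s_y,
            slope = slope, ell_z = ell_z)
}

random_frame <- function() {
  ref_frame(o_x = runif(1, 25, 45), o_y = runif(1, 80, 150),
            s_x = runif(1, 2, 6), s_y = runif(1, 15, 40),
            slope = -runif(1, 0.3, 3), ell_z = runif(1, 2, 10))
}

# Standardized coordinates -> raw units under a frame (test-side inverse).
raw_point <- function(frame, zx, zy) {
  list(porosity = frame$o_x + zx * frame$s_x,
       density = frame$o_y + zy * frame$s_y)
}
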