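# triangle TG curve: flat 0 to t=2, linear rise to 300 nM at t=5,
# linear fall to 0 at t=15 (vertices on the grid so trapezoids are exact)
triangle_curve <- function(dt = 0.1) {
  tt <- seq(0, 15, dt)
  y <- ifelse(tt < 2, 0, ifelse(tt <= 5, (tt - 2) * 100, 300 * (15 - tt) / 10))
  thrombin_curve(tt, y, sample_id = "tri")
}

median_factors <- function() plasma_factors(113, 2.6, 2.9)

# constant-fibrinogen model with round numbers: TDC = 2e-4*2500 + 5e-5*3000
# = 0.65 /min for at_pct = 100 (25 nM/%) and a2m = 3 uM
round_model <- function(stoich = FALSE) {
  rate_model(k_at_ref = 2e-4, k_a2m_ref = 5e-5, fib_dependence = "constant",
             at_nM_per_pct = 25, stoichiometric_depletion = stoich)
}
round_factors <- function() plasma_factors(100, 3, 2.9)

cohort_factor_table <- function(cohort) {
  fac <- cohort$factors
  names(fac)[names(fac) == "subject_id"] <- "sample_id"
  fac
}

# merge pipeline results with the generator's hidden ground truth
merge_truth <- function(results, truth) {
  merge(results, truth, by.x = c("sample_id", "condition"),
        by.y = c("subject_id", "condition"), suffixes = c("", ".true"))
}
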