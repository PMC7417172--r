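# Shared fixtures: tiny deterministic datasets built in code.

# Three-patient toy cohort exercising both likelihood branches.
toy_cohort <- function() {
  tibble::tibble(
    patient_id = c("A", "B", "C"),
    cohort = c(1L, 2L, 3L),
    admission_conc = c(5, 20, 45),
    peak_conc = c(5, NA, 50),
    peak_observed = c(TRUE, FALSE, TRUE),
    qrs_ms = c(95, 140, 160),
    died = c(0L, 1L, 1L)
  )
}

prior_mean_params <- function() {
  list(alpha = -15, beta = 4, gamma = 0.7, delta = 0.125,
       a_cohort = c(0, 0, 0))
}

prior_mean_qrs_params <- function() {
  list(e_max = 180, e_min = 90, e50 = 1.3, k = exp(1))
}

# A fabricated single-draw "posterior" at the prior means, handy for
# deterministic risk-engine checks.
single_draw_posterior <- function() {
  tibble::tibble(alpha = -15, beta = 4)
}

# Small synthetic posterior cloud around the prior means.
fake_posterior <- function(n = 400, seed = 42) {
  set.seed(seed)
  tibble::tibble(alpha = rnorm(n, -15, 0.5), beta = rnorm(n, 4, 0.25))
}

quiet_fit_mortality <- function(...) {
  suppressWarnings(fit_mortality(...))
}

quiet_fit_qrs <- function(...) {
  suppressWarnings(fit_qrs(...))
}
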