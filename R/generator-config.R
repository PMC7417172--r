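#' Configuration for the synthetic clinical-data generator
#'
#' Bundles the "true" values of every quantity the downstream Bayesian models
#' try to infer, so that parameter recovery can be checked end-to-end. The
#' defaults describe a self-poisoning population in which roughly 11% of
#' patients die: peak measured (chloroquine + desethyl metabolite) whole-blood
#' concentrations are log-normal, death is Bernoulli on the logistic
#' concentration-fatality scale, and QRS durations follow the sigmoid Emax
#' model with stratum-specific measurement noise.
#'
#' @param alpha_true Logit-scale global intercept of the fatality model.
#' @param beta_true Slope per unit log concentration (log umol/L).
#' @param gamma_true Fraction of the measured concentration that is parent
#'   chloroquine (metabolite correction), in (0, 1).
#' @param delta_true Mean log-scale gap between peak and admission
#'   concentration; per-patient gaps are Exponential with this mean.
#' @param cohort_effects_true Numeric length-3 vector of logit-scale cohort
#'   intercept offsets (cohorts 1, 2, 3).
#' @param cohort_props Sampling proportions of the three cohorts; default is
#'   the 11 : 247 : 44 split of the prospective series.
#' @param conc_log_mu,conc_log_sd Log-normal parameters of the measured peak
#'   concentration (umol/L). The defaults are calibration products: chosen by
#'   quadrature so the marginal death fraction under the default logistic
#'   parameters is 33/302.
#' @param frac_multi_sampled Fraction of patients with more than one
#'   concentration measurement (default 173/302).
#' @param frac_peak_after_admission Fraction of multi-sampled patients whose
#'   peak occurred in hospital, i.e. was observed (default 61/173).
#' @param qrs_params_true Named list with elements `e_max`, `e_min`, `e50`,
#'   `k`, `bias_cohort2`, `sigma_hv` (msec / log10 umol/L as appropriate).
#' @param noise_sds Named numeric vector of QRS error SDs for the three error
#'   strata: `cohort2`, `cohort3`, `volunteer` (msec).
#' @param seed Default RNG seed used by the generator functions.
#'
#' @return An object of class `cq_generator_config` (a validated list).
#' @export
#' @examples
#' cfg <- generator_config()
#' cohort <- simulate_poisoning_cohort(cfg, n = 50)
generator_config <- function(alpha_true = -15,
                             beta_true = 4,
                             gamma_true = 0.7,
                             delta_true = 0.125,
                             cohort_effects_true = c(0, 0, 0),
                             cohort_props = c(11, 247, 44) / 302,
                             conc_log_mu = 2.925,
                             conc_log_sd = 0.85,
                             frac_multi_sampled = 173 / 302,
                             frac_peak_after_admission = 61 / 173,
                             qrs_params_true = list(
                               e_max = 180, e_min = 90, e50 = 1.3,
                               k = exp(1), bias_cohort2 = -20, sigma_hv = 5
                             ),
                             noise_sds = c(cohort2 = 25, cohort3 = 15,
                                           volunteer = 2),
                             seed = 1L) {
  cfg <- list(
    alpha_true = alpha_true, beta_true = beta_true, gamma_true = gamma_true,
    delta_true = delta_true, cohort_effects_true = cohort_effects_true,
    cohort_props = cohort_props, conc_log_mu = conc_log_mu,
    conc_log_sd = conc_log_sd, frac_multi_sampled = frac_multi_sampled,
    frac_peak_after_admission = frac_peak_after_admission,
    qrs_params_true = qrs_params_true, noise_sds = noise_sds,
    seed = as.integer(seed)
  )
  class(cfg) <- "cq_generator_config"
  validate_generator_config(cfg)
}

validate_generator_config <- function(cfg) {
  bad <- character(0)
  chk <- function(ok, field) if (!isTRUE(all(ok))) bad <<- c(bad, field)

  chk(is.numeric(cfg$alpha_true) && is.finite(cfg$alpha_true), "alpha_true")
  chk(is.numeric(cfg$beta_true) && is.finite(cfg$beta_true), "beta_true")
  chk(cfg$gamma_true > 0 && cfg$gamma_true < 1, "gamma_true")
  chk(cfg$delta_true >= 0, "delta_true")
  chk(length(cfg$cohort_effects_true) == 3 &&
        all(is.finite(cfg$cohort_effects_true)), "cohort_effects_true")
  chk(length(cfg$cohort_props) == 3 && all(cfg$cohort_props >= 0) &&
        abs(sum(cfg$cohort_props) - 1) < 1e-8, "cohort_props")
  chk(is.finite(cfg$conc_log_mu), "conc_log_mu")
  chk(cfg$conc_log_sd > 0, "conc_log_sd")
  chk(cfg$frac_multi_sampled >= 0 && cfg$frac_multi_sampled <= 1,
      "frac_multi_sampled")
  chk(cfg$frac_peak_after_admission >= 0 &&
        cfg$frac_peak_after_admission <= 1, "frac_peak_after_admission")
  q <- cfg$qrs_params_true
  chk(all(c("e_max", "e_min", "e50", "k", "bias_cohort2", "sigma_hv") %in%
            names(q)), "qrs_params_true")
  if (all(c("e_max", "e_min", "k", "sigma_hv") %in% names(q))) {
    chk(q$e_max > q$e_min && q$e_min > 0 && q$k > 0 && q$sigma_hv >= 0,
        "qrs_params_true")
  }
  chk(all(c("cohort2", "cohort3", "volunteer") %in% names(cfg$noise_sds)) &&
        all(cfg$noise_sds > 0), "noise_sds")

  if (length(bad) > 0) {
    stop_invalid(paste0("Invalid generator configuration field(s): ",
                        paste(unique(bad), collapse = ", ")))
  }
  cfg
}

#' @export
print.cq_generator_config <- function(x, ...) {
  cat("<cq_generator_config>\n")
  cat(sprintf("  fatality truth: alpha=%g, beta=%g, gamma=%g, delta=%g\n",
              x$alpha_true, x$beta_true, x$gamma_true, x$delta_true))
  cat(sprintf("  peak conc ~ logNormal(%g, %g) umol/L; cohorts %s\n",
              x$conc_log_mu, x$conc_log_sd,
              paste(signif(x$cohort_props, 3), collapse = "/")))
  cat(sprintf("  QRS truth: Emin=%g, Emax=%g, E50=%g, k=%.3g, bias=%g\n",
              x$qrs_params_true$e_min, x$qrs_params_true$e_max,
              x$qrs_params_true$e50, x$qrs_params_true$k,
              x$qrs_params_true$bias_cohort2))
  invisible(x)
}
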