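#' Priors for the hierarchical QRS Emax model
#'
#' QRS duration rises sigmoidally with whole-blood chloroquine concentration
#' from a lower asymptote `e_min` (drug-free mean QRS, prior Normal(90, 4)
#' msec) to an upper asymptote `e_max` (prior Normal(180, 10) msec), with
#' midpoint `e50` on the log10 concentration scale (prior Normal(1.3, 1))
#' and slope `k` modelled on the log scale (prior Normal(1, 1)). Manually
#' read cohort-2 measurements carry an additive reading bias (prior
#' Normal(-20, 5) msec). Measurement error SDs are stratum-specific:
#' Normal(25, 5) for the cohort-2 stratum, Normal(15, 5) for cohort 3 and
#' Normal(2, 1) for the volunteers (all truncated positive). Volunteer
#' subject intercepts are Normal(0, sigma_hv) with an Exponential(0.2)
#' prior on sigma_hv.
#'
#' @param e_max,e_min,e50,log_k,bias,eps1,eps2,eps3 Length-2 numeric
#'   `c(mean, sd)` vectors.
#' @param sigma_hv_rate Rate of the exponential prior on the
#'   between-volunteer SD.
#' @return An object of class `cq_qrs_priors`.
#' @export
qrs_priors <- function(e_max = c(180, 10), e_min = c(90, 4),
                       e50 = c(1.3, 1), log_k = c(1, 1), bias = c(-20, 5),
                       eps1 = c(25, 5), eps2 = c(15, 5), eps3 = c(2, 1),
                       sigma_hv_rate = 0.2) {
  p <- list(e_max = e_max, e_min = e_min, e50 = e50, log_k = log_k,
            bias = bias, eps1 = eps1, eps2 = eps2, eps3 = eps3,
            sigma_hv_rate = sigma_hv_rate)
  sds <- c(vapply(p[1:8], `[`, numeric(1), 2), p$sigma_hv_rate)
  if (any(sds <= 0)) stop_invalid("All prior scales must be positive.")
  structure(p, class = "cq_qrs_priors")
}

#' Mean QRS duration under the sigmoid Emax model
#'
#' `e_max - (e_max - e_min) / (1 + exp(k * (log10(x) - e50)))`: strictly
#' between the asymptotes and strictly increasing in concentration for
#' positive slope.
#'
#' @param conc Whole-blood chloroquine concentration(s), umol/L, strictly
#'   positive (drug-free records are handled separately by the fit).
#' @param params Named list with `e_max`, `e_min`, `e50`, `k`.
#' @return Mean QRS duration(s) in msec.
#' @export
#' @examples
#' emax_mean(3, list(e_max = 180, e_min = 90, e50 = 1.3, k = exp(1)))
emax_mean <- function(conc, params) {
  if (any(!is.finite(conc)) || any(conc <= 0)) {
    abort("`conc` must be strictly positive.", class = "cqrisk_domain_error")
  }
  params$e_max - (params$e_max - params$e_min) /
    (1 + exp(params$k * (log10(conc) - params$e50)))
}

#' Pool volunteer and self-poisoning data on a common concentration scale
#'
#' Harmonises both data sources to whole-blood parent-drug chloroquine
#' concentration: volunteer plasma concentrations are multiplied by 4 (whole
#' blood : plasma ratio) and poisoning admission concentrations by 0.7 (to
#' remove the desethyl-metabolite contribution of the spectrophotometric
#' assay). Rows are tagged with their error stratum: 1 for the manually read
#' cohort-2 series (which also carries the additive reading-bias term),
#' 2 for cohort 3, 3 for the volunteers. Drug-free volunteer rows are kept
#' with concentration 0; they inform the drug-free mean (`e_min`) and the
#' subject intercepts. Poisoning rows without a QRS value are dropped.
#'
#' @param volunteers Volunteer tibble (see [simulate_volunteer_study()]).
#' @param poisoning Poisoning tibble (see [simulate_poisoning_cohort()]).
#' @return A tibble with `source`, `subject_id`, `stratum`, `conc_umol_L`,
#'   `qrs_ms`, `drug_free`.
#' @export
harmonize_concentrations <- function(volunteers, poisoning) {
  if (any(volunteers$plasma_conc < 0, na.rm = TRUE)) {
    stop_invalid("Negative volunteer plasma concentration.")
  }
  if (any(poisoning$admission_conc <= 0, na.rm = TRUE)) {
    stop_invalid("Non-positive poisoning admission concentration.")
  }
  vol <- tibble::tibble(
    source = "volunteer",
    subject_id = volunteers$subject_id,
    stratum = 3L,
    conc_umol_L = WB_PLASMA_RATIO * volunteers$plasma_conc,
    qrs_ms = volunteers$qrs_ms,
    drug_free = volunteers$plasma_conc == 0
  )
  poi <- poisoning[!is.na(poisoning$qrs_ms), ]
  poi <- tibble::tibble(
    source = "poisoning",
    subject_id = NA_character_,
    stratum = ifelse(poi$cohort == 2L, 1L, 2L),
    conc_umol_L = 0.7 * poi$admission_conc,
    qrs_ms = poi$qrs_ms,
    drug_free = FALSE
  )
  dplyr::bind_rows(vol, poi)
}

qrs_model_string <- "model {
  for (i in 1:N) {
    mu[i] <- df[i] * Emin +
      (1 - df[i]) * (Emax - (Emax - Emin) / (1 + exp(k * (logc[i] - E50)))) +
      bias * is1[i] + b[sub[i]]
    qrs[i] ~ dnorm(mu[i], tau[stratum[i]])
  }
  for (s in 1:S) { b[s] ~ dnorm(0, 1 / pow(sigma_hv, 2)) }
  b[S + 1] <- 0
  k <- exp(logk)
  Emax ~ dnorm(p_emax_mu, p_emax_tau)
  Emin ~ dnorm(p_emin_mu, p_emin_tau)
  E50 ~ dnorm(p_e50_mu, p_e50_tau)
  logk ~ dnorm(p_logk_mu, p_logk_tau)
  bias ~ dnorm(p_bias_mu, p_bias_tau)
  eps1 ~ dnorm(p_eps1_mu, p_eps1_tau) T(0.01,)
  eps2 ~ dnorm(p_eps2_mu, p_eps2_tau) T(0.01,)
  eps3 ~ dnorm(p_eps3_mu, p_eps3_tau) T(0.01,)
  tau[1] <- 1 / pow(eps1, 2)
  tau[2] <- 1 / pow(eps2, 2)
  tau[3] <- 1 / pow(eps3, 2)
  sigma_hv ~ dexp(p_hv_rate)
}"

#' Fit the hierarchical Bayesian QRS Emax model
#'
#' Likelihood: `QRS_i ~ Normal(mu_i, eps_stratum(i))` where `mu_i` is the
#' sigmoid Emax mean at the row's whole-blood concentration (the drug-free
#' mean `e_min` for zero-concentration volunteer rows), plus the reading
#' bias for stratum-1 rows and a subject intercept for volunteer rows.
#'
#' @param pooled Analysis table from [harmonize_concentrations()].
#' @param priors A [qrs_priors()] object.
#' @inheritParams fit_mortality
#' @return An object of class `cq_qrs_fit` with `draws` (tibble: e_max,
#'   e_min, e50, k, bias, eps1, eps2, eps3, sigma_hv, .chain),
#'   `diagnostics`, `mcmc_config`, `converged`, `warnings`, `n`.
#' @export
fit_qrs <- function(pooled, priors = qrs_priors(), chains = 4, iter = 2000,
                    burnin_frac = 0.5, thin = 1, seed = 1L, quiet = TRUE) {
  stopifnot(inherits(priors, "cq_qrs_priors"))
  if (nrow(pooled) == 0) stop_bad_arg("Empty analysis table.")
  if (!all(pooled$stratum %in% 1:3)) {
    stop_invalid("Strata must be 1 (cohort 2), 2 (cohort 3) or 3 (volunteers).")
  }
  warnings <- character(0)
  if (length(unique(pooled$stratum)) < 2) {
    msg <- "Fewer than two error strata present: stratum error SDs are only weakly identifiable."
    warn(msg, class = "cqrisk_data_warning")
    warnings <- c(warnings, msg)
  }

  subjects <- unique(pooled$subject_id[!is.na(pooled$subject_id)])
  S <- length(subjects)
  sub_idx <- match(pooled$subject_id, subjects)
  sub_idx[is.na(sub_idx)] <- S + 1L

  drug_free <- as.numeric(pooled$drug_free)
  logc <- ifelse(pooled$drug_free, 0, log10(pmax(pooled$conc_umol_L, 1e-12)))
  if (any(!pooled$drug_free & pooled$conc_umol_L <= 0)) {
    abort("Dosed rows must have strictly positive concentrations.",
          class = "cqrisk_domain_error")
  }

  jdata <- list(
    N = nrow(pooled), qrs = pooled$qrs_ms, logc = logc, df = drug_free,
    is1 = as.numeric(pooled$stratum == 1L), stratum = pooled$stratum,
    sub = sub_idx, S = max(S, 1L),
    p_emax_mu = priors$e_max[1], p_emax_tau = 1 / priors$e_max[2]^2,
    p_emin_mu = priors$e_min[1], p_emin_tau = 1 / priors$e_min[2]^2,
    p_e50_mu = priors$e50[1], p_e50_tau = 1 / priors$e50[2]^2,
    p_logk_mu = priors$log_k[1], p_logk_tau = 1 / priors$log_k[2]^2,
    p_bias_mu = priors$bias[1], p_bias_tau = 1 / priors$bias[2]^2,
    p_eps1_mu = priors$eps1[1], p_eps1_tau = 1 / priors$eps1[2]^2,
    p_eps2_mu = priors$eps2[1], p_eps2_tau = 1 / priors$eps2[2]^2,
    p_eps3_mu = priors$eps3[1], p_eps3_tau = 1 / priors$eps3[2]^2,
    p_hv_rate = priors$sigma_hv_rate
  )
  res <- run_jags(qrs_model_string, jdata,
                  monitors = c("Emax", "Emin", "E50", "k", "bias",
                               "eps1", "eps2", "eps3", "sigma_hv"),
                  chains = chains, iter = iter, burnin_frac = burnin_frac,
                  thin = thin, seed = seed, quiet = quiet)

  draws <- tibble::as_tibble(res$draws)
  names(draws) <- c(Emax = "e_max", Emin = "e_min", E50 = "e50", k = "k",
                    bias = "bias", eps1 = "eps1", eps2 = "eps2",
                    eps3 = "eps3", sigma_hv = "sigma_hv")[names(draws)]
  draws <- draws[c("e_max", "e_min", "e50", "k", "bias", "eps1", "eps2",
                   "eps3", "sigma_hv")]
  draws$.chain <- res$chain_id

  diagnostics <- res$diagnostics
  diagnostics$term <- dplyr::recode(diagnostics$term, Emax = "e_max",
                                    Emin = "e_min", E50 = "e50")
  converged <- check_convergence(diagnostics)
  if (!converged) warnings <- c(warnings, "R-hat above 1.05 for some parameters")

  structure(
    list(
      draws = draws, diagnostics = diagnostics,
      mcmc_config = list(chains = chains, iter = iter,
                         burnin_frac = burnin_frac, thin = thin,
                         seed = seed, backend = "jags"),
      converged = converged, warnings = warnings, priors = priors,
      n = nrow(pooled), n_subjects = S
    ),
    class = c("cq_qrs_fit", "cq_fit")
  )
}

#' @export
print.cq_qrs_fit <- function(x, ...) {
  cat(sprintf("<cq_qrs_fit: %d datapoints, %d volunteers, %d draws>\n",
              x$n, x$n_subjects, nrow(x$draws)))
  print(tidy(x))
  invisible(x)
}

#' QRS prolongation at a given concentration
#'
#' Per posterior draw, the increase of the Emax mean over the drug-free mean
#' (`emax_mean(conc) - e_min`), summarised across draws.
#'
#' @param fit A `cq_qrs_fit` (or a draws tibble with e_max, e_min, e50, k).
#' @param conc Whole-blood chloroquine concentration(s), umol/L (> 0).
#' @return A tibble with one row per concentration: `conc_umol_L`, `mean`,
#'   `median`, `conf_low`, `conf_high` (msec).
#' @export
qrs_prolongation_at <- function(fit, conc = 3) {
  if (any(conc <= 0)) {
    abort("`conc` must be strictly positive.", class = "cqrisk_domain_error")
  }
  draws <- if (inherits(fit, "cq_qrs_fit")) fit$draws else fit
  purrr::map_dfr(conc, function(cc) {
    delta <- emax_mean(cc, draws) - draws$e_min
    tibble::tibble(
      conc_umol_L = cc, mean = mean(delta), median = median(delta),
      conf_low = unname(quantile(delta, 0.025)),
      conf_high = unname(quantile(delta, 0.975))
    )
  })
}
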