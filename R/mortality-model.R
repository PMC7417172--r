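#' Priors for the concentration-fatality model
#'
#' Informative priors: the intercept alpha is Normal(-15, 1) on the logit
#' scale (roughly a 3e-7 death probability at 1 umol/L); the log-concentration
#' slope beta is Normal(4, 1); the latent-peak shift delta has an Exponential
#' prior with rate 8, matching the log-scale peak-vs-admission gaps observed
#' in patients whose concentrations peaked in hospital; the metabolite
#' correction gamma is Normal(0.7, 0.065) truncated to (0, 1); and the three
#' cohort intercept offsets are Normal(0, 0.5).
#'
#' @param alpha_mean,alpha_sd,beta_mean,beta_sd,gamma_mean,gamma_sd,delta_rate,cohort_sd
#'   Prior hyperparameters; all scales must be positive.
#' @return An object of class `cq_mortality_priors`.
#' @export
mortality_priors <- function(alpha_mean = -15, alpha_sd = 1,
                             beta_mean = 4, beta_sd = 1,
                             gamma_mean = 0.7, gamma_sd = 0.065,
                             delta_rate = 8, cohort_sd = 0.5) {
  p <- list(alpha_mean = alpha_mean, alpha_sd = alpha_sd,
            beta_mean = beta_mean, beta_sd = beta_sd,
            gamma_mean = gamma_mean, gamma_sd = gamma_sd,
            delta_rate = delta_rate, cohort_sd = cohort_sd)
  if (any(unlist(p[c("alpha_sd", "beta_sd", "gamma_sd", "delta_rate",
                     "cohort_sd")]) <= 0)) {
    stop_invalid("All prior scale parameters must be positive.")
  }
  structure(p, class = "cq_mortality_priors")
}

# Concentration entering the linear predictor for each record: the observed
# peak when it was measured after admission, otherwise the admission value
# (whose log is shifted by +delta inside the model).
mortality_design <- function(data) {
  need <- c("admission_conc", "peak_observed", "died", "cohort")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    stop_bad_arg(paste0("Data is missing column(s): ",
                        paste(miss, collapse = ", ")))
  }
  if (!all(data$cohort %in% 1:3)) {
    stop_invalid("Unknown cohort label; cohorts must be 1, 2 or 3.")
  }
  obs <- as.logical(data$peak_observed) & !is.na(data$peak_conc %||% NA)
  x <- ifelse(obs, data$peak_conc, data$admission_conc)
  if (any(is.na(x)) || any(x <= 0)) {
    abort("All concentrations entering the model must be positive.",
          class = "cqrisk_domain_error")
  }
  list(logx = log(x), shift = as.numeric(!obs),
       cohort = as.integer(data$cohort), died = as.integer(data$died))
}

#' Log-likelihood of the concentration-fatality model
#'
#' Sum over patients of the Bernoulli log-mass of the observed outcome, with
#' logit-scale death probability
#' `alpha + beta * log(gamma * x) + a_cohort` when the peak concentration
#' `x` was observed, and
#' `alpha + beta * (log(gamma * x) + delta) + a_cohort` when only the
#' admission concentration is available.
#'
#' @param data Poisoning-cohort tibble (see [simulate_poisoning_cohort()]).
#' @param params Named list with `alpha`, `beta`, `gamma` (in (0,1)),
#'   `delta` (>= 0) and `a_cohort` (numeric length 3).
#' @return A single finite log-probability.
#' @export
#' @examples
#' cohort <- simulate_poisoning_cohort(generator_config(), 20)
#' mortality_loglik(cohort, list(alpha = -15, beta = 4, gamma = 0.7,
#'                               delta = 0.125, a_cohort = c(0, 0, 0)))
mortality_loglik <- function(data, params) {
  if (!(params$gamma > 0 && params$gamma <= 1)) {
    abort("`gamma` must lie in (0, 1] (1 disables the metabolite correction).",
          class = "cqrisk_domain_error")
  }
  if (params$delta < 0) {
    abort("`delta` must be >= 0.", class = "cqrisk_domain_error")
  }
  a <- params$a_cohort %||% c(0, 0, 0)
  d <- mortality_design(data)
  lp <- params$alpha +
    params$beta * (log(params$gamma) + d$logx + params$delta * d$shift) +
    a[d$cohort]
  # log Bernoulli mass, numerically stable via plogis on the log scale
  sum(ifelse(d$died == 1L, plogis(lp, log.p = TRUE),
             plogis(-lp, log.p = TRUE)))
}

mortality_model_string <- function(cohort_effects) {
  a_block <- if (cohort_effects) {
    "for (k in 1:3) { a[k] ~ dnorm(0, pc_tau) }"
  } else {
    "for (k in 1:3) { a[k] <- 0 }\n  pc_dummy ~ dnorm(0, pc_tau)"
  }
  paste0("model {
  for (i in 1:N) {
    logit(p[i]) <- alpha + beta * (lg + logx[i] + delta * shift[i]) + a[cohort[i]]
    died[i] ~ dbern(p[i])
  }
  lg <- log(gamma)
  alpha ~ dnorm(pa_mu, pa_tau)
  beta ~ dnorm(pb_mu, pb_tau)
  gamma ~ dnorm(pg_mu, pg_tau) T(1e-4, 0.9999)
  delta ~ dexp(pd_rate)
  ", a_block, "
}")
}

#' Fit the Bayesian concentration-fatality model
#'
#' Samples the joint posterior of (alpha, beta, gamma, delta, cohort
#' intercepts) by MCMC (JAGS backend). The default configuration is the
#' reduced one used throughout the package's tests and pipeline (4 chains of
#' 2000 iterations, first half discarded, no thinning: 4000 retained draws);
#' the full configuration used for final inference is 8 chains of 1e5
#' iterations, half burn-in, thinning every 100 (also 4000 retained draws).
#'
#' @param data Poisoning-cohort tibble; must contain at least one death and
#'   one survivor, otherwise the fit proceeds on the priors with a warning.
#' @param priors A [mortality_priors()] object.
#' @param chains,iter,burnin_frac,thin MCMC configuration.
#' @param seed Integer seed driving all chains.
#' @param cohort_effects If `FALSE` the cohort offsets are fixed at 0
#'   (useful for single-stratum data and for validation against a plain
#'   logistic model).
#' @param quiet Suppress JAGS progress output.
#'
#' @return An object of class `cq_mortality_fit` with elements `draws`
#'   (tibble: alpha, beta, gamma, delta, a1, a2, a3, .chain), `diagnostics`
#'   (per-parameter R-hat and effective sample size), `mcmc_config`,
#'   `converged`, `warnings`, `priors`, `n`, `n_deaths`.
#' @export
fit_mortality <- function(data, priors = mortality_priors(), chains = 4,
                          iter = 2000, burnin_frac = 0.5, thin = 1,
                          seed = 1L, cohort_effects = TRUE, quiet = TRUE) {
  stopifnot(inherits(priors, "cq_mortality_priors"))
  if (nrow(data) == 0) stop_bad_arg("Empty cohort.")
  d <- mortality_design(data)

  warnings <- character(0)
  if (all(d$died == 1L) || all(d$died == 0L)) {
    msg <- "Outcome is constant (no deaths or no survivors): the slope is informed almost entirely by its prior."
    warn(msg, class = "cqrisk_data_warning")
    warnings <- c(warnings, msg)
  }

  jdata <- list(
    N = length(d$died), died = d$died, logx = d$logx, shift = d$shift,
    cohort = d$cohort,
    pa_mu = priors$alpha_mean, pa_tau = 1 / priors$alpha_sd^2,
    pb_mu = priors$beta_mean, pb_tau = 1 / priors$beta_sd^2,
    pg_mu = priors$gamma_mean, pg_tau = 1 / priors$gamma_sd^2,
    pd_rate = priors$delta_rate, pc_tau = 1 / priors$cohort_sd^2
  )
  res <- run_jags(mortality_model_string(cohort_effects), jdata,
                  monitors = c("alpha", "beta", "gamma", "delta", "a"),
                  chains = chains, iter = iter, burnin_frac = burnin_frac,
                  thin = thin, seed = seed, quiet = quiet)

  draws <- tibble::as_tibble(res$draws)
  names(draws) <- sub("^a\\[(\\d)\\]$", "a\\1", names(draws))
  draws <- draws[c("alpha", "beta", "gamma", "delta", "a1", "a2", "a3")]
  draws$.chain <- res$chain_id

  diagnostics <- res$diagnostics
  diagnostics$term <- sub("^a\\[(\\d)\\]$", "a\\1", diagnostics$term)
  if (!cohort_effects) {
    diagnostics <- diagnostics[!grepl("^a\\d$", diagnostics$term), ]
  }
  converged <- check_convergence(diagnostics)
  if (!converged) warnings <- c(warnings, "R-hat above 1.05 for some parameters")

  structure(
    list(
      draws = draws,
      diagnostics = diagnostics,
      mcmc_config = list(chains = chains, iter = iter,
                         burnin_frac = burnin_frac, thin = thin, seed = seed,
                         cohort_effects = cohort_effects, backend = "jags"),
      converged = converged,
      warnings = warnings,
      priors = priors,
      n = length(d$died),
      n_deaths = sum(d$died)
    ),
    class = c("cq_mortality_fit", "cq_fit")
  )
}

#' @export
print.cq_mortality_fit <- function(x, ...) {
  cat(sprintf("<cq_mortality_fit: %d patients (%d deaths), %d draws>\n",
              x$n, x$n_deaths, nrow(x$draws)))
  print(tidy(x))
  invisible(x)
}

#' Concentration associated with a given mortality probability
#'
#' Inverts the population-level logistic curve (cohort offset 0) per
#' posterior draw: the peak whole-blood parent-drug concentration at which
#' predicted mortality equals `p` is `exp((logit(p) - alpha) / beta)`.
#' Draws with non-positive slope cannot be inverted and are excluded with a
#' warning.
#'
#' @param x A `cq_mortality_fit`, a tibble of draws with columns `alpha` and
#'   `beta`, or a named list with `alpha` and `beta`.
#' @param p Mortality probability in (0, 1); default 0.01, the lowest
#'   mortality reliably estimable from a few hundred patients.
#' @return A one-row tibble with `p`, `mean`, `median`, `conf_low`,
#'   `conf_high` (central 95%), `n_draws`, `n_excluded`; the draw-wise
#'   thresholds are in `attr(, "thresholds")`.
#' @export
concentration_at_mortality <- function(x, p = 0.01) {
  if (!is.numeric(p) || length(p) != 1 || is.na(p) || p <= 0 || p >= 1) {
    stop_bad_arg("`p` must be a single probability strictly inside (0, 1).")
  }
  draws <- as_param_draws(x)
  ok <- draws$beta > 0
  if (any(!ok)) {
    warn(sprintf("%d draw(s) with beta <= 0 excluded from threshold inversion.",
                 sum(!ok)), class = "cqrisk_inversion_warning")
  }
  if (!any(ok)) stop_bad_arg("No draws with positive slope to invert.")
  thr <- exp((qlogis(p) - draws$alpha[ok]) / draws$beta[ok])
  out <- tibble::tibble(
    p = p,
    mean = mean(thr),
    median = median(thr),
    conf_low = unname(quantile(thr, 0.025)),
    conf_high = unname(quantile(thr, 0.975)),
    n_draws = sum(ok),
    n_excluded = sum(!ok)
  )
  attr(out, "thresholds") <- thr
  out
}

as_param_draws <- function(x) {
  if (inherits(x, "cq_mortality_fit")) return(x$draws)
  if (is.data.frame(x)) {
    if (!all(c("alpha", "beta") %in% names(x))) {
      stop_bad_arg("Draws need columns `alpha` and `beta`.")
    }
    return(x)
  }
  if (is.list(x) && all(c("alpha", "beta") %in% names(x))) {
    return(tibble::tibble(alpha = x$alpha, beta = x$beta))
  }
  stop_bad_arg("Cannot interpret `x` as mortality parameters or draws.")
}

#' Posterior concentration-response curve
#'
#' Summarises, over posterior draws, the population-level probability of
#' death `logit^-1(alpha + beta * log(c))` on a grid of peak whole-blood
#' parent-drug concentrations (cohort offset 0).
#'
#' @param x A `cq_mortality_fit` or draws tibble.
#' @param conc_grid Positive concentrations (umol/L).
#' @return A tibble with `conc_umol_L`, `p_mean`, `p_median`, `conf_low`,
#'   `conf_high`.
#' @export
mortality_curve <- function(x, conc_grid = exp(seq(log(1), log(100),
                                                   length.out = 100))) {
  if (any(conc_grid <= 0)) stop_bad_arg("Concentration grid must be positive.")
  draws <- as_param_draws(x)
  purrr::map_dfr(conc_grid, function(cc) {
    pr <- plogis(draws$alpha + draws$beta * log(cc))
    tibble::tibble(
      conc_umol_L = cc, p_mean = mean(pr), p_median = median(pr),
      conf_low = unname(quantile(pr, 0.025)),
      conf_high = unname(quantile(pr, 0.975))
    )
  })
}

#' Maximum-likelihood exponential rate of the peak-admission log gap
#'
#' For patients with an observed admission concentration and a later
#' (in-hospital) peak, the log-scale gaps `log(peak) - log(admission)` are
#' modelled as exponential; the MLE of the rate is the reciprocal of the
#' mean gap. This is how the rate of the delta prior is obtained from data.
#'
#' @param paired Tibble with columns `admission_conc` and `peak_conc`
#'   (rows with a missing peak are dropped; if a `peak_observed` column is
#'   present only observed-peak rows are used).
#' @return A one-row tibble with `rate`, `mean_log_gap`, `n_pairs`.
#' @export
delta_prior_rate <- function(paired) {
  if (!all(c("admission_conc", "peak_conc") %in% names(paired))) {
    stop_bad_arg("`paired` needs columns admission_conc and peak_conc.")
  }
  if ("peak_observed" %in% names(paired)) {
    paired <- paired[as.logical(paired$peak_observed) %in% TRUE, ]
  }
  paired <- paired[!is.na(paired$peak_conc) & !is.na(paired$admission_conc), ]
  if (nrow(paired) == 0) stop_bad_arg("No admission/peak pairs supplied.")
  if (any(paired$peak_conc < paired$admission_conc)) {
    stop_invalid("Found peak_conc < admission_conc: peaks must be at least the admission value.")
  }
  gaps <- log(paired$peak_conc) - log(paired$admission_conc)
  m <- mean(gaps)
  tibble::tibble(rate = 1 / m, mean_log_gap = m, n_pairs = length(gaps))
}

#' Adjusted logistic regression of death on QRS duration
#'
#' Maximum-likelihood logistic regression of the survival outcome on QRS
#' duration (per 10 msec), adjusted for log admission concentration.
#' Complete separation is detected and flagged rather than crashing.
#'
#' @param data Poisoning tibble with `died`, `qrs_ms`, `admission_conc`.
#' @return A one-row tibble with `or_per_10ms`, `conf_low`, `conf_high`
#'   (Wald 95%), `p_value`, `n`, `n_deaths`, `separation`.
#' @export
qrs_death_logistic <- function(data) {
  d <- data[!is.na(data$qrs_ms) & !is.na(data$admission_conc) &
              !is.na(data$died), ]
  if (nrow(d) == 0 || length(unique(d$died)) < 2) {
    stop_bad_arg("Need QRS data with at least one death and one survivor.")
  }
  separation <- FALSE
  fit <- withCallingHandlers(
    glm(died ~ I(qrs_ms / 10) + log(admission_conc), family = binomial(),
        data = d),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
          grepl("did not converge", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  est <- coef(fit)[["I(qrs_ms/10)"]]
  se <- sqrt(vcov(fit)["I(qrs_ms/10)", "I(qrs_ms/10)"])
  tibble::tibble(
    or_per_10ms = exp(est),
    conf_low = exp(est - 1.96 * se),
    conf_high = exp(est + 1.96 * se),
    p_value = 2 * pnorm(-abs(est / se)),
    n = nrow(d),
    n_deaths = sum(d$died),
    separation = separation
  )
}
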