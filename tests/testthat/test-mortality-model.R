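test_that("the log-likelihood matches direct arithmetic on the toy cohort", {
  toy <- toy_cohort()
  params <- prior_mean_params()
  # independent oracle: the three Bernoulli terms written out by hand
  lp1 <- -15 + 4 * log(0.7 * 5)            # observed peak, survivor
  lp2 <- -15 + 4 * (log(0.7 * 20) + 0.125) # unobserved peak, death
  lp3 <- -15 + 4 * log(0.7 * 50)           # observed peak, death
  oracle <- log(1 - plogis(lp1)) + log(plogis(lp2)) + log(plogis(lp3))
  expect_equal(mortality_loglik(toy, params), oracle, tolerance = 1e-12)
})

test_that("a zero slope reduces to constant per-cohort Bernoulli mass", {
  toy <- toy_cohort()
  params <- prior_mean_params()
  params$beta <- 0
  params$alpha <- qlogis(0.3)
  params$a_cohort <- c(0.5, -0.2, 0)
  p <- plogis(params$alpha + params$a_cohort[toy$cohort])
  oracle <- sum(dbinom(toy$died, 1, p, log = TRUE))
  expect_equal(mortality_loglik(toy, params), oracle, tolerance = 1e-12)
})

test_that("disabling both corrections gives a plain logistic log-likelihood", {
  toy <- toy_cohort()
  params <- list(alpha = -14, beta = 3.5, gamma = 1, delta = 0,
                 a_cohort = c(0, 0, 0))
  x <- ifelse(toy$peak_observed, toy$peak_conc, toy$admission_conc)
  oracle <- sum(dbinom(toy$died, 1, plogis(-14 + 3.5 * log(x)), log = TRUE))
  expect_equal(mortality_loglik(toy, params), oracle, tolerance = 1e-12)
})

test_that("the likelihood is equivariant under rescaling concentrations", {
  coh <- simulate_poisoning_cohort(generator_config(), 80, seed = 17)
  params <- prior_mean_params()
  k <- 3.7
  coh2 <- dplyr::mutate(coh, admission_conc = k * admission_conc,
                        peak_conc = k * peak_conc)
  params2 <- params
  params2$alpha <- params$alpha - params$beta * log(k)
  expect_equal(mortality_loglik(coh2, params2), mortality_loglik(coh, params),
               tolerance = 1e-10)
})

test_that("domain and validation errors are raised for bad inputs", {
  toy <- toy_cohort()
  # record B has an unobserved peak, so its admission value enters the model
  bad <- dplyr::mutate(toy, admission_conc = c(5, -20, 45))
  expect_error(mortality_loglik(bad, prior_mean_params()),
               class = "cqrisk_domain_error")
  bad2 <- dplyr::mutate(toy, cohort = c(1L, 4L, 3L))
  expect_error(mortality_loglik(bad2, prior_mean_params()),
               class = "cqrisk_validation_error")
  p <- prior_mean_params()
  p$gamma <- 1.2
  expect_error(mortality_loglik(toy, p), class = "cqrisk_domain_error")
})

test_that("threshold inversion satisfies its closed forms and monotonicity", {
  one <- concentration_at_mortality(list(alpha = qlogis(0.01), beta = 2.3),
                                    p = 0.01)
  expect_equal(one$mean, 1.0, tolerance = 1e-12)
  pm <- concentration_at_mortality(list(alpha = -15, beta = 4), p = 0.01)
  expect_equal(pm$mean, exp((qlogis(0.01) + 15) / 4), tolerance = 1e-12)
  p5 <- concentration_at_mortality(list(alpha = -15, beta = 4), p = 0.05)
  expect_gt(p5$mean, pm$mean)
  expect_error(concentration_at_mortality(list(alpha = -15, beta = 4), p = 1),
               class = "cqrisk_argument_error")
})

test_that("draws with non-positive slope are excluded with a warning", {
  draws <- tibble::tibble(alpha = c(-15, -15, -15), beta = c(4, -1, 5))
  expect_warning(res <- concentration_at_mortality(draws, 0.01),
                 class = "cqrisk_inversion_warning")
  expect_equal(res$n_draws, 2)
  expect_equal(res$n_excluded, 1)
})

test_that("the mortality curve is consistent with threshold inversion and monotone", {
  draw <- single_draw_posterior()
  thr <- concentration_at_mortality(draw, 0.01)$mean
  curve <- mortality_curve(draw, conc_grid = thr)
  expect_equal(curve$p_mean, 0.01, tolerance = 1e-12)

  post <- fake_posterior()
  curve <- mortality_curve(post, conc_grid = c(2, 5, 10, 20, 50))
  expect_true(all(diff(curve$p_mean) > 0))
  # scalar oracle at the prior means
  expect_equal(mortality_curve(draw, 30)$p_mean, plogis(-15 + 4 * log(30)),
               tolerance = 1e-12)
  expect_error(mortality_curve(post, c(-1, 3)), class = "cqrisk_argument_error")
})

test_that("the exponential-rate estimator matches its closed form and is consistent", {
  const <- tibble::tibble(admission_conc = exp(log(10) - 0.125),
                          peak_conc = 10)
  expect_equal(delta_prior_rate(const)$rate, 8, tolerance = 1e-12)

  set.seed(99)
  n <- 10000
  peak <- rlnorm(n, 2.9, 0.8)
  gaps <- rexp(n, rate = 20)
  pairs <- tibble::tibble(admission_conc = peak * exp(-gaps), peak_conc = peak)
  est <- delta_prior_rate(pairs)
  se <- 20 / sqrt(n)  # asymptotic SE of the exponential-rate MLE
  expect_lt(abs(est$rate - 20), 3 * se)

  expect_error(delta_prior_rate(tibble::tibble(admission_conc = numeric(0),
                                               peak_conc = numeric(0))),
               class = "cqrisk_argument_error")
  expect_error(delta_prior_rate(tibble::tibble(admission_conc = 10,
                                               peak_conc = 9)),
               class = "cqrisk_validation_error")
})

test_that("an all-survivor cohort warns and leaves the slope at its prior", {
  # nobody dies, and a small low-exposure cohort keeps the likelihood
  # nearly flat in the slope
  cfg <- generator_config(alpha_true = -40, conc_log_mu = 2.0)
  coh <- simulate_poisoning_cohort(cfg, 15, seed = 23)
  expect_equal(sum(coh$died), 0)
  expect_warning(
    fit <- suppressWarnings(
      fit_mortality(coh, chains = 2, iter = 1500, seed = 1),
      classes = "cqrisk_convergence_warning"
    ),
    class = "cqrisk_data_warning"
  )
  beta <- fit$draws$beta
  # without any deaths the slope posterior stays prior-like: wide, and its
  # central 95% interval overlapping most of the Normal(4, 1) prior mass
  expect_gt(sd(beta), 0.5)
  post_ci <- quantile(beta, c(0.025, 0.975))
  prior_ci <- qnorm(c(0.025, 0.975), 4, 1)
  overlap <- min(post_ci[2], prior_ci[2]) - max(post_ci[1], prior_ci[1])
  expect_gt(overlap / diff(prior_ci), 0.5)
})

test_that("short mortality fits are reproducible given the seed", {
  coh <- simulate_poisoning_cohort(generator_config(), 120, seed = 41)
  f1 <- quiet_fit_mortality(coh, chains = 2, iter = 600, seed = 9)
  f2 <- quiet_fit_mortality(coh, chains = 2, iter = 600, seed = 9)
  expect_identical(f1$draws, f2$draws)
})

test_that("QRS-death logistic recovers a null effect and flags separation", {
  set.seed(77)
  n <- 800
  x <- rlnorm(n, 2.9, 0.85)
  died <- rbinom(n, 1, plogis(-15 + 4 * log(0.7 * x)))
  null_data <- tibble::tibble(admission_conc = x,
                              qrs_ms = rnorm(n, 110, 20), died = died)
  res <- qrs_death_logistic(null_data)
  expect_false(res$separation)
  expect_true(res$conf_low < 1 && res$conf_high > 1)

  sep <- tibble::tibble(
    admission_conc = rep(10, 20),
    qrs_ms = c(seq(80, 99, length.out = 10), seq(150, 170, length.out = 10)),
    died = rep(c(0L, 1L), each = 10)
  )
  expect_true(qrs_death_logistic(sep)$separation)
  expect_error(qrs_death_logistic(dplyr::mutate(sep, died = 0L)),
               class = "cqrisk_argument_error")
})
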