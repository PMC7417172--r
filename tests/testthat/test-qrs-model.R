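test_that("the Emax mean satisfies its midpoint, asymptote and monotonicity identities", {
  p <- prior_mean_qrs_params()
  expect_equal(emax_mean(10^p$e50, p), (p$e_max + p$e_min) / 2,
               tolerance = 1e-12)
  expect_equal(emax_mean(1e12, p), p$e_max, tolerance = 1e-6)
  expect_equal(emax_mean(1e-12, p), p$e_min, tolerance = 1e-6)
  grid <- emax_mean(c(0.5, 1, 3, 10, 30, 100), p)
  expect_true(all(diff(grid) > 0))
  expect_true(all(grid > p$e_min & grid < p$e_max))
  # closed-form value at 3 umol/L, worked out independently
  oracle <- 180 - 90 / (1 + exp(exp(1) * (log10(3) - 1.3)))
  expect_equal(emax_mean(3, p), oracle, tolerance = 1e-12)
  expect_equal(oracle, 98.69, tolerance = 1e-3)
  expect_error(emax_mean(0, p), class = "cqrisk_domain_error")
})

test_that("harmonisation applies the matrix conversions and strata", {
  vol <- tibble::tibble(subject_id = "HV01", occasion = 3L,
                        plasma_conc = 2.5, qrs_ms = 100)
  poi <- tibble::tibble(patient_id = c("P1", "P2"), cohort = c(2L, 3L),
                        admission_conc = c(20, 30), peak_conc = NA_real_,
                        peak_observed = FALSE, qrs_ms = c(130, 125),
                        died = c(0L, 0L))
  pooled <- harmonize_concentrations(vol, poi)
  expect_equal(pooled$conc_umol_L, c(10, 14, 21))
  expect_equal(pooled$stratum, c(3L, 1L, 2L))
  expect_equal(pooled$drug_free, c(FALSE, FALSE, FALSE))
})

test_that("16 volunteers plus 290 QRS-measured patients give 514 datapoints", {
  cfg <- generator_config()
  vol <- simulate_volunteer_study(cfg, 16, seed = 51)
  coh <- simulate_poisoning_cohort(cfg, 600, seed = 52)
  with_qrs <- which(!is.na(coh$qrs_ms))
  coh$qrs_ms[with_qrs[-seq_len(290)]] <- NA  # keep exactly 290 QRS rows
  pooled <- harmonize_concentrations(vol, coh)
  expect_equal(nrow(pooled), 514)
  expect_equal(sum(pooled$drug_free), 32)
})

qrs_recovery_fit <- local({
  cfg <- generator_config()
  # modest between-subject spread keeps e_min cleanly identified from the
  # 32 drug-free rows in a single-seed recovery check
  cfg$qrs_params_true$sigma_hv <- 1
  vol <- simulate_volunteer_study(cfg, 16, seed = 61)
  coh <- simulate_poisoning_cohort(cfg, 400, seed = 62)
  pooled <- harmonize_concentrations(vol, coh)
  list(cfg = cfg, pooled = pooled,
       fit = quiet_fit_qrs(pooled, chains = 2, iter = 3000, seed = 63))
})

test_that("the fitted concentration-effect function recovers the generating curve", {
  # (e_max, e50, k) sit on a posterior ridge, so the robust check is on the
  # identified object: the mean QRS curve over the observed range, plus the
  # well-identified drug-free mean and reading bias
  truth <- qrs_recovery_fit$cfg$qrs_params_true
  fit <- qrs_recovery_fit$fit
  grid <- exp(seq(log(1), log(40), length.out = 40))
  truth_curve <- emax_mean(grid, truth)
  post_curve <- vapply(grid, function(cc) mean(emax_mean(cc, fit$draws)),
                       numeric(1))
  expect_lt(max(abs(post_curve - truth_curve)), 5)

  expect_lt(abs(mean(fit$draws$e_min) - truth$e_min), 2.5)
  td <- tidy(fit)
  bias <- td[td$term == "bias", ]
  expect_gte(truth$bias_cohort2, bias$conf.low)
  expect_lte(truth$bias_cohort2, bias$conf.high)
})

test_that("stratum error SDs are recovered in the right order", {
  draws <- qrs_recovery_fit$fit$draws
  # generated with eps1 = 25 > eps2 = 15 > eps3 = 2
  expect_gt(mean(draws$eps1), mean(draws$eps2))
  expect_gt(mean(draws$eps2), mean(draws$eps3))
})

test_that("the fitted mean curve is monotone for every retained draw", {
  draws <- qrs_recovery_fit$fit$draws
  expect_true(all(draws$k > 0))
  lo <- emax_mean(1, draws)
  hi <- emax_mean(30, draws)
  expect_true(all(hi > lo))
})

test_that("prolongation at 3 umol/L follows the closed form and limits", {
  p <- prior_mean_qrs_params()
  draw <- tibble::tibble(e_max = p$e_max, e_min = p$e_min, e50 = p$e50,
                         k = p$k)
  res <- qrs_prolongation_at(draw, 3)
  expect_equal(res$mean, emax_mean(3, p) - p$e_min, tolerance = 1e-12)
  expect_equal(res$mean, 8.69, tolerance = 1e-2)
  expect_equal(qrs_prolongation_at(draw, 10^p$e50)$mean,
               (p$e_max - p$e_min) / 2, tolerance = 1e-12)
  expect_lt(qrs_prolongation_at(draw, 1e-9)$mean, 1e-6)
  expect_error(qrs_prolongation_at(draw, -3), class = "cqrisk_domain_error")
})

test_that("a null reading bias is recovered as covering zero", {
  cfg <- generator_config()
  cfg$qrs_params_true$bias_cohort2 <- 0
  vol <- simulate_volunteer_study(cfg, 10, seed = 71)
  coh <- simulate_poisoning_cohort(cfg, 250, seed = 72)
  fit <- quiet_fit_qrs(harmonize_concentrations(vol, coh),
                       chains = 2, iter = 2500, seed = 73)
  td <- tidy(fit)
  bias <- td[td$term == "bias", ]
  expect_gte(0, bias$conf.low)
  expect_lte(0, bias$conf.high)
})

test_that("shifting stratum-1 observations and the bias prior together is an exact reparameterisation", {
  pooled <- qrs_recovery_fit$pooled
  shift <- 12
  shifted <- dplyr::mutate(
    pooled, qrs_ms = qrs_ms + ifelse(stratum == 1L, shift, 0)
  )
  f0 <- qrs_recovery_fit$fit
  f1 <- quiet_fit_qrs(shifted, priors = qrs_priors(bias = c(-20 + shift, 5)),
                      chains = 2, iter = 3000, seed = 63)
  expect_equal(f1$draws$bias, f0$draws$bias + shift, tolerance = 1e-8)
  for (term in c("e_max", "e_min", "e50", "k", "eps1", "eps2", "eps3")) {
    expect_equal(f1$draws[[term]], f0$draws[[term]], tolerance = 1e-8)
  }
})

test_that("a single-stratum table triggers the identifiability warning", {
  pooled <- qrs_recovery_fit$pooled
  only1 <- pooled[pooled$stratum == 1L, ]
  expect_warning(
    suppressWarnings(fit_qrs(only1, chains = 2, iter = 400, seed = 5),
                     classes = "cqrisk_convergence_warning"),
    class = "cqrisk_data_warning"
  )
})
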