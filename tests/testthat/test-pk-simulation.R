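wb_params <- pk_model_parameters("whole_blood_2cpt")
pl_params <- pk_model_parameters("plasma_3cpt")

test_that("allometric scaling applies the fixed exponents exactly", {
  same <- allometric_scale(wb_params, wb_params$ref_weight_kg)
  expect_equal(unlist(same$theta), unlist(wb_params$theta))

  half <- allometric_scale(wb_params, wb_params$ref_weight_kg / 2)
  expect_equal(half$theta$CL, wb_params$theta$CL * 0.5^0.75)
  expect_equal(half$theta$Q, wb_params$theta$Q * 0.5^0.75)
  expect_equal(half$theta$VC, wb_params$theta$VC * 0.5)
  expect_equal(half$theta$VP, wb_params$theta$VP * 0.5)
  expect_equal(half$theta$MTT, wb_params$theta$MTT)
  expect_equal(half$theta$F, wb_params$theta$F)

  expect_error(allometric_scale(wb_params, 0), class = "cqrisk_argument_error")
  expect_error(allometric_scale(half, 70), class = "cqrisk_argument_error")
})

test_that("plasma to whole blood conversion is elementwise x4", {
  expect_equal(plasma_to_whole_blood(0), 0)
  expect_equal(plasma_to_whole_blood(2.5), 10)
  expect_equal(plasma_to_whole_blood(c(1, 2, 3)), c(4, 8, 12))
  expect_error(plasma_to_whole_blood(-1), class = "cqrisk_argument_error")
})

test_that("zero doses give an all-zero profile and dosing must lie on the grid", {
  reg0 <- tibble::tibble(time_h = c(0, 12), dose_mg_base = c(0, 0))
  prof <- simulate_profile(wb_params, reg0)
  expect_true(all(prof$conc_umol_L == 0))
  expect_error(
    simulate_profile(wb_params, build_regimen("malaria_3d"), t_end = 10),
    class = "cqrisk_argument_error"
  )
  expect_error(
    simulate_profile(wb_params, tibble::tibble(time_h = 0.1234,
                                               dose_mg_base = 100)),
    class = "cqrisk_argument_error"
  )
})

test_that("kinetics are linear: doubling every dose doubles every concentration", {
  reg <- build_regimen("malaria_3d")
  reg2 <- dplyr::mutate(reg, dose_mg_base = 2 * dose_mg_base)
  p1 <- simulate_profile(wb_params, reg)
  p2 <- simulate_profile(wb_params, reg2)
  expect_equal(p2$conc_umol_L, 2 * p1$conc_umol_L, tolerance = 1e-12)
})

test_that("multi-dose profiles superpose time-shifted single-dose profiles", {
  reg <- build_regimen("malaria_3d")
  t_end <- max(reg$time_h) + 7
  multi <- simulate_profile(wb_params, reg, t_end = t_end)
  super <- rep(0, nrow(multi))
  for (i in seq_len(nrow(reg))) {
    single <- simulate_profile(
      wb_params,
      tibble::tibble(time_h = 0, dose_mg_base = reg$dose_mg_base[i]),
      t_end = t_end
    )
    shift <- as.integer(round(reg$time_h[i] / 0.25))
    contrib <- c(rep(0, shift), single$conc_umol_L)[seq_len(nrow(multi))]
    super <- super + contrib
  }
  expect_equal(multi$conc_umol_L, super, tolerance = 1e-9)
})

test_that("the analytic profile matches an independent stiff-ODE integration", {
  skip_if_not_installed("deSolve")
  for (params in list(wb_params, pl_params)) {
    th <- unlist(params$theta)
    ntr <- params$n_transit
    ktr <- (ntr + 1) / th[["MTT"]]
    three <- params$model_id == "plasma_3cpt"
    rhs <- function(t, y, p) {
      dy <- numeric(length(y))
      dy[1] <- -ktr * y[1]
      if (ntr > 1) for (j in 2:ntr) dy[j] <- ktr * (y[j - 1] - y[j])
      ic <- ntr + 1
      if (three) {
        dy[ic] <- ktr * y[ntr] - (th[["CL"]] + th[["Q1"]] + th[["Q2"]]) /
          th[["VC"]] * y[ic] + th[["Q1"]] / th[["VP1"]] * y[ic + 1] +
          th[["Q2"]] / th[["VP2"]] * y[ic + 2]
        dy[ic + 1] <- th[["Q1"]] / th[["VC"]] * y[ic] -
          th[["Q1"]] / th[["VP1"]] * y[ic + 1]
        dy[ic + 2] <- th[["Q2"]] / th[["VC"]] * y[ic] -
          th[["Q2"]] / th[["VP2"]] * y[ic + 2]
      } else {
        dy[ic] <- ktr * y[ntr] - (th[["CL"]] + th[["Q"]]) / th[["VC"]] * y[ic] +
          th[["Q"]] / th[["VP"]] * y[ic + 1]
        dy[ic + 1] <- th[["Q"]] / th[["VC"]] * y[ic] -
          th[["Q"]] / th[["VP"]] * y[ic + 1]
      }
      list(dy)
    }
    y0 <- numeric(ntr + if (three) 3 else 2)
    y0[1] <- 620 * 1000 / 319.87 * th[["F"]]
    times <- seq(0, 24, by = 0.25)
    ode <- deSolve::lsoda(y0, times, rhs, parms = NULL,
                          rtol = 1e-10, atol = 1e-12)
    oracle <- ode[, ntr + 2] / th[["VC"]]

    mine <- simulate_profile(params,
                             tibble::tibble(time_h = 0, dose_mg_base = 620),
                             t_end = 24)
    rel <- abs(mine$conc_umol_L[-1] - oracle[-1]) / pmax(oracle[-1], 1e-12)
    expect_lt(max(rel), 1e-6)
  }
})

test_that("halving the grid step changes C_max by less than 0.5 percent", {
  reg <- build_regimen("solidarity_10d")
  c1 <- max(simulate_profile(wb_params, reg, dt = 0.25)$conc_umol_L)
  c2 <- max(simulate_profile(wb_params, reg, dt = 0.125)$conc_umol_L)
  expect_lt(abs(c1 - c2) / c2, 0.005)
})

test_that("population C_max simulation is seed-reproducible and collapses without variability", {
  a <- simulate_cmax_population(wb_params, "malaria_3d", 70, n = 25, seed = 4)
  b <- simulate_cmax_population(wb_params, "malaria_3d", 70, n = 25, seed = 4)
  expect_identical(a, b)
  c <- simulate_cmax_population(wb_params, "malaria_3d", 70, n = 25, seed = 5)
  expect_false(identical(a$cmax_umol_L, c$cmax_umol_L))

  nov <- wb_params
  nov$omega[] <- 0
  s <- simulate_cmax_population(nov, "malaria_3d", 70, n = 20, seed = 1)
  expect_equal(max(s$cmax_umol_L), min(s$cmax_umol_L))
  expect_error(simulate_cmax_population(wb_params, "malaria_3d", 70, n = 0),
               class = "cqrisk_argument_error")
})

test_that("typical C_max under flat dosing strictly decreases with body weight", {
  nov <- wb_params
  nov$omega[] <- 0
  cm <- vapply(c(40, 65, 90), function(w) {
    simulate_cmax_population(nov, "brazil_600bid_10d", w, n = 1,
                             seed = 1)$cmax_umol_L
  }, numeric(1))
  expect_true(all(diff(cm) < 0))
})

test_that("plasma-model peaks convert to whole blood and agree in the median while spreading less", {
  wb <- simulate_cmax_population(wb_params, "brazil_600bid_10d", 70, n = 400,
                                 seed = 31)
  pl <- simulate_cmax_population(pl_params, "brazil_600bid_10d", 70, n = 400,
                                 seed = 32)
  expect_lt(abs(log(median(wb$cmax_umol_L) / median(pl$cmax_umol_L))), 0.1)
  expect_gt(sd(log(wb$cmax_umol_L)), sd(log(pl$cmax_umol_L)))
})

test_that("mismatched eta names are rejected", {
  expect_error(
    simulate_profile(wb_params, build_regimen("malaria_3d"),
                     etas = c(nonsense = 0.1)),
    class = "cqrisk_argument_error"
  )
})
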