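#' Simulate one concentration-time profile
#'
#' Solves the linear compartmental system (transit-compartment absorption
#' chain feeding a two- or three-compartment disposition model) exactly on a
#' uniform time grid: a single matrix exponential of `A * dt` propagates the
#' state between grid points, with oral doses entering the first transit
#' compartment as boluses. Kinetics are linear, so multi-dose profiles equal
#' the superposition of time-shifted single-dose profiles and concentrations
#' scale proportionally with dose.
#'
#' @param params A [pk_model_parameters()] object (scaled to the weight of
#'   interest if allometry is wanted).
#' @param regimen Dosing-event tibble with columns `time_h` and
#'   `dose_mg_base` (e.g. from [build_regimen()]); dose times must lie on
#'   the grid.
#' @param etas Optional named numeric vector of individual log-scale random
#'   effects; each named parameter is multiplied by `exp(eta)`. Names must
#'   be a subset of `names(params$omega)`.
#' @param dt Grid resolution in hours (default 0.25 h).
#' @param t_end End of the simulation grid in hours; defaults to 7 h after
#'   the last dose, which captures the peak.
#'
#' @return A tibble with columns `time_h` and `conc_umol_L` (umol/L in the
#'   model's own matrix: whole blood or plasma).
#' @export
#' @examples
#' p <- pk_model_parameters("whole_blood_2cpt")
#' prof <- simulate_profile(p, build_regimen("malaria_3d"))
#' max(prof$conc_umol_L)
simulate_profile <- function(params, regimen, etas = NULL, dt = 0.25,
                             t_end = NULL) {
  stopifnot(inherits(params, "cq_pk_params"))
  if (!all(c("time_h", "dose_mg_base") %in% names(regimen))) {
    stop_bad_arg("`regimen` needs columns time_h and dose_mg_base.")
  }
  t_last <- if (nrow(regimen) > 0) max(regimen$time_h) else 0
  t_end <- t_end %||% (t_last + 7)
  if (t_end < t_last) {
    stop_bad_arg("Simulation grid must cover the dosing span.")
  }

  theta <- apply_etas(params, etas)
  A <- build_system_matrix(theta, params$n_transit, params$model_id)
  if (any(!is.finite(A))) {
    abort("Non-finite rate constant after applying etas.",
          class = "cqrisk_numerical_error")
  }

  n_steps <- as.integer(round(t_end / dt))
  steps <- regimen$time_h / dt
  if (any(abs(steps - round(steps)) > 1e-8)) {
    stop_bad_arg("All dose times must be multiples of the grid step `dt`.")
  }
  ord <- order(regimen$time_h)
  dose_step <- as.integer(round(steps))[ord]
  dose_amt <- (mg_base_to_umol(regimen$dose_mg_base) * theta[["F"]])[ord]

  central <- params$n_transit  # 0-based index of central compartment
  amt <- pk_step_profile(A, dt, n_steps, dose_step, dose_amt, central)
  tibble::tibble(
    time_h = seq(0, by = dt, length.out = n_steps + 1),
    conc_umol_L = as.numeric(amt) / theta[["VC"]]
  )
}

apply_etas <- function(params, etas) {
  theta <- unlist(params$theta)
  if (!is.null(etas) && length(etas) > 0) {
    if (is.null(names(etas)) || !all(names(etas) %in% names(params$omega))) {
      stop_bad_arg("`etas` must be named and match names(params$omega).")
    }
    theta[names(etas)] <- theta[names(etas)] * exp(unname(etas))
  }
  if (any(!is.finite(theta)) || any(theta <= 0)) {
    abort("Non-finite or non-positive parameter after applying etas.",
          class = "cqrisk_numerical_error")
  }
  theta
}

# Transit compartments 1..n feed forward at ktr = (n + 1) / MTT; the last
# transit empties into the central compartment at the same rate. Disposition
# is the standard 2- or 3-compartment mammillary model.
build_system_matrix <- function(theta, n_transit, model_id) {
  ktr <- (n_transit + 1) / theta[["MTT"]]
  three <- model_id == "plasma_3cpt" || "Q2" %in% names(theta)
  ncomp <- if (three) 3L else 2L
  d <- n_transit + ncomp
  A <- matrix(0, d, d)
  for (j in seq_len(n_transit)) {
    A[j, j] <- -ktr
    if (j > 1) A[j, j - 1] <- ktr
  }
  ic <- n_transit + 1L
  A[ic, n_transit] <- ktr
  if (three) {
    k10 <- theta[["CL"]] / theta[["VC"]]
    k12 <- theta[["Q1"]] / theta[["VC"]]
    k21 <- theta[["Q1"]] / theta[["VP1"]]
    k13 <- theta[["Q2"]] / theta[["VC"]]
    k31 <- theta[["Q2"]] / theta[["VP2"]]
    A[ic, ic] <- -(k10 + k12 + k13)
    A[ic, ic + 1] <- k21
    A[ic, ic + 2] <- k31
    A[ic + 1, ic] <- k12
    A[ic + 1, ic + 1] <- -k21
    A[ic + 2, ic] <- k13
    A[ic + 2, ic + 2] <- -k31
  } else {
    k10 <- theta[["CL"]] / theta[["VC"]]
    k12 <- theta[["Q"]] / theta[["VC"]]
    k21 <- theta[["Q"]] / theta[["VP"]]
    A[ic, ic] <- -(k10 + k12)
    A[ic, ic + 1] <- k21
    A[ic + 1, ic] <- k12
    A[ic + 1, ic + 1] <- -k21
  }
  A
}

#' Draw individual log-normal random effects
#'
#' @param params A [pk_model_parameters()] object.
#' @param n Number of individuals.
#' @return An `n x length(omega)` matrix of normal draws with SDs
#'   `params$omega`, one named column per varying parameter.
#' @export
draw_etas <- function(params, n) {
  stopifnot(inherits(params, "cq_pk_params"), n >= 0)
  om <- params$omega
  m <- matrix(rnorm(n * length(om), 0, rep(om, each = n)), nrow = n,
              dimnames = list(NULL, names(om)))
  m
}

#' Simulate a population of peak concentrations for one regimen
#'
#' Draws `n` individuals with log-normal between-subject variability,
#' simulates each concentration-time profile from first dose to 7 h after
#' the last dose, and records the peak (C_max) on the grid. Plasma-model
#' peaks are converted to whole blood (x 4) before return, so C_max is
#' always a whole-blood chloroquine concentration.
#'
#' @param params Unscaled [pk_model_parameters()] object.
#' @param regimen_id A regimen id (see [regimen_ids()]) or a dosing tibble.
#' @param weight_kg Body weight (kg); applied via [allometric_scale()] and
#'   used by weight-based regimens.
#' @param n Number of simulated individuals (>= 1).
#' @param seed RNG seed; results are reproducible given the seed.
#' @param dt Grid resolution (h).
#'
#' @return A tibble of class `cq_cmax_sample` with columns `individual_id`
#'   and `cmax_umol_L`, and attributes `regimen_id`, `model_id`,
#'   `weight_kg`, `n` and `seed`.
#' @export
simulate_cmax_population <- function(params, regimen_id, weight_kg = 70,
                                     n = 1000, seed = 1L, dt = 0.25) {
  stopifnot(inherits(params, "cq_pk_params"))
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 1) {
    stop_bad_arg("`n` must be a single integer >= 1.")
  }
  n <- as.integer(n)
  regimen <- if (is.character(regimen_id)) {
    build_regimen(regimen_id, weight_kg)
  } else {
    regimen_id
  }
  scaled <- allometric_scale(params, weight_kg)
  if (!is.null(seed)) set.seed(seed)
  etas <- draw_etas(params, n)
  cmax <- vapply(seq_len(n), function(i) {
    prof <- simulate_profile(scaled, regimen, etas = etas[i, ], dt = dt)
    max(prof$conc_umol_L)
  }, numeric(1))
  if (params$matrix == "plasma") cmax <- plasma_to_whole_blood(cmax)

  out <- tibble::tibble(
    individual_id = seq_len(n),
    cmax_umol_L = cmax
  )
  attr(out, "regimen_id") <- attr(regimen, "regimen_id") %||% "custom"
  attr(out, "model_id") <- params$model_id
  attr(out, "weight_kg") <- weight_kg
  attr(out, "n") <- n
  attr(out, "seed") <- seed
  class(out) <- c("cq_cmax_sample", class(out))
  out
}
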