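#' Truncated death probability for a simulated peak concentration
#'
#' Evaluates the population-level logistic death probability
#' `logit^-1(alpha + beta * log(cmax))` for one posterior draw (cohort
#' offset 0; `cmax` is parent-drug whole-blood concentration so no
#' metabolite correction applies) and truncates it at the floor: predicted
#' probabilities below the floor are set to 0, because mortality below 1%
#' cannot be estimated reliably from a few hundred patients.
#'
#' @param cmax Peak whole-blood concentration(s), umol/L (> 0).
#' @param draw Named list or one-row data frame with `alpha` and `beta`.
#' @param floor Truncation probability in (0, 1); default 0.01.
#' @return Probability vector: `p` where `p >= floor`, else 0.
#' @export
truncated_death_prob <- function(cmax, draw, floor = 0.01) {
  if (any(!is.finite(cmax)) || any(cmax <= 0)) {
    abort("`cmax` must be strictly positive.", class = "cqrisk_domain_error")
  }
  if (floor <= 0 || floor >= 1) {
    stop_bad_arg("`floor` must lie strictly inside (0, 1).")
  }
  p <- plogis(draw$alpha + draw$beta * log(cmax))
  # tiny relative slack so a C_max sitting exactly on the draw's threshold
  # concentration is kept despite floating-point round-off
  ifelse(p >= floor * (1 - 1e-9), p, 0)
}

# Draw-by-individual matrix of truncated probabilities, individuals in rows.
truncated_prob_matrix <- function(cmax, alpha, beta, floor) {
  lp <- outer(log(cmax), beta) + rep(alpha, each = length(cmax))
  p <- plogis(lp)
  p[p < floor * (1 - 1e-9)] <- 0
  p
}

#' Expected fatality ratio for a simulated population
#'
#' For each posterior draw, the mean over simulated individuals of the
#' truncated death probability at their C_max; reported per 1000 with the
#' posterior mean and central 95% interval over draws. PK Monte-Carlo and
#' pharmacodynamic posterior uncertainty are propagated by nesting: every
#' individual is evaluated under every draw.
#'
#' @param cmax_sample A [simulate_cmax_population()] tibble (or any tibble
#'   with a `cmax_umol_L` column).
#' @param posterior A `cq_mortality_fit` or draws tibble.
#' @param floor Truncation probability (default 0.01).
#' @param n_draws Optional cap on the number of posterior draws used
#'   (evenly thinned); default uses all.
#' @return A one-row tibble with `fatality_per1000_mean`,
#'   `fatality_per1000_lo`, `fatality_per1000_hi`, `floor`, `n_pk`,
#'   `n_draws`; draw-wise means (per 1000) in `attr(, "draws")`.
#' @export
expected_fatality_ratio <- function(cmax_sample, posterior, floor = 0.01,
                                    n_draws = NULL) {
  cmax <- cmax_sample$cmax_umol_L
  if (length(cmax) == 0) stop_bad_arg("Empty C_max sample.")
  draws <- as_param_draws(posterior)
  if (nrow(draws) == 0) stop_bad_arg("Empty posterior.")
  draws <- thin_draws(draws, n_draws)
  m <- colMeans(truncated_prob_matrix(cmax, draws$alpha, draws$beta, floor))
  out <- tibble::tibble(
    fatality_per1000_mean = 1000 * mean(m),
    fatality_per1000_lo = 1000 * unname(quantile(m, 0.025)),
    fatality_per1000_hi = 1000 * unname(quantile(m, 0.975)),
    floor = floor,
    n_pk = length(cmax),
    n_draws = nrow(draws)
  )
  attr(out, "draws") <- 1000 * m
  out
}

thin_draws <- function(draws, n_draws) {
  if (is.null(n_draws) || n_draws >= nrow(draws)) return(draws)
  draws[round(seq(1, nrow(draws), length.out = n_draws)), ]
}

#' Probability of exceeding the mortality threshold or a fixed cutoff
#'
#' Draw mode (posterior supplied): per posterior draw, the empirical
#' fraction of simulated C_max values above that draw's own
#' `floor`-mortality threshold concentration, summarised over draws. Fixed
#' mode (`cutoff` supplied): the single empirical fraction of C_max values
#' above the cutoff, e.g. the 10 umol/L "danger zone".
#'
#' @inheritParams expected_fatality_ratio
#' @param posterior A `cq_mortality_fit` / draws tibble, or `NULL` when
#'   using `cutoff`.
#' @param cutoff Fixed whole-blood concentration cutoff (umol/L, > 0).
#' @param floor Mortality probability defining the draw-wise threshold.
#' @return A one-row tibble with `p_exceed_mean`, `p_exceed_lo`,
#'   `p_exceed_hi` (degenerate in fixed mode), `mode`, `n_pk`, `n_draws`.
#' @export
prob_exceed_threshold <- function(cmax_sample, posterior = NULL,
                                  cutoff = NULL, floor = 0.01,
                                  n_draws = NULL) {
  cmax <- cmax_sample$cmax_umol_L
  if (length(cmax) == 0) stop_bad_arg("Empty C_max sample.")
  if (is.null(posterior) && is.null(cutoff)) {
    stop_bad_arg("Supply either a posterior (draw mode) or a fixed cutoff.")
  }
  if (!is.null(cutoff)) {
    if (cutoff <= 0) stop_bad_arg("`cutoff` must be positive.")
    frac <- mean(cmax > cutoff)
    return(tibble::tibble(
      p_exceed_mean = frac, p_exceed_lo = frac, p_exceed_hi = frac,
      mode = "fixed_cutoff", n_pk = length(cmax), n_draws = NA_integer_
    ))
  }
  draws <- thin_draws(as_param_draws(posterior), n_draws)
  ok <- draws$beta > 0
  draws <- draws[ok, ]
  thr <- exp((qlogis(floor) - draws$alpha) / draws$beta)
  frac <- vapply(thr, function(th) mean(cmax > th), numeric(1))
  tibble::tibble(
    p_exceed_mean = mean(frac),
    p_exceed_lo = unname(quantile(frac, 0.025)),
    p_exceed_hi = unname(quantile(frac, 0.975)),
    mode = "posterior_threshold",
    n_pk = length(cmax),
    n_draws = nrow(draws)
  )
}

#' Weight-by-regimen risk projection table
#'
#' Crosses PK models, regimens and body weights; for each cell simulates a
#' C_max population and reports the probability of crossing the
#' `floor`-mortality threshold (posterior mean and 95% interval), the
#' truncated expected fatality per 1000, and the fraction of individuals
#' above the fixed 10 umol/L danger-zone cutoff.
#'
#' @param pk_params A `cq_pk_params` object or (named) list of them.
#' @param posterior A `cq_mortality_fit` or draws tibble.
#' @param regimens Character vector of regimen ids.
#' @param weights_kg Body-weight grid (default 40-90 kg in 5 kg steps).
#' @param n Simulated individuals per cell (default 1000).
#' @param seed Base seed; each cell uses a distinct derived seed.
#' @param floor Truncation probability.
#' @param danger_cutoff Fixed cutoff for the danger-zone fraction (umol/L).
#' @param n_draws Optional cap on posterior draws per cell.
#' @return A tibble of class `cq_risk_table`, one row per
#'   (model, regimen, weight) with the summaries above plus `n_pk`,
#'   `n_draws` and the cell seed.
#' @export
weight_risk_table <- function(pk_params, posterior,
                              regimens = regimen_ids(),
                              weights_kg = seq(40, 90, by = 5),
                              n = 1000, seed = 1L, floor = 0.01,
                              danger_cutoff = 10, n_draws = NULL) {
  if (inherits(pk_params, "cq_pk_params")) pk_params <- list(pk_params)
  if (!all(vapply(pk_params, inherits, logical(1), "cq_pk_params"))) {
    abort("`pk_params` must be cq_pk_params objects (check the parameter file for each model).",
          class = "cqrisk_config_error")
  }
  grid <- tidyr::expand_grid(
    model_idx = seq_along(pk_params),
    regimen_id = regimens,
    weight_kg = weights_kg
  )
  out <- purrr::pmap_dfr(grid, function(model_idx, regimen_id, weight_kg) {
    params <- pk_params[[model_idx]]
    cell_seed <- (seed + 7919L * model_idx +
                    101L * match(regimen_id, regimens) +
                    as.integer(weight_kg)) %% .Machine$integer.max
    cmax <- simulate_cmax_population(params, regimen_id, weight_kg, n = n,
                                     seed = cell_seed)
    exceed <- prob_exceed_threshold(cmax, posterior, floor = floor,
                                    n_draws = n_draws)
    fatal <- expected_fatality_ratio(cmax, posterior, floor = floor,
                                     n_draws = n_draws)
    tibble::tibble(
      regimen_id = regimen_id,
      model_id = params$model_id,
      weight_kg = weight_kg,
      p_exceed_mean = exceed$p_exceed_mean,
      p_exceed_lo = exceed$p_exceed_lo,
      p_exceed_hi = exceed$p_exceed_hi,
      fatality_per1000_mean = fatal$fatality_per1000_mean,
      fatality_per1000_lo = fatal$fatality_per1000_lo,
      fatality_per1000_hi = fatal$fatality_per1000_hi,
      frac_above_10umol = mean(cmax$cmax_umol_L > danger_cutoff),
      n_pk = n,
      n_draws = fatal$n_draws,
      seed = cell_seed
    )
  })
  class(out) <- c("cq_risk_table", class(out))
  out
}
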