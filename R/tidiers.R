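#' Tidy posterior summaries of a fitted model
#'
#' One row per model parameter: posterior mean, median, central 95%
#' credible interval, and the convergence diagnostics (split-chain R-hat,
#' effective sample size).
#'
#' @param x A `cq_mortality_fit` or `cq_qrs_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate` (posterior mean),
#'   `median`, `conf.low`, `conf.high`, `rhat`, `ess`.
#' @export
tidy.cq_fit <- function(x, ...) {
  params <- setdiff(names(x$draws), ".chain")
  sums <- purrr::map_dfr(params, function(p) {
    v <- x$draws[[p]]
    tibble::tibble(
      term = p, estimate = mean(v), median = median(v),
      conf.low = unname(quantile(v, 0.025)),
      conf.high = unname(quantile(v, 0.975))
    )
  })
  dplyr::left_join(sums, x$diagnostics, by = "term")
}

#' One-row fit summary
#'
#' @param x A `cq_mortality_fit` or `cq_qrs_fit`.
#' @param ... Unused.
#' @return A tibble with `n_obs`, `n_draws`, `chains`, `max_rhat`,
#'   `min_ess`, `converged`.
#' @export
glance.cq_fit <- function(x, ...) {
  tibble::tibble(
    n_obs = x$n,
    n_draws = nrow(x$draws),
    chains = x$mcmc_config$chains,
    max_rhat = suppressWarnings(max(x$diagnostics$rhat, na.rm = TRUE)),
    min_ess = suppressWarnings(min(x$diagnostics$ess, na.rm = TRUE)),
    converged = x$converged
  )
}
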