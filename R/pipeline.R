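#' Configuration for the full analysis pipeline
#'
#' @param data_dir Optional directory containing `poisoning.csv` and
#'   `volunteers.csv`; when `NULL` the synthetic generator is used.
#' @param generator A [generator_config()] used when no data are supplied.
#' @param n_patients,n_volunteers Synthetic cohort sizes (defaults: the
#'   302-patient / 16-volunteer study sizes).
#' @param pk_params_path Path to the PK parameter YAML (default: packaged
#'   synthetic set).
#' @param pk_models PK model ids to simulate.
#' @param regimens,weights_kg,n_pk Risk-projection grid.
#' @param mcmc List with `chains`, `iter`, `burnin_frac`, `thin`.
#' @param seed Base seed for every stochastic stage.
#' @return A validated list of class `cq_pipeline_config`.
#' @export
pipeline_config <- function(data_dir = NULL,
                            generator = generator_config(),
                            n_patients = 302, n_volunteers = 16,
                            pk_params_path = NULL,
                            pk_models = c("whole_blood_2cpt", "plasma_3cpt"),
                            regimens = regimen_ids(),
                            weights_kg = seq(40, 90, by = 5),
                            n_pk = 1000,
                            mcmc = list(chains = 4, iter = 2000,
                                        burnin_frac = 0.5, thin = 1),
                            seed = 1L) {
  pk_params_path <- pk_params_path %||%
    system.file("extdata", "pk_parameters_synthetic.yaml", package = "cqrisk")
  if (!file.exists(pk_params_path)) {
    abort(paste0("PK parameter file not found: '", pk_params_path, "'"),
          class = "cqrisk_config_error")
  }
  if (!is.null(data_dir)) {
    for (f in c("poisoning.csv", "volunteers.csv")) {
      if (!file.exists(file.path(data_dir, f))) {
        abort(paste0("Data file not found: '", file.path(data_dir, f), "'"),
              class = "cqrisk_config_error")
      }
    }
  }
  structure(
    list(data_dir = data_dir, generator = generator,
         n_patients = n_patients, n_volunteers = n_volunteers,
         pk_params_path = pk_params_path, pk_models = pk_models,
         regimens = regimens, weights_kg = weights_kg, n_pk = n_pk,
         mcmc = mcmc, seed = as.integer(seed)),
    class = "cq_pipeline_config"
  )
}

#' Run the full concentration-toxicity pipeline
#'
#' Executes the stages in order: obtain data (read or simulate), fit the
#' concentration-fatality model, fit the QRS Emax model, simulate C_max
#' populations and build the weight-by-regimen risk table. Writes posterior
#' draw CSVs, diagnostics JSON, the risk table CSV and a plain-text summary
#' (threshold with credible interval, QRS prolongation at 3 umol/L,
#' per-regimen fatality) to `out_dir`; every artifact is stamped with the
#' configuration hash and base seed. Stage failures abort with the stage
#' name; convergence warnings are recorded in the summary, never swallowed.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, a list with `poisoning`, `volunteers`,
#'   `mortality_fit`, `qrs_fit`, `threshold`, `qrs_prolongation`,
#'   `risk_table`, `config_hash`.
#' @export
run_full_pipeline <- function(config = pipeline_config(), out_dir,
                              quiet = FALSE) {
  stopifnot(inherits(config, "cq_pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_hash <- rlang::hash(config)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("Pipeline stage '", name, "' failed: ",
                   conditionMessage(e)), class = "cqrisk_pipeline_error")
    })
  }

  # -- data ------------------------------------------------------------------
  if (is.null(config$data_dir)) {
    say("stage data: simulating %d patients, %d volunteers",
        config$n_patients, config$n_volunteers)
    poisoning <- stage("data", simulate_poisoning_cohort(
      config$generator, config$n_patients, seed = config$seed))
    volunteers <- stage("data", simulate_volunteer_study(
      config$generator, config$n_volunteers, seed = config$seed + 1L))
    write_poisoning_csv(poisoning, file.path(out_dir, "poisoning.csv"))
    write_volunteer_csv(volunteers, file.path(out_dir, "volunteers.csv"))
  } else {
    say("stage data: reading from %s", config$data_dir)
    poisoning <- stage("data", read_poisoning_csv(
      file.path(config$data_dir, "poisoning.csv")))
    volunteers <- stage("data", read_volunteer_csv(
      file.path(config$data_dir, "volunteers.csv")))
  }

  mc <- config$mcmc
  # -- mortality fit ---------------------------------------------------------
  say("stage fit-mortality: %d chains x %d iterations", mc$chains, mc$iter)
  mort <- stage("fit-mortality", fit_mortality(
    poisoning, chains = mc$chains, iter = mc$iter,
    burnin_frac = mc$burnin_frac, thin = mc$thin, seed = config$seed + 2L))
  readr::write_csv(mort$draws, file.path(out_dir, "mortality_draws.csv"))
  write_diag_json(mort, file.path(out_dir, "mortality_diagnostics.json"),
                  cfg_hash, config$seed)
  threshold <- concentration_at_mortality(mort, p = 0.01)

  # -- qrs fit ---------------------------------------------------------------
  say("stage fit-qrs")
  pooled <- stage("fit-qrs", harmonize_concentrations(volunteers, poisoning))
  qrs <- stage("fit-qrs", fit_qrs(
    pooled, chains = mc$chains, iter = mc$iter,
    burnin_frac = mc$burnin_frac, thin = mc$thin, seed = config$seed + 3L))
  readr::write_csv(qrs$draws, file.path(out_dir, "qrs_draws.csv"))
  write_diag_json(qrs, file.path(out_dir, "qrs_diagnostics.json"),
                  cfg_hash, config$seed)
  prolong <- qrs_prolongation_at(qrs, 3)

  # -- pk + risk -------------------------------------------------------------
  say("stage project-risk: %d regimens x %d weights x %d models",
      length(config$regimens), length(config$weights_kg),
      length(config$pk_models))
  pk_list <- stage("project-risk", lapply(
    config$pk_models, pk_model_parameters, path = config$pk_params_path))
  risk <- stage("project-risk", weight_risk_table(
    pk_list, mort, regimens = config$regimens,
    weights_kg = config$weights_kg, n = config$n_pk,
    seed = config$seed + 4L))
  readr::write_csv(tibble::as_tibble(risk),
                   file.path(out_dir, "risk_table.csv"))

  # -- summary ---------------------------------------------------------------
  summary_lines <- c(
    "Chloroquine concentration-toxicity pipeline summary",
    sprintf("config_hash: %s  seed: %d", cfg_hash, config$seed),
    sprintf("patients: %d (%d deaths); volunteers: %d rows",
            nrow(poisoning), sum(poisoning$died), nrow(volunteers)),
    sprintf("1%% mortality threshold: %.1f umol/L (95%% CI %.1f-%.1f)",
            threshold$median, threshold$conf_low, threshold$conf_high),
    sprintf("QRS prolongation at 3 umol/L: %.1f msec (95%% CI %.1f-%.1f)",
            prolong$mean, prolong$conf_low, prolong$conf_high),
    "warnings:",
    paste0("  mortality: ", paste(c(mort$warnings, "none")[1],
                                  collapse = "; ")),
    paste0("  qrs: ", paste(c(qrs$warnings, "none")[1], collapse = "; ")),
    "",
    "expected fatality per 1000 (truncated at 1%), by regimen (70 kg):"
  )
  at70 <- risk[risk$weight_kg == 70 & risk$model_id == risk$model_id[1], ]
  summary_lines <- c(summary_lines, sprintf(
    "  %-20s %6.2f (%.2f-%.2f)", at70$regimen_id,
    at70$fatality_per1000_mean, at70$fatality_per1000_lo,
    at70$fatality_per1000_hi))
  writeLines(summary_lines, file.path(out_dir, "summary.txt"))

  invisible(list(
    poisoning = poisoning, volunteers = volunteers, mortality_fit = mort,
    qrs_fit = qrs, threshold = threshold, qrs_prolongation = prolong,
    risk_table = risk, config_hash = cfg_hash
  ))
}

write_diag_json <- function(fit, path, cfg_hash, seed) {
  jsonlite::write_json(
    list(
      config_hash = cfg_hash, seed = seed,
      mcmc_config = fit$mcmc_config,
      converged = fit$converged,
      warnings = fit$warnings,
      diagnostics = fit$diagnostics
    ),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
}
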