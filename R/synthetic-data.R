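#' Simulate a synthetic chloroquine self-poisoning cohort
#'
#' Draws one row per patient with the generative structure the
#' concentration-fatality model assumes: the measured peak whole-blood
#' chloroquine + desethyl-metabolite concentration is log-normal; the
#' admission concentration sits below the peak by a per-patient exponential
#' gap on the log scale (mean `delta_true`); death is Bernoulli with logit
#' probability `alpha + beta * log(gamma * peak) + a_cohort`; QRS durations
#' (cohorts 2 and 3 only, as in the source series) follow the sigmoid Emax
#' mean at the parent-drug concentration `gamma * peak` plus stratum noise,
#' with the additive reading bias applied to cohort 2.
#'
#' @param cfg A [generator_config()] object.
#' @param n Number of patients (>= 0).
#' @param seed RNG seed; defaults to `cfg$seed`. Output is reproducible
#'   given the seed.
#'
#' @return A tibble with columns `patient_id`, `cohort` (integer 1-3),
#'   `admission_conc`, `peak_conc` (umol/L; `NA` when the peak was not
#'   observed), `peak_observed` (logical), `qrs_ms` (msec, `NA` when not
#'   measured) and `died` (0/1).
#' @export
#' @examples
#' cohort <- simulate_poisoning_cohort(generator_config(), n = 100)
#' mean(cohort$died)
simulate_poisoning_cohort <- function(cfg, n, seed = cfg$seed) {
  cfg <- validate_generator_config(cfg)
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 0 ||
      n != floor(n)) {
    stop_bad_arg("`n` must be a single non-negative integer.")
  }
  n <- as.integer(n)
  if (n == 0L) return(empty_poisoning_tbl())
  if (!is.null(seed)) set.seed(seed)

  x_peak <- rlnorm(n, cfg$conc_log_mu, cfg$conc_log_sd)
  gap <- if (cfg$delta_true > 0) rexp(n, rate = 1 / cfg$delta_true) else
    rep(0, n)
  admission <- x_peak * exp(-gap)

  cohort <- sample.int(3L, n, replace = TRUE, prob = cfg$cohort_props)
  multi <- runif(n) < cfg$frac_multi_sampled
  peak_observed <- multi & (runif(n) < cfg$frac_peak_after_admission)

  lp <- cfg$alpha_true + cfg$beta_true * log(cfg$gamma_true * x_peak) +
    cfg$cohort_effects_true[cohort]
  died <- rbinom(n, 1L, inv_logit(lp))

  qp <- cfg$qrs_params_true
  qrs_mean <- emax_mean(cfg$gamma_true * x_peak, qp)
  qrs <- rep(NA_real_, n)
  i2 <- which(cohort == 2L)
  i3 <- which(cohort == 3L)
  qrs[i2] <- qrs_mean[i2] + qp$bias_cohort2 +
    rnorm(length(i2), 0, cfg$noise_sds[["cohort2"]])
  qrs[i3] <- qrs_mean[i3] + rnorm(length(i3), 0, cfg$noise_sds[["cohort3"]])

  tibble::tibble(
    patient_id = sprintf("P%04d", seq_len(n)),
    cohort = cohort,
    admission_conc = admission,
    peak_conc = ifelse(peak_observed, x_peak, NA_real_),
    peak_observed = peak_observed,
    qrs_ms = qrs,
    died = as.integer(died)
  )
}

empty_poisoning_tbl <- function() {
  tibble::tibble(
    patient_id = character(0), cohort = integer(0),
    admission_conc = double(0), peak_conc = double(0),
    peak_observed = logical(0), qrs_ms = double(0), died = integer(0)
  )
}

#' Simulate a synthetic healthy-volunteer concentration-QRS study
#'
#' Each subject contributes two drug-free QRS measurements (occasions 1 and
#' 2) and twelve QRS measurements paired with plasma chloroquine
#' concentrations sampled from an individual population-PK profile after a
#' single 620 mg base oral dose (occasion 3). QRS means follow the sigmoid
#' Emax model evaluated at the whole-blood equivalent (4 x plasma), shifted
#' by a subject-level intercept with SD `sigma_hv`, plus volunteer-stratum
#' measurement noise; drug-free rows are centred on the lower asymptote
#' `e_min` plus the subject intercept.
#'
#' @inheritParams simulate_poisoning_cohort
#' @param n_subjects Number of volunteers (>= 0).
#' @param pk_params Plasma PK parameter set used to simulate concentrations;
#'   defaults to the packaged synthetic plasma model.
#'
#' @return A tibble with columns `subject_id`, `occasion`, `plasma_conc`
#'   (umol/L, 0 for drug-free rows) and `qrs_ms`. 16 subjects give
#'   16 x (2 + 12) = 224 rows.
#' @export
simulate_volunteer_study <- function(cfg, n_subjects, seed = cfg$seed,
                                     pk_params = pk_model_parameters("plasma_3cpt")) {
  cfg <- validate_generator_config(cfg)
  if (!is.numeric(n_subjects) || length(n_subjects) != 1 ||
      is.na(n_subjects) || n_subjects < 0 || n_subjects != floor(n_subjects)) {
    stop_bad_arg("`n_subjects` must be a single non-negative integer.")
  }
  n_subjects <- as.integer(n_subjects)
  if (n_subjects == 0L) {
    return(tibble::tibble(subject_id = character(0), occasion = integer(0),
                          plasma_conc = double(0), qrs_ms = double(0)))
  }
  if (!is.null(seed)) set.seed(seed)

  qp <- cfg$qrs_params_true
  eps_hv <- cfg$noise_sds[["volunteer"]]
  sample_times <- c(0.5, 1, 1.5, 2, 3, 4, 5, 6, 8, 12, 18, 24)
  regimen <- tibble::tibble(time_h = 0, dose_mg_base = 620)

  purrr::map_dfr(seq_len(n_subjects), function(s) {
    b_s <- rnorm(1, 0, qp$sigma_hv)
    qrs_free <- qp$e_min + b_s + rnorm(2, 0, eps_hv)

    etas <- draw_etas(pk_params, 1)[1, ]
    prof <- simulate_profile(pk_params, regimen, etas = etas,
                             t_end = max(sample_times))
    conc <- approx(prof$time_h, prof$conc_umol_L, xout = sample_times)$y
    conc <- pmax(conc, 1e-6)  # detectable by construction
    qrs_dosed <- emax_mean(WB_PLASMA_RATIO * conc, qp) + b_s +
      rnorm(length(conc), 0, eps_hv)

    tibble::tibble(
      subject_id = sprintf("HV%02d", s),
      occasion = c(1L, 2L, rep(3L, length(sample_times))),
      plasma_conc = c(0, 0, conc),
      qrs_ms = c(qrs_free, qrs_dosed)
    )
  })
}

#' @importFrom stats approx
NULL

# ---- CSV round-trip ---------------------------------------------------------

poisoning_cols <- function() {
  readr::cols(
    patient_id = readr::col_character(),
    cohort = readr::col_integer(),
    admission_conc = readr::col_double(),
    peak_conc = readr::col_double(),
    peak_observed = readr::col_logical(),
    qrs_ms = readr::col_double(),
    died = readr::col_integer()
  )
}

volunteer_cols <- function() {
  readr::cols(
    subject_id = readr::col_character(),
    occasion = readr::col_integer(),
    plasma_conc = readr::col_double(),
    qrs_ms = readr::col_double()
  )
}

#' Read and write the cohort CSV formats
#'
#' Plain UTF-8 comma-separated files with a header row and empty fields for
#' missing values. Poisoning columns: `patient_id, cohort, admission_conc,
#' peak_conc, peak_observed, qrs_ms, died`; volunteer columns: `subject_id,
#' occasion, plasma_conc, qrs_ms`. Reading validates the schema and cohort
#' labels and reports offending rows.
#'
#' @param records A tibble in the corresponding schema.
#' @param path File path.
#' @return The records tibble (invisibly for writers).
#' @name cohort_csv
NULL

#' @rdname cohort_csv
#' @export
write_poisoning_csv <- function(records, path) {
  records <- records[names(empty_poisoning_tbl())]
  readr::write_csv(records, path, na = "")
  invisible(records)
}

#' @rdname cohort_csv
#' @export
read_poisoning_csv <- function(path) {
  out <- readr::read_csv(path, col_types = poisoning_cols(), na = "",
                         progress = FALSE)
  check_parse_problems(out, path)
  bad <- which(!out$cohort %in% 1:3 | is.na(out$cohort))
  if (length(bad) > 0) {
    stop_invalid(paste0("Unknown cohort label in '", path, "' at row(s): ",
                        paste(utils::head(bad, 10), collapse = ", "),
                        " (must be 1, 2 or 3)."))
  }
  if (any(!is.na(out$admission_conc) & out$admission_conc <= 0)) {
    stop_invalid("Non-positive admission concentration in poisoning CSV.")
  }
  out
}

#' @rdname cohort_csv
#' @export
write_volunteer_csv <- function(records, path) {
  records <- records[c("subject_id", "occasion", "plasma_conc", "qrs_ms")]
  readr::write_csv(records, path, na = "")
  invisible(records)
}

#' @rdname cohort_csv
#' @export
read_volunteer_csv <- function(path) {
  out <- readr::read_csv(path, col_types = volunteer_cols(), na = "",
                         progress = FALSE)
  check_parse_problems(out, path)
  if (any(!is.na(out$plasma_conc) & out$plasma_conc < 0)) {
    stop_invalid("Negative plasma concentration in volunteer CSV.")
  }
  out
}

check_parse_problems <- function(tbl, path) {
  probs <- readr::problems(tbl)
  if (nrow(probs) > 0) {
    stop_invalid(paste0(
      "Malformed CSV '", path, "': parse failure at row(s) ",
      paste(utils::head(unique(probs$row), 10), collapse = ", "), "."
    ))
  }
  invisible(tbl)
}
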