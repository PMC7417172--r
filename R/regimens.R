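#' Dosing regimens for chloroquine simulation
#'
#' Builds the ordered dosing-event table for one of the six simulated adult
#' regimens. Four are "flat" (weight-independent): the Brazilian high-dose
#' trial regimen (600 mg base twice daily for 10 days, no loading dose); the
#' SOLIDARITY/RECOVERY regimen (620 mg base at 0 and 6 h, then 310 mg base
#' 12-hourly from 12 h for a total of ten days: 2 loading + 20 maintenance
#' doses); its 7-day adaptation (2 loading + 14 maintenance doses); and the
#' standard 3-day malaria regimen (620 mg on days 1 and 2, 310 mg on day 3,
#' taken 24-hourly). The two weight-based regimens target 10 mg base/kg
#' loading doses at 0 and 6 h and 5 mg/kg maintenance doses 12-hourly from
#' 12 h (10 or 7 days total), approximated to the nearest whole number of
#' 155 mg base tablets (ties rounded up).
#'
#' @param regimen_id One of `regimen_ids()`.
#' @param weight_kg Body weight in kg (> 0); used only by the weight-based
#'   regimens.
#'
#' @return A tibble with columns `time_h` and `dose_mg_base`, with
#'   attributes `regimen_id` and `weight_kg`.
#' @export
#' @examples
#' build_regimen("solidarity_10d", 70)
build_regimen <- function(regimen_id, weight_kg = 70) {
  if (!is.character(regimen_id) || length(regimen_id) != 1 ||
      !regimen_id %in% regimen_ids()) {
    stop_bad_arg(paste0("Unknown regimen_id; must be one of: ",
                        paste(regimen_ids(), collapse = ", ")))
  }
  if (!is.numeric(weight_kg) || length(weight_kg) != 1 ||
      is.na(weight_kg) || weight_kg <= 0) {
    stop_bad_arg("`weight_kg` must be a single positive number.")
  }

  events <- switch(
    regimen_id,
    brazil_600bid_10d = tibble::tibble(
      time_h = seq(0, by = 12, length.out = 20),
      dose_mg_base = 600
    ),
    solidarity_10d = loading_maintenance(620, 310, n_maintenance = 20),
    solidarity_7d = loading_maintenance(620, 310, n_maintenance = 14),
    weight_based_10d = loading_maintenance(
      round_to_tablets(10 * weight_kg), round_to_tablets(5 * weight_kg),
      n_maintenance = 20
    ),
    weight_based_7d = loading_maintenance(
      round_to_tablets(10 * weight_kg), round_to_tablets(5 * weight_kg),
      n_maintenance = 14
    ),
    malaria_3d = tibble::tibble(
      time_h = c(0, 24, 48),
      dose_mg_base = c(620, 620, 310)
    )
  )
  stopifnot(all(diff(events$time_h) > 0), all(events$dose_mg_base > 0))
  attr(events, "regimen_id") <- regimen_id
  attr(events, "weight_kg") <- weight_kg
  events
}

#' @rdname build_regimen
#' @export
regimen_ids <- function() {
  c("brazil_600bid_10d", "solidarity_10d", "solidarity_7d",
    "weight_based_10d", "weight_based_7d", "malaria_3d")
}

loading_maintenance <- function(loading_mg, maintenance_mg, n_maintenance) {
  tibble::tibble(
    time_h = c(0, 6, seq(12, by = 12, length.out = n_maintenance)),
    dose_mg_base = c(loading_mg, loading_mg,
                     rep(maintenance_mg, n_maintenance))
  )
}

#' Round a target dose to whole 155 mg base tablets
#'
#' Nearest whole tablet count, with exact half-tablet ties rounded up; the
#' result is at least one tablet.
#'
#' @param dose_mg_base Target dose in mg base.
#' @param tablet_mg Tablet strength in mg base (default 155).
#' @return Dose in mg base corresponding to a whole number of tablets.
#' @export
round_to_tablets <- function(dose_mg_base, tablet_mg = 155) {
  n <- floor(dose_mg_base / tablet_mg + 0.5)  # ties up
  pmax(n, 1) * tablet_mg
}
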