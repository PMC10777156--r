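# Molar gas constant, J mol^-1 K^-1
GAS_CONSTANT <- 8.314

#' Chamber and mesocosm geometry
#'
#' Geometry and ambient state of the closed-loop flux chamber. Defaults match
#' the measurement set-up: a transparent acrylic chamber (diameter 0.29 m,
#' height 0.30 m) sealed onto a mesocosm core of diameter 0.225 m, in a
#' climate room at 22 degrees C and standard pressure.
#'
#' The effective gas volume is the chamber cylinder only; loop tubing or
#' analyzer cell volume can be added through `extra_volume`.
#'
#' @param chamber_diameter,chamber_height Chamber cylinder dimensions, m.
#' @param collar_diameter Mesocosm (collar) diameter, m; the flux is
#'   normalised to this surface, where the moss exchanges CO2.
#' @param air_temperature Chamber air temperature, K.
#' @param pressure Air pressure, Pa.
#' @param extra_volume Additional loop volume, m^3 (default 0).
#' @return A list of class `"chamber_spec"` with the inputs plus derived
#'   `volume_m3` (cylinder + extra) and `area_m2` (collar cross-section).
#' @examples
#' chamber_spec()$volume_m3  # ~0.0198 m^3
#' @export
chamber_spec <- function(chamber_diameter = 0.29, chamber_height = 0.30,
                         collar_diameter = 0.225,
                         air_temperature = 295.15, pressure = 101325,
                         extra_volume = 0) {
  vals <- c(chamber_diameter, chamber_height, collar_diameter,
            air_temperature, pressure)
  if (any(!is.finite(vals)) || any(vals <= 0) || extra_volume < 0) {
    stop("chamber geometry and ambient state must be positive and finite",
         call. = FALSE)
  }
  if (collar_diameter > chamber_diameter) {
    stop("collar_diameter must not exceed chamber_diameter", call. = FALSE)
  }
  structure(list(
    chamber_diameter = chamber_diameter,
    chamber_height = chamber_height,
    collar_diameter = collar_diameter,
    air_temperature = air_temperature,
    pressure = pressure,
    extra_volume = extra_volume,
    volume_m3 = pi * (chamber_diameter / 2)^2 * chamber_height + extra_volume,
    area_m2 = pi * (collar_diameter / 2)^2
  ), class = "chamber_spec")
}

#' Concentration trace container
#'
#' One closed-chamber CO2 record: concentration (ppm = umol CO2 per mol air)
#' sampled at nominally 1 Hz over 120 s from chamber closure.
#'
#' @param time_s Seconds since chamber closure, strictly increasing.
#' @param co2_ppm CO2 mole fraction, ppm; finite and positive.
#' @param chamber A [chamber_spec()].
#' @param mesocosm_id,day Identifiers used to key batch output.
#' @return A list of class `"concentration_trace"`.
#' @export
concentration_trace <- function(time_s, co2_ppm, chamber = chamber_spec(),
                                mesocosm_id = NA_character_,
                                day = NA_integer_) {
  if (length(time_s) != length(co2_ppm)) {
    stop("time_s and co2_ppm must have equal length", call. = FALSE)
  }
  if (is.unsorted(time_s, strictly = TRUE)) {
    stop("time_s must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(co2_ppm)) || any(co2_ppm <= 0)) {
    stop("co2_ppm must be finite and positive", call. = FALSE)
  }
  stopifnot(inherits(chamber, "chamber_spec"))
  structure(list(time_s = as.numeric(time_s), co2_ppm = as.numeric(co2_ppm),
                 chamber = chamber, mesocosm_id = mesocosm_id,
                 day = day),
            class = "concentration_trace")
}

#' Fit the chamber concentration slope
#'
#' Ordinary least-squares line through the concentration trace after
#' discarding an initial dead band (closure artefacts); the slope is the
#' rate of CO2 accumulation (+) or depletion (-) in the chamber headspace.
#'
#' @param trace A [concentration_trace()].
#' @param dead_band_s Seconds discarded from the start of the record
#'   (default 30; points with `time_s >= dead_band_s` are retained).
#' @return List with `slope_ppm_per_s`, `intercept_ppm`, `r_squared` and
#'   `n_points_used`.
#' @export
fit_concentration_slope <- function(trace, dead_band_s = 30) {
  stopifnot(inherits(trace, "concentration_trace"))
  keep <- trace$time_s >= dead_band_s
  n <- sum(keep)
  if (n < 10) {
    stop(structure(class = c("peatstab_insufficient_data", "error",
                             "condition"),
                   list(message = sprintf(
                     "only %d points remain after the %g s dead band (>= 10 required)",
                     n, dead_band_s), call = NULL, n_points = n)))
  }
  t <- trace$time_s[keep]
  y <- trace$co2_ppm[keep]
  fit <- stats::lm(y ~ t)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot < 1e-15) 1 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  list(slope_ppm_per_s = unname(stats::coef(fit)[2]),
       intercept_ppm = unname(stats::coef(fit)[1]),
       r_squared = r2,
       n_points_used = n)
}

# umol m^-2 s^-1 of NEE per (ppm s^-1) of headspace slope, for a chamber.
# n = PV/RT mol of chamber air; 1 ppm = 1 umol CO2 per mol air, so a slope of
# s ppm/s is s*n umol/s over the collar area. The ecological sign convention
# flips the sign: a declining concentration (uptake) is positive NEE.
nee_per_ppm_slope <- function(chamber) {
  n_air <- chamber$pressure * chamber$volume_m3 /
    (GAS_CONSTANT * chamber$air_temperature)
  n_air / chamber$area_m2
}

#' Compute NEE from a chamber concentration trace
#'
#' Fits the dead-band trimmed concentration slope and converts it to a CO2
#' flux with the ideal gas law: the chamber holds `n = PV/(RT)` moles of air,
#' so a headspace slope of `s` ppm/s corresponds to `s * n / A`
#' umol CO2 m^-2 s^-1 over the mesocosm surface `A`. The sign is flipped to
#' the ecological convention: positive NEE = CO2 uptake by the mesocosm
#' (declining chamber concentration).
#'
#' @inheritParams fit_concentration_slope
#' @param r2_flag_threshold Traces with a fit r-squared below this value are
#'   flagged (`qc_flag = TRUE`) but never dropped (default 0.75).
#' @return A one-row `data.frame`: `mesocosm_id`, `day`, `nee`
#'   (umol CO2 m^-2 s^-1), `slope_ppm_per_s`, `r_squared`, `n_points_used`,
#'   `dead_band_s`, `qc_flag`.
#' @examples
#' ch <- chamber_spec()
#' tr <- concentration_trace(0:120, 450 - 0.0486 * (0:120), ch)
#' trace_to_nee(tr)$nee  # ~ +1.0
#' @export
trace_to_nee <- function(trace, dead_band_s = 30, r2_flag_threshold = 0.75) {
  stopifnot(inherits(trace, "concentration_trace"))
  fit <- fit_concentration_slope(trace, dead_band_s)
  conv <- nee_per_ppm_slope(trace$chamber)
  nee <- -fit$slope_ppm_per_s * conv
  data.frame(mesocosm_id = trace$mesocosm_id, day = trace$day,
             nee = nee,
             slope_ppm_per_s = fit$slope_ppm_per_s,
             r_squared = fit$r_squared,
             n_points_used = fit$n_points_used,
             dead_band_s = dead_band_s,
             qc_flag = fit$r_squared < r2_flag_threshold,
             stringsAsFactors = FALSE)
}

#' Batch flux computation
#'
#' Applies [trace_to_nee()] to a list of traces. Per-trace failures (e.g.
#' too few points after the dead band) are collected as error records, not
#' raised, so one bad record never aborts a measurement campaign.
#'
#' @param traces List of [concentration_trace()] objects (non-empty).
#' @inheritParams trace_to_nee
#' @return List with `fluxes` (data.frame of successful results, keyed by
#'   `mesocosm_id` and `day`) and `errors` (data.frame `mesocosm_id`, `day`,
#'   `message`; zero rows when all traces succeed).
#' @export
batch_fluxes <- function(traces, dead_band_s = 30, r2_flag_threshold = 0.75) {
  if (length(traces) == 0) stop("no traces supplied", call. = FALSE)
  ok <- list(); bad <- list()
  for (tr in traces) {
    res <- tryCatch(trace_to_nee(tr, dead_band_s, r2_flag_threshold),
                    error = function(e) e)
    if (inherits(res, "error")) {
      bad[[length(bad) + 1L]] <- data.frame(
        mesocosm_id = tr$mesocosm_id, day = tr$day,
        message = conditionMessage(res), stringsAsFactors = FALSE)
    } else {
      ok[[length(ok) + 1L]] <- res
    }
  }
  empty_err <- data.frame(mesocosm_id = character(), day = integer(),
                          message = character(), stringsAsFactors = FALSE)
  list(fluxes = if (length(ok)) do.call(rbind, ok) else NULL,
       errors = if (length(bad)) do.call(rbind, bad) else empty_err)
}
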