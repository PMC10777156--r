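#' Default generative parameters
#'
#' `default_baselines()` gives the mean acclimation NEE per mixture, inside
#' the observed acclimation range of 0.74-1.71 umol CO2 m^-2 s^-1, with the
#' *S. cuspidatum* monoculture highest and the *S. medium* monoculture
#' lowest. `default_phase_slopes()` gives the generative NEE trend for every
#' mixture x treatment x phase cell, in umol CO2 m^-2 s^-1 per day:
#' acclimation trends are zero (NEE is stationary before drawdown), drawdown
#' trends are the published per-mixture response slopes (mild: 0.20, 0.14,
#' 0.21, 0.14, 0.19; deep: -0.18, -0.11, -0.11, -0.13, -0.09, in design
#' order), and recovery trends are small positive rates, faster in the deep
#' arm for mixtures with >= 75% *S. cuspidatum*.
#'
#' @return `default_baselines()`: named numeric vector (umol CO2 m^-2 s^-1).
#' @export
default_baselines <- function() {
  stats::setNames(c(1.35, 1.25, 1.15, 1.05, 0.95), mixture_levels())
}

#' @rdname default_baselines
#' @return `default_phase_slopes()`: `data.frame` with columns `mixture`,
#'   `treatment`, `phase`, `slope`.
#' @export
default_phase_slopes <- function() {
  mixes <- mixture_levels()
  mild_slopes <- stats::setNames(c(0.20, 0.14, 0.21, 0.14, 0.19), mixes)
  deep_slopes <- stats::setNames(c(-0.18, -0.11, -0.11, -0.13, -0.09), mixes)
  rec_mild <- stats::setNames(rep(0.003, 5), mixes)
  rec_deep <- stats::setNames(c(0.009, 0.008, 0.006, 0.004, 0.003), mixes)
  rows <- list()
  for (mix in mixes) {
    rows[[length(rows) + 1L]] <- data.frame(
      mixture = mix,
      treatment = rep(c("mild", "deep"), times = c(3L, 4L)),
      phase = c("acclimation", "mild_drawdown", "recovery",
                "acclimation", "mild_drawdown", "deep_drawdown", "recovery"),
      slope = c(0, mild_slopes[mix], rec_mild[mix],
                0, mild_slopes[mix], deep_slopes[mix], rec_deep[mix]),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generator configuration
#'
#' Collects everything the synthetic NEE generator needs: per-mixture
#' baseline (mean acclimation) NEE, per-cell phase trends, measurement noise
#' and the rewetting behaviour at the start of recovery.
#'
#' The default `noise_sd` of 0.4 umol CO2 m^-2 s^-1 is calibrated so that
#' group-level slope standard errors in simulated experiments match the
#' published ones: with the mild-drawdown measurement days at phase offsets
#' 1, 3, 5, 7 the slope design sum of squares is Sxx = 20, so the standard
#' error of an n = 8 group mean slope is `noise_sd / sqrt(20 * 8)` = 0.032
#' (published mild band 0.03-0.05); the 14-day deep phase gives Sxx = 148.1
#' and an n = 4 standard error of 0.016 (published deep band 0.01-0.04).
#'
#' Rewetting: each arm has a `mode` and an `offset`. Mode `"reset"` places
#' the recovery-entry level at `baseline + offset` (the mild arm drops back
#' towards — by default slightly below — its pre-drought level immediately
#' on rewetting); mode `"continuous"` places it at the previous phase's
#' noiseless end value plus `offset` (the deep arm shows no such step).
#'
#' @param baseline_nee Named numeric, mean acclimation NEE per mixture.
#' @param phase_slope `data.frame(mixture, treatment, phase, slope)`; slope
#'   in umol CO2 m^-2 s^-1 per day.
#' @param noise_sd Gaussian measurement noise SD on NEE, umol CO2 m^-2 s^-1.
#' @param n_replicates Mesocosms per mixture x treatment cell.
#' @param seed Integer seed.
#' @param rewet List with elements `mild` and `deep`, each
#'   `list(mode = "reset"|"continuous", offset = <numeric>)`.
#' @param drop_mesocosm Optional mesocosm_id removed after generation
#'   (emulates the loss of one deep-arm 75/25 mesocosm to a leaking
#'   container).
#' @return A list of class `"generator_config"`.
#' @export
generator_config <- function(baseline_nee = default_baselines(),
                             phase_slope = default_phase_slopes(),
                             noise_sd = 0.4,
                             n_replicates = 4,
                             seed = 1,
                             rewet = list(
                               mild = list(mode = "reset", offset = -0.1),
                               deep = list(mode = "continuous", offset = 0)),
                             drop_mesocosm = NULL) {
  if (!is.numeric(noise_sd) || length(noise_sd) != 1 || noise_sd < 0) {
    stop("`noise_sd` must be a single non-negative number", call. = FALSE)
  }
  if (n_replicates < 1) stop("`n_replicates` must be >= 1", call. = FALSE)
  stopifnot(is.data.frame(phase_slope),
            all(c("mixture", "treatment", "phase", "slope") %in%
                  names(phase_slope)))
  for (arm in c("mild", "deep")) {
    m <- rewet[[arm]]$mode
    if (!m %in% c("reset", "continuous")) {
      stop("rewet mode for the ", arm, " arm must be 'reset' or 'continuous'",
           call. = FALSE)
    }
  }
  structure(list(baseline_nee = baseline_nee, phase_slope = phase_slope,
                 noise_sd = noise_sd, n_replicates = n_replicates,
                 seed = seed, rewet = rewet, drop_mesocosm = drop_mesocosm),
            class = "generator_config")
}

# slope lookup with a configuration error naming the missing key
lookup_slope <- function(config, mixture, treatment, phase) {
  tab <- config$phase_slope
  hit <- tab$mixture == mixture & tab$treatment == treatment &
    tab$phase == phase
  if (sum(hit) != 1) {
    stop(structure(class = c("peatstab_config_error", "error", "condition"),
                   list(message = sprintf(
                     "no phase_slope entry for (%s, %s, %s)",
                     mixture, treatment, phase), call = NULL)))
  }
  tab$slope[hit]
}

# noiseless phase-entry levels for one mixture x treatment arm; continuity
# with the previous phase's end value except at the configured rewet step
phase_entry_levels <- function(mixture, treatment, schedule, config) {
  b <- config$baseline_nee[[mixture]]
  if (is.null(b)) {
    stop(structure(class = c("peatstab_config_error", "error", "condition"),
                   list(message = sprintf("no baseline_nee entry for '%s'",
                                          mixture), call = NULL)))
  }
  ph <- schedule$phases
  entry <- numeric(nrow(ph)); names(entry) <- ph$phase
  level <- b
  for (i in seq_len(nrow(ph))) {
    p <- ph$phase[i]
    s <- lookup_slope(config, mixture, treatment, p)
    if (p == "recovery") {
      rw <- config$rewet[[treatment]]
      level <- if (rw$mode == "reset") b + rw$offset else level + rw$offset
    }
    entry[i] <- level
    level <- level + s * (ph$end_day[i] - ph$start_day[i])
  }
  entry
}

#' Generate synthetic per-mesocosm NEE series
#'
#' For every mesocosm in the design, NEE at each scheduled measurement day
#' is the phase-entry level plus the phase trend times days since phase
#' start, plus independent Gaussian noise. Phase-entry levels are continuous
#' with the previous phase's noiseless end value, except at the start of
#' recovery where the configured rewetting step applies.
#'
#' @param design Design table from [build_design()] (or any data.frame with
#'   `mesocosm_id`, `mixture`, `treatment`).
#' @param schedules Named list of `"phase_schedule"` objects per treatment
#'   arm, as from [default_schedules()].
#' @param config A [generator_config()].
#' @return A `data.frame` of class `"nee_series"`: `mesocosm_id`, `mixture`,
#'   `treatment`, `day`, `phase`, `nee` (umol CO2 m^-2 s^-1). Deterministic
#'   for a fixed `config$seed`.
#' @examples
#' design <- build_design(2, seed = 1)
#' nee <- generate_nee_series(design, default_schedules(),
#'                            generator_config(seed = 1))
#' head(nee)
#' @export
generate_nee_series <- function(design, schedules = default_schedules(),
                                config = generator_config()) {
  stopifnot(is.data.frame(design),
            all(c("mesocosm_id", "mixture", "treatment") %in% names(design)))
  for (s in schedules) validate_schedule(s)
  set.seed(config$seed)
  out <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    mix <- as.character(design$mixture[i])
    trt <- as.character(design$treatment[i])
    sched <- schedules[[trt]]
    if (is.null(sched)) stop("no schedule for treatment '", trt, "'",
                             call. = FALSE)
    entry <- phase_entry_levels(mix, trt, sched, config)
    rows <- lapply(sched$phases$phase, function(p) {
      d <- sched$measurement_days[[p]]
      start <- sched$phases$start_day[sched$phases$phase == p]
      s <- lookup_slope(config, mix, trt, p)
      mu <- entry[[p]] + s * (d - start)
      noise <- if (config$noise_sd > 0) {
        stats::rnorm(length(d), 0, config$noise_sd)
      } else 0
      data.frame(mesocosm_id = design$mesocosm_id[i], mixture = mix,
                 treatment = trt, day = d, phase = p, nee = mu + noise,
                 stringsAsFactors = FALSE)
    })
    out[[i]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("nee_series", "data.frame")
  res
}

#' Synthesise a raw chamber concentration trace for a target NEE
#'
#' Inverse of the flux computation: builds a 1 Hz chamber CO2 record whose
#' noiseless dead-band slope converts back to exactly the requested NEE
#' (round-trip identity). Under the ecological sign convention a positive
#' NEE (uptake) yields a declining concentration.
#'
#' @param nee Target flux, umol CO2 m^-2 s^-1 (ecological sign convention).
#' @param chamber A [chamber_spec()].
#' @param ambient_co2 Concentration at chamber closure, ppm.
#' @param duration_s Record length, s (>= 60; nominal 120).
#' @param noise_sd_ppm Gaussian noise SD added to each 1 Hz sample, ppm.
#' @param seed Optional integer seed for the noise.
#' @param mesocosm_id,day Identifiers stored on the trace.
#' @return A [concentration_trace()].
#' @export
generate_concentration_trace <- function(nee, chamber = chamber_spec(),
                                         ambient_co2 = 420,
                                         duration_s = 120,
                                         noise_sd_ppm = 0, seed = NULL,
                                         mesocosm_id = NA_character_,
                                         day = NA_integer_) {
  if (duration_s < 60) stop("`duration_s` must be >= 60 s", call. = FALSE)
  stopifnot(inherits(chamber, "chamber_spec"))
  if (!is.null(seed)) set.seed(seed)
  t <- 0:duration_s
  slope <- -nee / nee_per_ppm_slope(chamber)
  co2 <- ambient_co2 + slope * t
  if (noise_sd_ppm > 0) co2 <- co2 + stats::rnorm(length(t), 0, noise_sd_ppm)
  concentration_trace(t, co2, chamber, mesocosm_id, day)
}

#' Remove a mesocosm from a NEE series
#'
#' Drops every record of one mesocosm, emulating the loss of a unit during
#' the experiment (a leaking container). Downstream summaries must tolerate
#' the resulting imbalance (one cell at n - 1).
#'
#' @param series A `"nee_series"` data.frame.
#' @param drop_id `mesocosm_id` to remove; must be present.
#' @return The series without the dropped mesocosm.
#' @export
apply_missingness <- function(series, drop_id) {
  stopifnot(is.data.frame(series), "mesocosm_id" %in% names(series))
  if (!drop_id %in% series$mesocosm_id) {
    stop(structure(class = c("peatstab_key_error", "error", "condition"),
                   list(message = sprintf("mesocosm '%s' not found", drop_id),
                        call = NULL)))
  }
  out <- series[series$mesocosm_id != drop_id, , drop = FALSE]
  rownames(out) <- NULL
  out
}
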