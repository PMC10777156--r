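#' Signed resistance of NEE to water table drawdown
#'
#' Resistance expresses how close net CO2 exchange at the end of the
#' drawdown treatment stayed to its pre-drawdown level, as the dimensionless
#' ratio `omega = nee_acc_mean / (nee_d - nee_acc_mean)`. Because drawdown
#' can push NEE either way, the signed ("true") value is kept rather than a
#' magnitude: a doubling of NEE gives omega = 1, a halving gives omega = -2.
#' Values near 0 indicate low resistance; large values of either sign
#' indicate high resistance. An unchanged NEE (denominator below `tol`)
#' returns `Inf` — the infinite-resistance marker, flagged downstream as
#' `omega_infinite` and excluded from group statistics.
#'
#' @param nee_acc_mean Mean NEE over the acclimation period,
#'   umol CO2 m^-2 s^-1; must be nonzero.
#' @param nee_d NEE on the last day of the drawdown treatment.
#' @param tol Degenerate-denominator tolerance (umol CO2 m^-2 s^-1 scale).
#' @return Dimensionless signed resistance; `Inf` when NEE is unchanged.
#' @examples
#' resistance_omega(1.0, 2.0)  #  1  (doubling)
#' resistance_omega(1.0, 0.5)  # -2  (halving)
#' @export
resistance_omega <- function(nee_acc_mean, nee_d, tol = 1e-9) {
  if (!is.finite(nee_acc_mean) || !is.finite(nee_d)) {
    stop("NEE inputs must be finite", call. = FALSE)
  }
  if (nee_acc_mean == 0) {
    stop(structure(class = c("peatstab_undefined_baseline", "error",
                             "condition"),
                   list(message = "acclimation NEE is zero; resistance undefined",
                        call = NULL)))
  }
  denom <- nee_d - nee_acc_mean
  if (abs(denom) < tol) return(Inf)
  nee_acc_mean / denom
}

#' Resilience of NEE after rewetting
#'
#' Resilience expresses the ability of the perturbed CO2 exchange to return
#' to pre-perturbation levels, as
#' `delta = |(nee_d - nee_acc_mean) / (nee_rec - nee_acc_mean)|`.
#' High values indicate strong return towards the acclimation level; a full
#' return (denominator below `tol`) gives `Inf`, the infinite-resilience
#' marker, flagged as `delta_infinite` downstream.
#'
#' @inheritParams resistance_omega
#' @param nee_rec NEE on the last day of the recovery period.
#' @return Non-negative dimensionless resilience; `Inf` on full return.
#' @examples
#' resilience_delta(1.0, 2.0, 2.0)   # 1
#' resilience_delta(1.0, 0.5, 0.75)  # 2
#' @export
resilience_delta <- function(nee_acc_mean, nee_d, nee_rec, tol = 1e-9) {
  if (any(!is.finite(c(nee_acc_mean, nee_d, nee_rec)))) {
    stop("NEE inputs must be finite", call. = FALSE)
  }
  denom <- nee_rec - nee_acc_mean
  if (abs(denom) < tol) return(Inf)
  abs((nee_d - nee_acc_mean) / denom)
}

#' Within-phase NEE response slope of one mesocosm
#'
#' Ordinary least-squares regression of NEE on measurement day within one
#' experimental phase, with day re-zeroed to the phase start so slopes are
#' comparable across arms whose phases begin on different calendar days.
#'
#' @param series NEE records of a single mesocosm (data.frame with `day`,
#'   `phase`, `nee`).
#' @param phase Phase name to fit within.
#' @param phase_start Calendar day of the phase start used to re-zero `day`;
#'   defaults to the earliest measurement day in the phase.
#' @return List with `slope` (umol CO2 m^-2 s^-1 per day), `stderr` and `n`.
#' @export
phase_slope <- function(series, phase, phase_start = NULL) {
  stopifnot(is.data.frame(series), all(c("day", "phase", "nee") %in%
                                         names(series)))
  sub <- series[series$phase == phase, , drop = FALSE]
  if (nrow(sub) < 3) {
    stop(structure(class = c("peatstab_insufficient_data", "error",
                             "condition"),
                   list(message = sprintf(
                     "phase '%s' has %d records (>= 3 required for a slope)",
                     phase, nrow(sub)), call = NULL)))
  }
  if (is.null(phase_start)) phase_start <- min(sub$day)
  d <- sub$day - phase_start
  fit <- stats::lm(nee ~ d, data = data.frame(nee = sub$nee, d = d))
  n <- nrow(sub)
  sxx <- sum((d - mean(d))^2)
  sigma2 <- sum(stats::residuals(fit)^2) / (n - 2)
  list(slope = unname(stats::coef(fit)["d"]),
       stderr = sqrt(sigma2 / sxx),
       n = n)
}

#' Per-mesocosm stability summary
#'
#' Derives the full stability record of one mesocosm from its NEE series:
#'
#' * `nee_acc_mean`: mean NEE over all acclimation measurements;
#' * `nee_d`: mean NEE on the final measurement day of the arm's drawdown
#'   treatment (mild arm: end of the mild phase; deep arm: end of the deep
#'   phase) — a mean so that accidental duplicate readings on that day are
#'   averaged rather than arbitrarily picked;
#' * `nee_rec`: mean NEE on the final recovery measurement day;
#' * `omega`, `delta`: signed resistance and resilience, with
#'   `omega_infinite` / `delta_infinite` flags when degenerate;
#' * `slope_mild` (and `slope_deep` for the deep arm): within-phase response
#'   slopes; `drawdown_slope` is the slope over the arm-defining drawdown
#'   phase (mild phase for the mild arm, deep phase for the deep arm);
#' * `recovery_rate`: slope over all recovery-period measurements.
#'
#' @param series NEE records of a single mesocosm (`mesocosm_id`, `day`,
#'   `phase`, `nee`; at least 2 acclimation, 1 drawdown and 1 recovery
#'   record).
#' @param schedule The `"phase_schedule"` of the mesocosm's arm.
#' @param tol Degenerate-denominator tolerance for omega and delta.
#' @return One-row `data.frame` with the fields above plus standard errors
#'   of the slopes.
#' @export
summarize_mesocosm <- function(series, schedule, tol = 1e-9) {
  stopifnot(is.data.frame(series),
            all(c("mesocosm_id", "day", "phase", "nee") %in% names(series)),
            inherits(schedule, "phase_schedule"))
  id <- unique(series$mesocosm_id)
  if (length(id) != 1) stop("series must contain exactly one mesocosm",
                            call. = FALSE)
  arm_final_phase <- if (schedule$treatment == "deep") "deep_drawdown"
                     else "mild_drawdown"
  for (p in c("acclimation", arm_final_phase, "recovery")) {
    if (!any(series$phase == p)) {
      stop(structure(class = c("peatstab_missing_phase", "error", "condition"),
                     list(message = sprintf(
                       "mesocosm '%s' has no '%s' records", id, p),
                       call = NULL, phase = p)))
    }
  }
  acc <- series[series$phase == "acclimation", ]
  if (nrow(acc) < 2) {
    stop(structure(class = c("peatstab_insufficient_data", "error",
                             "condition"),
                   list(message = sprintf(
                     "mesocosm '%s' has %d acclimation records (>= 2 required)",
                     id, nrow(acc)), call = NULL)))
  }
  last_day_mean <- function(phase) {
    sub <- series[series$phase == phase, ]
    mean(sub$nee[sub$day == max(sub$day)])
  }
  nee_acc_mean <- mean(acc$nee)
  nee_d <- last_day_mean(arm_final_phase)
  nee_rec <- last_day_mean("recovery")

  omega <- resistance_omega(nee_acc_mean, nee_d, tol)
  delta <- resilience_delta(nee_acc_mean, nee_d, nee_rec, tol)

  start_of <- function(p) {
    schedule$phases$start_day[schedule$phases$phase == p]
  }
  sl_mild <- phase_slope(series, "mild_drawdown", start_of("mild_drawdown"))
  sl_deep <- if (schedule$treatment == "deep") {
    phase_slope(series, "deep_drawdown", start_of("deep_drawdown"))
  } else list(slope = NA_real_, stderr = NA_real_, n = NA_integer_)
  sl_rec <- phase_slope(series, "recovery", start_of("recovery"))
  drawdown_slope <- if (schedule$treatment == "deep") sl_deep$slope
                    else sl_mild$slope

  data.frame(
    mesocosm_id = id,
    nee_acc_mean = nee_acc_mean, nee_d = nee_d, nee_rec = nee_rec,
    omega = omega, delta = delta,
    omega_infinite = is.infinite(omega),
    delta_infinite = is.infinite(delta),
    slope_mild = sl_mild$slope, slope_mild_se = sl_mild$stderr,
    slope_deep = sl_deep$slope, slope_deep_se = sl_deep$stderr,
    drawdown_slope = drawdown_slope,
    recovery_rate = sl_rec$slope, recovery_rate_se = sl_rec$stderr,
    stringsAsFactors = FALSE
  )
}

#' Stability summary for a whole experiment
#'
#' Applies [summarize_mesocosm()] to every mesocosm in a NEE series table
#' and joins the design columns.
#'
#' @param series A `"nee_series"` data.frame (all mesocosms).
#' @param design Design table from [build_design()]; rows without series
#'   records (e.g. a dropped mesocosm) are skipped.
#' @param schedules Named list of per-arm schedules
#'   (see [default_schedules()]).
#' @param tol Passed to [summarize_mesocosm()].
#' @return `data.frame` with one row per mesocosm: design columns plus the
#'   [summarize_mesocosm()] fields.
#' @export
summarize_stability <- function(series, design,
                                schedules = default_schedules(),
                                tol = 1e-9) {
  keep <- design$mesocosm_id %in% unique(series$mesocosm_id)
  design <- design[keep, , drop = FALSE]
  rows <- lapply(seq_len(nrow(design)), function(i) {
    id <- design$mesocosm_id[i]
    trt <- as.character(design$treatment[i])
    one <- series[series$mesocosm_id == id, , drop = FALSE]
    res <- summarize_mesocosm(one, schedules[[trt]], tol)
    cbind(design[i, c("mesocosm_id", "mixture", "cuspidatum_fraction",
                      "treatment", "replicate")],
          res[, setdiff(names(res), "mesocosm_id"), drop = FALSE])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
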