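#' Experimental phase schedule
#'
#' Builds the calendar of experimental phases and measurement days for one
#' drawdown arm. Day 0 is the start of the (measured) acclimation period and
#' water table drawdown begins on day `drawdown_start`. The default calendar
#' follows the study design:
#'
#' * acclimation: days 0 to `drawdown_start`, NEE measured 11, 9 and 1 days
#'   before drawdown (days 0, 2, 10 with the default start);
#' * mild drawdown: 7 days of no precipitation, measured 4x per week;
#' * deep drawdown (deep arm only): a further 14 days, measured 4x per week;
#' * recovery (rewetting): 56 days, measured 2x per week, starting at the end
#'   of the arm's drawdown (day 18 mild arm, day 32 deep arm).
#'
#' For the mild arm the deep drawdown phase is empty and recovery starts
#' where the mild phase ends.
#'
#' @param treatment `"mild"` or `"deep"`.
#' @param drawdown_start Calendar day on which drawdown begins (default 11,
#'   so the three acclimation measurements fall 11, 9 and 1 days before it).
#' @param mild_days,deep_days,recovery_days Phase durations in days
#'   (defaults 7, 14, 56).
#' @return An object of class `"phase_schedule"`: a list with `treatment`,
#'   `phases` (data.frame `phase`, `start_day`, `end_day`) and
#'   `measurement_days` (named list of integer day vectors per phase).
#' @examples
#' sched <- phase_schedule("deep")
#' sched$phases
#' @export
phase_schedule <- function(treatment = c("mild", "deep"),
                           drawdown_start = 11,
                           mild_days = 7, deep_days = 14,
                           recovery_days = 56) {
  treatment <- match.arg(treatment)
  if (any(c(drawdown_start, mild_days, recovery_days) <= 0) ||
      (treatment == "deep" && deep_days <= 0)) {
    stop("phase durations and drawdown_start must be positive", call. = FALSE)
  }
  acc <- c(0, drawdown_start)
  mild <- c(drawdown_start, drawdown_start + mild_days)
  if (treatment == "deep") {
    deep <- c(mild[2], mild[2] + deep_days)
    rec_start <- deep[2]
  } else {
    deep <- NULL
    rec_start <- mild[2]
  }
  rec <- c(rec_start, rec_start + recovery_days)

  phases <- data.frame(
    phase = c("acclimation", "mild_drawdown",
              if (!is.null(deep)) "deep_drawdown", "recovery"),
    start_day = c(acc[1], mild[1], if (!is.null(deep)) deep[1], rec[1]),
    end_day = c(acc[2], mild[2], if (!is.null(deep)) deep[2], rec[2]),
    stringsAsFactors = FALSE
  )

  meas <- list(
    acclimation = acc[2] - c(11, 9, 1),
    mild_drawdown = drawdown_week_days(mild[1], mild[2]),
    deep_drawdown = if (!is.null(deep)) drawdown_week_days(deep[1], deep[2]),
    recovery = recovery_week_days(rec[1], rec[2])
  )
  meas <- meas[!vapply(meas, is.null, logical(1))]
  meas$acclimation <- sort(pmax(meas$acclimation, acc[1]))

  structure(list(treatment = treatment, phases = phases,
                 measurement_days = meas),
            class = "phase_schedule")
}

# 4 measurements per week at day offsets 1, 3, 5, 7 within each drawdown week
drawdown_week_days <- function(start, end) {
  weeks <- seq(start, end - 1, by = 7)
  days <- unlist(lapply(weeks, function(w) w + c(1, 3, 5, 7)))
  sort(unique(days[days <= end]))
}

# 2 measurements per week at day offsets 3 and 7 within each recovery week
recovery_week_days <- function(start, end) {
  weeks <- seq(start, end - 1, by = 7)
  days <- unlist(lapply(weeks, function(w) w + c(3, 7)))
  sort(unique(days[days <= end]))
}

#' @export
print.phase_schedule <- function(x, ...) {
  cat("Phase schedule (", x$treatment, " drawdown arm)\n", sep = "")
  print(x$phases)
  invisible(x)
}

#' Validate a phase schedule
#'
#' Checks contiguity, ordering and that every measurement day lies inside
#' its phase.
#'
#' @param schedule A `"phase_schedule"` object.
#' @return `TRUE` invisibly; otherwise an error.
#' @export
validate_schedule <- function(schedule) {
  stopifnot(inherits(schedule, "phase_schedule"))
  ph <- schedule$phases
  ord <- c("acclimation", "mild_drawdown", "deep_drawdown", "recovery")
  if (!identical(ph$phase, intersect(ord, ph$phase))) {
    stop("phases out of order", call. = FALSE)
  }
  if (any(ph$end_day <= ph$start_day)) stop("empty phase", call. = FALSE)
  if (any(abs(ph$start_day[-1] - ph$end_day[-nrow(ph)]) > 0)) {
    stop("phases must be contiguous", call. = FALSE)
  }
  for (p in ph$phase) {
    d <- schedule$measurement_days[[p]]
    if (is.null(d) || length(d) == 0) {
      stop("phase '", p, "' has no measurement days", call. = FALSE)
    }
    lo <- ph$start_day[ph$phase == p]
    hi <- ph$end_day[ph$phase == p]
    if (is.unsorted(d, strictly = TRUE) || any(d < lo) || any(d > hi)) {
      stop("measurement days of phase '", p, "' outside phase bounds",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Default schedules for both drawdown arms
#'
#' @param ... Passed on to [phase_schedule()].
#' @return Named list with elements `mild` and `deep`, each a
#'   `"phase_schedule"`.
#' @export
default_schedules <- function(...) {
  list(mild = phase_schedule("mild", ...),
       deep = phase_schedule("deep", ...))
}

#' Recovery start day of an arm
#' @param schedule A `"phase_schedule"` object.
#' @return Integer calendar day on which the rewetting period starts.
#' @export
recovery_start <- function(schedule) {
  stopifnot(inherits(schedule, "phase_schedule"))
  schedule$phases$start_day[schedule$phases$phase == "recovery"]
}
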