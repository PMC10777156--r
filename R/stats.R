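#' Align recovery periods to a common origin
#'
#' The rewetting period starts on different calendar days in the two arms
#' (the deep arm's drawdown lasts two weeks longer). For analyses that pool
#' both arms over recovery, recovery-record days are re-indexed so that day 0
#' is each arm's recovery start; all other phases are untouched. The
#' original calendar day is kept in `calendar_day`.
#'
#' @param series A `"nee_series"` data.frame; every mesocosm must have
#'   recovery records.
#' @param schedules Named list of per-arm schedules.
#' @return The series with recovery `day`s re-indexed and a `calendar_day`
#'   column; record counts and NEE values are unchanged. Already-aligned
#'   input (recognised by its `calendar_day` column) is returned unchanged.
#' @export
align_recovery <- function(series, schedules = default_schedules()) {
  stopifnot(is.data.frame(series),
            all(c("mesocosm_id", "treatment", "day", "phase", "nee") %in%
                  names(series)))
  if ("calendar_day" %in% names(series)) return(series)
  ids <- unique(series$mesocosm_id)
  has_rec <- vapply(ids, function(id) {
    any(series$phase[series$mesocosm_id == id] == "recovery")
  }, logical(1))
  if (any(!has_rec)) {
    stop(structure(class = c("peatstab_missing_phase", "error", "condition"),
                   list(message = sprintf(
                     "mesocosm(s) without recovery records: %s",
                     paste(ids[!has_rec], collapse = ", ")), call = NULL)))
  }
  out <- series
  out$calendar_day <- out$day
  for (arm in names(schedules)) {
    idx <- out$treatment == arm & out$phase == "recovery"
    out$day[idx] <- out$day[idx] - recovery_start(schedules[[arm]])
  }
  out
}

#' Group-level response-slope table
#'
#' Summarises per-mesocosm response slopes as mean +/- standard error per
#' mixture, the published table's layout. The mild-drawdown phase pools both
#' arms (the hydrological regime is identical over that week, n = 8 per
#' mixture); the deep-drawdown phase and the recovery period use the
#' relevant arm(s) only, split by treatment for recovery.
#'
#' @param stability Table from [summarize_stability()].
#' @param phase One of `"mild_drawdown"`, `"deep_drawdown"`, `"recovery"`.
#' @return `data.frame` with `mixture` (design order), `treatment` (recovery
#'   only), `mean_slope`, `stderr` (sample SD / sqrt(n); `NA` at n = 1) and
#'   `n`.
#' @export
group_slope_table <- function(stability,
                              phase = c("mild_drawdown", "deep_drawdown",
                                        "recovery")) {
  phase <- match.arg(phase)
  col <- switch(phase, mild_drawdown = "slope_mild",
                deep_drawdown = "slope_deep", recovery = "recovery_rate")
  df <- stability[!is.na(stability[[col]]), , drop = FALSE]
  split_by <- if (phase == "recovery") {
    interaction(df$mixture, df$treatment, drop = FALSE)
  } else df$mixture
  groups <- if (phase == "recovery") {
    expand.grid(mixture = mixture_levels(), treatment = treatment_levels(),
                stringsAsFactors = FALSE)
  } else data.frame(mixture = mixture_levels(), stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    sel <- df$mixture == groups$mixture[i]
    if (phase == "recovery") sel <- sel & df$treatment == groups$treatment[i]
    v <- df[[col]][sel]
    data.frame(groups[i, , drop = FALSE],
               mean_slope = if (length(v)) mean(v) else NA_real_,
               stderr = if (length(v) > 1) stats::sd(v) / sqrt(length(v))
                        else NA_real_,
               n = length(v), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' One-way analysis of variance from the sum-of-squares definitions
#'
#' Classical equal-variance one-way ANOVA computed directly from the
#' between/within sum-of-squares decomposition:
#' `F = (SS_between / df_between) / (SS_within / df_within)`, with the
#' p-value from the F distribution. When every group is internally constant
#' but groups differ, `SS_within = 0` and the F statistic is the `Inf`
#' marker (p = 0).
#'
#' @param values Numeric response (e.g. per-mesocosm response slopes).
#' @param groups Group labels, same length; >= 2 groups with >= 2 members
#'   each.
#' @return List of class `"anova_result"`: `factor`, `df_between`,
#'   `df_within`, `f_statistic`, `p_value`, `ss_between`, `ss_within`,
#'   `ss_total`.
#' @export
oneway_anova <- function(values, groups) {
  if (length(values) != length(groups)) {
    stop("`values` and `groups` must have equal length", call. = FALSE)
  }
  keep <- is.finite(values) & !is.na(groups)
  values <- values[keep]
  groups <- as.character(groups[keep])
  counts <- table(groups)
  if (length(counts) < 2 || any(counts < 2)) {
    stop("need >= 2 groups with >= 2 members each", call. = FALSE)
  }
  grand <- mean(values)
  means <- tapply(values, groups, mean)
  n_i <- as.numeric(counts[names(means)])
  ss_between <- sum(n_i * (means - grand)^2)
  ss_within <- sum((values - means[groups])^2)
  ss_total <- sum((values - grand)^2)
  df_b <- length(means) - 1L
  df_w <- length(values) - length(means)
  f <- if (ss_within == 0) {
    if (ss_between == 0) 0 else Inf
  } else (ss_between / df_b) / (ss_within / df_w)
  p <- if (is.infinite(f)) 0 else stats::pf(f, df_b, df_w, lower.tail = FALSE)
  structure(list(factor = "group", df_between = df_b, df_within = df_w,
                 f_statistic = f, p_value = p,
                 ss_between = ss_between, ss_within = ss_within,
                 ss_total = ss_total),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$f_statistic, x$p_value))
  invisible(x)
}

#' Tukey HSD pairwise contrasts
#'
#' All pairwise group mean differences with Tukey honest-significant-
#' difference adjusted p-values from the studentized range distribution
#' (Tukey-Kramer standard errors for unbalanced groups).
#'
#' @inheritParams oneway_anova
#' @param method Adjustment method; only `"tukey"` is provided.
#' @return `data.frame` with `pair` (`"a-b"`), `estimate` (mean a - mean b),
#'   `se`, `t_statistic` and `p_adjusted`.
#' @export
pairwise_contrasts <- function(values, groups, method = c("tukey")) {
  method <- match.arg(method)
  keep <- is.finite(values) & !is.na(groups)
  values <- values[keep]
  groups <- as.character(groups[keep])
  counts <- table(groups)
  if (length(counts) < 2 || any(counts < 2)) {
    stop("need >= 2 groups with >= 2 members each", call. = FALSE)
  }
  lv <- names(counts)
  k <- length(lv)
  means <- tapply(values, groups, mean)[lv]
  n_i <- as.numeric(counts[lv])
  df_w <- length(values) - k
  mse <- sum((values - means[groups])^2) / df_w
  pairs <- utils::combn(lv, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    est <- means[[a]] - means[[b]]
    se <- sqrt(mse * (1 / counts[[a]] + 1 / counts[[b]]))
    tstat <- if (se == 0) ifelse(est == 0, 0, Inf * sign(est)) else est / se
    # studentized range statistic q = |diff| / (se / sqrt(2))
    q <- sqrt(2) * abs(tstat)
    p <- if (is.infinite(q)) 0 else
      stats::ptukey(q, nmeans = k, df = df_w, lower.tail = FALSE)
    data.frame(pair = paste(a, b, sep = "-"), estimate = est, se = se,
               t_statistic = tstat, p_adjusted = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Repeated-measures mixed model within one phase
#'
#' Convenience refit of the phase-wise repeated-measures analysis on
#' simulated data: a linear mixed-effects model of NEE on treatment x
#' mixture x day (all interactions) with a random intercept per mesocosm,
#' fitted within one experimental phase. The mild-drawdown and acclimation
#' phases use both arms (identical hydrology over those periods); the deep
#' phase only exists in the deep arm, so `treatment` is dropped there.
#' The model structure is this package's own; no equivalence with any
#' particular published random-effects specification is implied.
#'
#' @param series A `"nee_series"` data.frame.
#' @param phase Phase to fit within.
#' @return An object from [lmerTest::lmer()]; inspect with `anova()`.
#' @export
fit_phase_lmm <- function(series, phase) {
  sub <- series[series$phase == phase, , drop = FALSE]
  if (nrow(sub) == 0) stop("no records in phase '", phase, "'", call. = FALSE)
  sub$day_c <- sub$day - min(sub$day)
  two_arms <- length(unique(sub$treatment)) > 1
  fml <- if (two_arms) {
    nee ~ treatment * mixture * day_c + (1 | mesocosm_id)
  } else {
    nee ~ mixture * day_c + (1 | mesocosm_id)
  }
  lmerTest::lmer(fml, data = sub)
}
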