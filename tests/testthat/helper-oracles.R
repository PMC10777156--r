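# Independent closed-form oracles, coded from the textbook sum formulas so
# they share no code path with the package implementation.

# simple linear regression: slope, intercept and slope SE from the centered
# textbook sums Sxy/Sxx (centering keeps the closed form numerically exact)
ols_sigma_oracle <- function(x, y) {
  n <- length(x)
  xbar <- sum(x) / n; ybar <- sum(y) / n
  slope <- sum((x - xbar) * (y - ybar)) / sum((x - xbar)^2)
  intercept <- ybar - slope * xbar
  yhat <- intercept + slope * x
  se <- sqrt((sum((y - yhat)^2) / (n - 2)) / sum((x - mean(x))^2))
  list(slope = slope, intercept = intercept, stderr = se)
}

# one-way ANOVA from the raw-total sum formulas (no group-mean vectors)
anova_sigma_oracle <- function(values, groups) {
  groups <- as.character(groups)
  N <- length(values)
  G <- sum(values)
  ss_total <- sum(values^2) - G^2 / N
  totals <- tapply(values, groups, sum)
  counts <- tapply(values, groups, length)
  ss_between <- sum(totals^2 / counts) - G^2 / N
  ss_within <- ss_total - ss_between
  k <- length(totals)
  f <- (ss_between / (k - 1)) / (ss_within / (N - k))
  list(f = f, df1 = k - 1, df2 = N - k,
       ss_between = ss_between, ss_within = ss_within, ss_total = ss_total,
       p = pf(f, k - 1, N - k, lower.tail = FALSE))
}

# small helper: a single-cell design table for simulating many mesocosms of
# one mixture x treatment combination
single_cell_design <- function(n, mixture = "c100", treatment = "mild") {
  data.frame(mesocosm_id = sprintf("%s_%s_x%03d", treatment, mixture,
                                   seq_len(n)),
             mixture = mixture, treatment = treatment,
             replicate = seq_len(n), stringsAsFactors = FALSE)
}

# per-mesocosm fitted slopes in one phase of a generated series
fitted_slopes <- function(series, phase) {
  ids <- unique(series$mesocosm_id)
  vapply(ids, function(id) {
    phase_slope(series[series$mesocosm_id == id, ], phase)$slope
  }, numeric(1))
}
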