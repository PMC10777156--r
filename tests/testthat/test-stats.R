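make_experiment <- function(noise_sd = 0.3, seed = 1, n = 4) {
  design <- build_design(n, seed = seed)
  nee <- generate_nee_series(design, default_schedules(),
                             generator_config(noise_sd = noise_sd,
                                              seed = seed,
                                              n_replicates = n))
  list(design = design, nee = nee)
}

test_that("recovery alignment re-zeroes both arms to a common origin", {
  ex <- make_experiment(seed = 3)
  aligned <- align_recovery(ex$nee)
  rec <- aligned[aligned$phase == "recovery", ]
  # both arms now start their recovery at the same offsets
  expect_equal(min(rec$day[rec$treatment == "mild"]),
               min(rec$day[rec$treatment == "deep"]))
  expect_equal(sort(unique(rec$day[rec$treatment == "mild"])),
               sort(unique(rec$day[rec$treatment == "deep"])))
  # counts and values untouched; other phases untouched
  expect_equal(nrow(aligned), nrow(ex$nee))
  expect_identical(aligned$nee, ex$nee$nee)
  other <- aligned$phase != "recovery"
  expect_identical(aligned$day[other], ex$nee$day[other])
  # calendar day preserved, re-application is the identity
  expect_identical(aligned$calendar_day, ex$nee$day)
  expect_identical(align_recovery(aligned), aligned)
})

test_that("alignment refuses series without a recovery phase", {
  ex <- make_experiment(seed = 3)
  truncated <- ex$nee[ex$nee$phase != "recovery", ]
  expect_error(align_recovery(truncated), class = "peatstab_missing_phase")
})

test_that("group slope table pools arms for the mild phase and splits recovery", {
  ex <- make_experiment(noise_sd = 0.2, seed = 4)
  st <- summarize_stability(ex$nee, ex$design)
  mild <- group_slope_table(st, "mild_drawdown")
  expect_equal(mild$n, rep(8L, 5))           # both arms pooled
  expect_equal(as.character(mild$mixture), mixture_levels())
  deep <- group_slope_table(st, "deep_drawdown")
  expect_equal(deep$n, rep(4L, 5))           # deep arm only
  rec <- group_slope_table(st, "recovery")
  expect_equal(nrow(rec), 10)                # mixture x treatment
  expect_equal(rec$n, rep(4L, 10))
  # stderr is the sample SD over member slopes / sqrt(n)
  v <- st$slope_mild[st$mixture == "c100"]
  expect_equal(mild$stderr[mild$mixture == "c100"], sd(v) / sqrt(length(v)),
               tolerance = 1e-12)
})

test_that("group slope table handles n = 1 and identical members", {
  st <- data.frame(mixture = c("c100", "c100", "m100"),
                   treatment = "deep",
                   slope_mild = c(0.2, 0.2, 0.1),
                   slope_deep = c(-0.1, -0.1, -0.2),
                   recovery_rate = c(0.01, 0.01, 0.02))
  deep <- group_slope_table(st, "deep_drawdown")
  expect_equal(deep$stderr[deep$mixture == "c100"], 0)       # identical members
  expect_true(is.na(deep$stderr[deep$mixture == "m100"]))    # single member
  expect_equal(deep$n[deep$mixture == "c25m75"], 0L)         # empty cell kept
})

test_that("one-way ANOVA matches the raw sum-of-squares oracle and aov", {
  set.seed(55)
  for (i in 1:100) {
    k <- sample(3:5, 1)
    n_g <- sample(3:8, k, replace = TRUE)
    groups <- rep(letters[1:k], times = n_g)
    values <- rnorm(sum(n_g), mean = rep(rnorm(k), times = n_g))
    got <- oneway_anova(values, groups)
    want <- anova_sigma_oracle(values, groups)
    expect_equal(got$f_statistic, want$f, tolerance = 1e-10)
    expect_equal(got$p_value, want$p, tolerance = 1e-10)
    # decomposition conserved
    expect_equal(got$ss_between + got$ss_within, got$ss_total,
                 tolerance = 1e-9)
  }
  # independent cross-check against the reference implementation
  set.seed(56)
  values <- rnorm(20); groups <- rep(letters[1:4], each = 5)
  ref <- anova(stats::aov(values ~ groups))
  got <- oneway_anova(values, groups)
  expect_equal(got$f_statistic, ref$`F value`[1], tolerance = 1e-10)
  expect_equal(got$p_value, ref$`Pr(>F)`[1], tolerance = 1e-10)
})

test_that("ANOVA degenerate layouts: zero within-variance and all-equal", {
  res <- oneway_anova(c(1, 1, 2, 2), c("a", "a", "b", "b"))
  expect_identical(res$f_statistic, Inf)
  expect_equal(res$p_value, 0)
  res2 <- oneway_anova(rep(3, 6), rep(c("a", "b"), each = 3))
  expect_equal(res2$f_statistic, 0)
  expect_error(oneway_anova(1:3, c("a", "a", "b")), ">= 2 groups")
})

test_that("Tukey contrasts agree with the reference HSD implementation", {
  set.seed(77)
  for (i in 1:10) {
    k <- sample(3:5, 1)
    n_g <- sample(c(4L, 4L, 5L, 6L), k, replace = TRUE)  # incl. unbalanced
    groups <- factor(rep(letters[1:k], times = n_g))
    values <- rnorm(sum(n_g), mean = rep(rnorm(k, sd = 0.5), times = n_g))
    got <- pairwise_contrasts(values, groups)
    ref <- stats::TukeyHSD(stats::aov(values ~ groups))$groups
    # reference labels pairs "b-a" with estimate mean(b)-mean(a)
    for (j in seq_len(nrow(got))) {
      ab <- strsplit(got$pair[j], "-")[[1]]
      ref_row <- paste(ab[2], ab[1], sep = "-")
      expect_equal(got$estimate[j], -ref[ref_row, "diff"], tolerance = 1e-9)
      expect_equal(got$p_adjusted[j], ref[ref_row, "p adj"], tolerance = 1e-6)
    }
  }
})

test_that("Tukey edge cases: two groups and identical groups", {
  set.seed(78)
  v <- rnorm(10); g <- rep(c("a", "b"), each = 5)
  got <- pairwise_contrasts(v, g)
  expect_equal(nrow(got), 1)
  # with two groups the HSD p equals the plain t-test p
  tt <- t.test(v[g == "a"], v[g == "b"], var.equal = TRUE)
  expect_equal(got$p_adjusted, tt$p.value, tolerance = 1e-9)
  same <- pairwise_contrasts(c(1, 2, 1, 2), c("a", "a", "b", "b"))
  expect_equal(same$estimate, 0)
})

test_that("mixture differences in deep-drawdown slopes are detectable at n = 4", {
  # power sanity: the generative deep-phase extremes (-0.18 vs -0.09) should
  # be flagged by the slope ANOVA in most replicate experiments
  design <- build_design(4, seed = 1)
  deep_design <- design[design$treatment == "deep", ]
  rejections <- 0L
  n_rep <- 100
  for (r in seq_len(n_rep)) {
    cfg <- generator_config(noise_sd = 0.4, seed = 5000 + r)
    nee <- generate_nee_series(deep_design, default_schedules(), cfg)
    st <- summarize_stability(nee, deep_design)
    res <- oneway_anova(st$slope_deep, st$mixture)
    if (res$p_value < 0.05) rejections <- rejections + 1L
  }
  expect_gt(rejections / n_rep, 0.5)
})

test_that("the full pipeline is deterministic and both entry points agree", {
  cfg <- generator_config(noise_sd = 0.2, seed = 9, n_replicates = 2)
  a <- run_pipeline(cfg)
  b <- run_pipeline(cfg)
  expect_identical(a$stability, b$stability)
  expect_identical(a$anova, b$anova)
  # routing every NEE value through a synthetic chamber trace and the flux
  # computation must reproduce the direct-NEE analysis
  via <- run_pipeline(cfg, via_traces = TRUE)
  num <- vapply(a$stability, is.numeric, logical(1))
  expect_equal(via$stability[num], a$stability[num], tolerance = 1e-9)
})

test_that("pipeline writes the report bundle and aborts cleanly on bad config", {
  out <- file.path(tempdir(), "peatstab_bundle")
  unlink(out, recursive = TRUE)
  cfg <- generator_config(noise_sd = 0.2, seed = 10, n_replicates = 2,
                          drop_mesocosm = "deep_c75m25_r1")
  res <- run_pipeline(cfg, out_dir = out)
  files <- c("design.csv", "nee_series.csv", "stability.csv",
             "table1_slopes_mild.csv", "table1_slopes_deep.csv",
             "recovery_rates.csv", "anova.csv", "contrasts.csv",
             "run_log.json")
  expect_true(all(file.exists(file.path(out, files))))
  expect_equal(res$run_log$n_mesocosms_analysed, 19)
  log <- jsonlite::read_json(file.path(out, "run_log.json"))
  expect_equal(log$seed, 10)
  expect_equal(log$dropped_mesocosm, "deep_c75m25_r1")
  # csv round trip preserves the series
  back <- read_nee_series(file.path(out, "nee_series.csv"))
  expect_equal(back$nee, res$nee$nee, tolerance = 1e-12)

  # a missing slope entry aborts in the simulate stage, before any output
  bad <- cfg
  bad$phase_slope <- bad$phase_slope[-1, ]
  out2 <- file.path(tempdir(), "peatstab_bundle2")
  unlink(out2, recursive = TRUE)
  expect_error(run_pipeline(bad, out_dir = out2), "stage 'simulate'")
  expect_false(dir.exists(out2))
})

test_that("trace csv files round-trip through the readers", {
  ch <- chamber_spec()
  tr <- generate_concentration_trace(1.2, ch, mesocosm_id = "m1", day = 3)
  p <- tempfile(fileext = ".csv")
  write_trace_csv(tr, p)
  back <- read_trace_csv(p, ch, mesocosm_id = "m1", day = 3)
  expect_equal(back$co2_ppm, tr$co2_ppm, tolerance = 1e-9)
  expect_equal(trace_to_nee(back)$nee, 1.2, tolerance = 1e-6)
})

test_that("phase-wise mixed model fits and reports fixed effects", {
  ex <- make_experiment(noise_sd = 0.3, seed = 21)
  fit <- fit_phase_lmm(ex$nee, "mild_drawdown")
  an <- anova(fit)
  expect_true("day_c" %in% rownames(an))
  expect_true(an["day_c", "F value"] > 0)
  # deep phase only exists in one arm: treatment is dropped from the model
  fit_d <- fit_phase_lmm(ex$nee, "deep_drawdown")
  expect_false(any(grepl("treatment", rownames(anova(fit_d)))))
})
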