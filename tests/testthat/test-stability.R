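test_that("signed resistance matches its worked anchors exactly", {
  expect_identical(resistance_omega(1.0, 2.0), 1)    # doubling of NEE
  expect_identical(resistance_omega(1.0, 0.5), -2)   # halving of NEE
})

test_that("resistance anchors hold for every positive baseline", {
  set.seed(31)
  for (acc in c(runif(50, 0.01, 10))) {
    expect_equal(resistance_omega(acc, 2 * acc), 1, tolerance = 1e-12)
    expect_equal(resistance_omega(acc, acc / 2), -2, tolerance = 1e-12)
  }
})

test_that("resistance sign tracks the direction of change; degenerate cases flagged", {
  expect_gt(resistance_omega(1.0, 1.6), 0)
  expect_lt(resistance_omega(1.0, 0.7), 0)
  expect_identical(resistance_omega(1.0, 1.0), Inf)          # unchanged NEE
  expect_identical(resistance_omega(1.0, 1.0 + 1e-12), Inf)  # below tolerance
  expect_error(resistance_omega(0, 1),
               class = "peatstab_undefined_baseline")
})

test_that("resilience examples and non-negativity", {
  expect_equal(resilience_delta(1.0, 2.0, 2.0), 1, tolerance = 1e-12)
  expect_equal(resilience_delta(1.0, 0.5, 0.75), 2, tolerance = 1e-12)  # |-0.5/-0.25|
  expect_identical(resilience_delta(1.0, 2.0, 1.0), Inf)  # full return
  set.seed(17)
  for (i in 1:50) {
    v <- runif(3, 0.1, 5)
    d <- resilience_delta(v[1], v[2], v[3])
    expect_gte(d, 0)
  }
})

test_that("omega and delta are invariant to rescaling all NEE inputs", {
  set.seed(23)
  for (i in 1:50) {
    acc <- runif(1, 0.2, 3); d <- runif(1, 0.2, 3); rec <- runif(1, 0.2, 3)
    k <- runif(1, 0.01, 100)
    expect_equal(resistance_omega(k * acc, k * d),
                 resistance_omega(acc, d), tolerance = 1e-9)
    expect_equal(resilience_delta(k * acc, k * d, k * rec),
                 resilience_delta(acc, d, rec), tolerance = 1e-9)
    expect_equal(sign(resistance_omega(acc, d)), sign(d - acc))
  }
})

test_that("phase slopes come from within-phase OLS with day re-zeroed", {
  days <- c(12, 14, 16, 18)
  series <- data.frame(mesocosm_id = "m", day = days, phase = "mild_drawdown",
                       nee = 1 + 0.2 * (days - 11))
  fit <- phase_slope(series, "mild_drawdown", phase_start = 11)
  expect_equal(fit$slope, 0.2, tolerance = 1e-12)
  expect_equal(fit$stderr, 0, tolerance = 1e-9)

  const <- transform(series, nee = 2)
  expect_equal(phase_slope(const, "mild_drawdown")$slope, 0, tolerance = 1e-12)

  set.seed(5)
  noisy <- transform(series, nee = nee + rnorm(4, 0, 0.3))
  want <- ols_sigma_oracle(days - 11, noisy$nee)
  got <- phase_slope(noisy, "mild_drawdown", phase_start = 11)
  expect_equal(got$slope, want$slope, tolerance = 1e-12)
  expect_equal(got$stderr, want$stderr, tolerance = 1e-12)

  expect_error(phase_slope(series[1:2, ], "mild_drawdown"),
               class = "peatstab_insufficient_data")
})

test_that("mesocosm summary assembles the stability record on a worked mild arm", {
  # noiseless mild arm: baseline 1.0, +0.20/day over 7 days, rewetting resets
  # NEE exactly to baseline and recovery stays flat
  cfg <- generator_config(
    baseline_nee = setNames(rep(1, 5), mixture_levels()),
    noise_sd = 0, seed = 1,
    rewet = list(mild = list(mode = "reset", offset = 0),
                 deep = list(mode = "continuous", offset = 0)))
  cfg$phase_slope$slope[cfg$phase_slope$phase == "mild_drawdown"] <- 0.20
  cfg$phase_slope$slope[cfg$phase_slope$phase == "recovery"] <- 0
  sched <- default_schedules()
  nee <- generate_nee_series(single_cell_design(1, "c100", "mild"), sched, cfg)
  res <- summarize_mesocosm(nee, sched$mild)
  expect_equal(res$nee_acc_mean, 1.0, tolerance = 1e-12)
  expect_equal(res$nee_d, 2.4, tolerance = 1e-12)
  expect_equal(res$omega, 1.0 / 1.4, tolerance = 1e-9)
  expect_true(res$delta_infinite)           # full return to baseline
  expect_equal(res$drawdown_slope, 0.20, tolerance = 1e-9)
})

test_that("a deep arm that exactly halves NEE scores omega = -2", {
  cfg <- generator_config(
    baseline_nee = setNames(rep(1, 5), mixture_levels()),
    noise_sd = 0, seed = 1)
  # flat mild week, then a deep trend that ends the 14-day phase at 0.5
  cfg$phase_slope$slope[cfg$phase_slope$phase == "mild_drawdown"] <- 0
  cfg$phase_slope$slope[cfg$phase_slope$phase == "deep_drawdown"] <- -0.5 / 14
  sched <- default_schedules()
  nee <- generate_nee_series(single_cell_design(1, "c100", "deep"), sched, cfg)
  res <- summarize_mesocosm(nee, sched$deep)
  expect_equal(res$nee_d, 0.5, tolerance = 1e-12)
  expect_equal(res$omega, -2, tolerance = 1e-9)
  expect_equal(res$drawdown_slope, -0.5 / 14, tolerance = 1e-9)
})

test_that("missing phases produce structured errors naming the phase", {
  sched <- default_schedules()
  cfg <- generator_config(noise_sd = 0, seed = 1)
  nee <- generate_nee_series(single_cell_design(1, "c100", "mild"),
                             sched, cfg)
  acc_only <- nee[nee$phase == "acclimation", ]
  err <- tryCatch(summarize_mesocosm(acc_only, sched$mild), error = identity)
  expect_s3_class(err, "peatstab_missing_phase")
  expect_match(conditionMessage(err), "mild_drawdown")
})

test_that("experiment-wide summary joins the design and tolerates a dropped unit", {
  sched <- default_schedules()
  design <- build_design(4, seed = 1)
  cfg <- generator_config(noise_sd = 0.2, seed = 2)
  nee <- apply_missingness(generate_nee_series(design, sched, cfg),
                           "deep_c75m25_r1")
  st <- summarize_stability(nee, design, sched)
  expect_equal(nrow(st), 39)
  cell <- table(st$mixture, st$treatment)
  expect_equal(cell["c75m25", "deep"], 3L)
  expect_true(all(cell[cbind(setdiff(rownames(cell), "c75m25"), "deep")] == 4L))
  expect_true(all(is.na(st$slope_deep[st$treatment == "mild"])))
  expect_true(all(!is.na(st$slope_deep[st$treatment == "deep"])))
})
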