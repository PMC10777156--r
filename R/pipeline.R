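#' Read and write pipeline CSV files
#'
#' Plain-CSV interfaces shared by all pipeline stages, so measured data can
#' replace the synthetic generator at either entry point: `nee_series.csv`
#' (`mesocosm_id, mixture, treatment, day, phase, nee_umol_m2_s`),
#' `design.csv` (`mesocosm_id, mixture, cuspidatum_fraction, treatment,
#' replicate`), and per-measurement trace files `(time_s, co2_ppm)`.
#'
#' @param series,design Tables to write.
#' @param path File path.
#' @return Readers return data.frames; writers return the path invisibly.
#' @name peatstab_io
NULL

#' @rdname peatstab_io
#' @export
write_nee_series <- function(series, path) {
  out <- series[, c("mesocosm_id", "mixture", "treatment", "day", "phase",
                    "nee")]
  names(out)[names(out) == "nee"] <- "nee_umol_m2_s"
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname peatstab_io
#' @export
read_nee_series <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("mesocosm_id", "day", "phase", "nee_umol_m2_s")
  if (!all(need %in% names(df))) {
    stop("nee_series csv must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  names(df)[names(df) == "nee_umol_m2_s"] <- "nee"
  class(df) <- c("nee_series", "data.frame")
  df
}

#' @rdname peatstab_io
#' @export
write_design <- function(design, path) {
  utils::write.csv(design[, c("mesocosm_id", "mixture",
                              "cuspidatum_fraction", "treatment",
                              "replicate")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname peatstab_io
#' @export
read_design <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$mixture <- factor(df$mixture, levels = mixture_levels())
  df$treatment <- factor(df$treatment, levels = treatment_levels())
  df
}

#' @rdname peatstab_io
#' @param trace A [concentration_trace()] (writer) .
#' @param chamber Chamber spec attached to traces on read.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(data.frame(time_s = trace$time_s,
                              co2_ppm = trace$co2_ppm),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname peatstab_io
#' @param mesocosm_id,day Identifiers attached to the trace on read.
#' @export
read_trace_csv <- function(path, chamber = chamber_spec(),
                           mesocosm_id = NA_character_, day = NA_integer_) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_s", "co2_ppm") %in% names(df))) {
    stop("trace csv must have columns time_s, co2_ppm", call. = FALSE)
  }
  concentration_trace(df$time_s, df$co2_ppm, chamber, mesocosm_id, day)
}

#' Run the full simulation-to-report pipeline
#'
#' Executes the whole analysis chain on synthetic data: build the
#' replacement-series design, generate per-mesocosm NEE series (optionally
#' routed through raw chamber traces and the flux computation), apply the
#' configured single-mesocosm missingness, derive per-mesocosm stability
#' statistics, and produce the group-level report tables. All outputs are
#' written as CSV under `out_dir` together with a machine-readable
#' `run_log.json` (seed, package version, config hash, stage record).
#' Stage failures abort with the failing stage named; outputs of completed
#' stages are retained.
#'
#' @param config A [generator_config()].
#' @param schedules Per-arm schedules (see [default_schedules()]).
#' @param out_dir Output directory (created if needed); `NULL` writes
#'   nothing.
#' @param via_traces If `TRUE`, every NEE value is converted to a raw 1 Hz
#'   chamber concentration trace and recomputed through the flux module
#'   before analysis (round-trip entry point; identical results to within
#'   numerical noise on noiseless traces).
#' @param trace_noise_sd_ppm Gaussian noise on synthetic traces (ppm) when
#'   `via_traces = TRUE`.
#' @return Invisible list: `design`, `nee`, `stability`, `slopes` (per-phase
#'   group tables), `anova`, `contrasts`, `run_log`.
#' @export
run_pipeline <- function(config = generator_config(),
                         schedules = default_schedules(),
                         out_dir = NULL,
                         via_traces = FALSE,
                         trace_noise_sd_ppm = 0) {
  stage <- "design"
  result <- tryCatch({
    design <- build_design(config$n_replicates, seed = config$seed)

    stage <- "simulate"
    nee <- generate_nee_series(design, schedules, config)

    if (via_traces) {
      stage <- "flux"
      chamber <- chamber_spec()
      traces <- lapply(seq_len(nrow(nee)), function(i) {
        generate_concentration_trace(nee$nee[i], chamber,
                                     noise_sd_ppm = trace_noise_sd_ppm,
                                     seed = if (trace_noise_sd_ppm > 0)
                                       config$seed + i else NULL,
                                     mesocosm_id = nee$mesocosm_id[i],
                                     day = nee$day[i])
      })
      fl <- batch_fluxes(traces)
      if (nrow(fl$errors) > 0) {
        stop("flux stage produced ", nrow(fl$errors), " error records",
             call. = FALSE)
      }
      key <- paste(nee$mesocosm_id, nee$day)
      fkey <- paste(fl$fluxes$mesocosm_id, fl$fluxes$day)
      nee$nee <- fl$fluxes$nee[match(key, fkey)]
    }

    stage <- "missingness"
    if (!is.null(config$drop_mesocosm)) {
      nee <- apply_missingness(nee, config$drop_mesocosm)
    }

    stage <- "stability"
    stability <- summarize_stability(nee, design, schedules)

    stage <- "report"
    slopes <- list(
      mild_drawdown = group_slope_table(stability, "mild_drawdown"),
      deep_drawdown = group_slope_table(stability, "deep_drawdown"),
      recovery = group_slope_table(stability, "recovery"))

    anova_rows <- list(
      slope_anova_row(stability$slope_mild, stability$mixture,
                      "slope_mild"),
      slope_anova_row(stability$slope_deep, stability$mixture,
                      "slope_deep"),
      slope_anova_row(stability$recovery_rate[stability$treatment == "mild"],
                      stability$mixture[stability$treatment == "mild"],
                      "recovery_rate_mild"),
      slope_anova_row(stability$recovery_rate[stability$treatment == "deep"],
                      stability$mixture[stability$treatment == "deep"],
                      "recovery_rate_deep"),
      slope_anova_row(stability$omega[!stability$omega_infinite],
                      stability$mixture[!stability$omega_infinite],
                      "omega"),
      slope_anova_row(stability$delta[!stability$delta_infinite],
                      stability$mixture[!stability$delta_infinite],
                      "delta"))
    anova_tab <- do.call(rbind, anova_rows)

    deep <- !is.na(stability$slope_deep)
    # pairwise contrasts need >= 2 members per group; a heavily reduced
    # design (after missingness) may not support them
    contrasts <- tryCatch(
      pairwise_contrasts(stability$slope_deep[deep],
                         stability$mixture[deep]),
      error = function(e) data.frame(pair = character(),
                                     estimate = numeric(), se = numeric(),
                                     t_statistic = numeric(),
                                     p_adjusted = numeric()))

    list(design = design, nee = nee, stability = stability, slopes = slopes,
         anova = anova_tab, contrasts = contrasts)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  result$run_log <- list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("peatstab")),
    r_version = as.character(getRversion()),
    n_replicates = config$n_replicates,
    noise_sd = config$noise_sd,
    via_traces = via_traces,
    dropped_mesocosm = if (is.null(config$drop_mesocosm)) NA_character_
                       else config$drop_mesocosm,
    n_mesocosms_analysed = nrow(result$stability),
    n_omega_infinite = sum(result$stability$omega_infinite),
    n_delta_infinite = sum(result$stability$delta_infinite),
    config_hash = config_hash(config)
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_design(result$design, file.path(out_dir, "design.csv"))
    write_nee_series(result$nee, file.path(out_dir, "nee_series.csv"))
    utils::write.csv(result$stability, file.path(out_dir, "stability.csv"),
                     row.names = FALSE)
    utils::write.csv(result$slopes$mild_drawdown,
                     file.path(out_dir, "table1_slopes_mild.csv"),
                     row.names = FALSE)
    utils::write.csv(result$slopes$deep_drawdown,
                     file.path(out_dir, "table1_slopes_deep.csv"),
                     row.names = FALSE)
    utils::write.csv(result$slopes$recovery,
                     file.path(out_dir, "recovery_rates.csv"),
                     row.names = FALSE)
    utils::write.csv(result$anova, file.path(out_dir, "anova.csv"),
                     row.names = FALSE)
    utils::write.csv(result$contrasts, file.path(out_dir, "contrasts.csv"),
                     row.names = FALSE)
    jsonlite::write_json(result$run_log,
                         file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(result)
}

# one tidy ANOVA row (mixture effect on a response); NA row when degenerate
slope_anova_row <- function(values, groups, response) {
  keep <- !is.na(values)
  res <- tryCatch(oneway_anova(values[keep], droplevels(factor(groups[keep]))),
                  error = function(e) NULL)
  if (is.null(res)) {
    return(data.frame(response = response, factor = "mixture",
                      df_between = NA_integer_, df_within = NA_integer_,
                      f_statistic = NA_real_, p_value = NA_real_,
                      stringsAsFactors = FALSE))
  }
  data.frame(response = response, factor = "mixture",
             df_between = res$df_between, df_within = res$df_within,
             f_statistic = res$f_statistic, p_value = res$p_value,
             stringsAsFactors = FALSE)
}

# stable hash of the configuration (content-addressed run log entry)
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config[setdiff(names(config), "seed")],
                              auto_unbox = TRUE, digits = NA, force = TRUE),
             tmp)
  unname(tools::md5sum(tmp))
}
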