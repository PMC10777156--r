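#' Canonical Sphagnum mixture compositions
#'
#' The replacement series varies the fractional cover of *S. cuspidatum*
#' against *S. medium* at constant total cover. The five canonical design
#' points are 100/0, 75/25, 50/50, 25/75 and 0/100 (% *S. cuspidatum* /
#' % *S. medium*).
#'
#' @return Character vector of mixture labels in design order
#'   (decreasing *S. cuspidatum* fraction).
#' @export
mixture_levels <- function() {
  c("c100", "c75m25", "c50m50", "c25m75", "m100")
}

#' @rdname mixture_levels
#' @return `cuspidatum_fractions()`: named numeric vector of *S. cuspidatum*
#'   cover fractions for the canonical mixtures.
#' @export
cuspidatum_fractions <- function() {
  stats::setNames(c(1, 0.75, 0.5, 0.25, 0), mixture_levels())
}

#' @rdname mixture_levels
#' @return `treatment_levels()`: the two water table drawdown treatments.
#' @export
treatment_levels <- function() {
  c("mild", "deep")
}

#' Mixture composition record
#'
#' @param cuspidatum_fraction Fractional cover of *S. cuspidatum* in `[0, 1]`.
#'   The *S. medium* fraction is the complement.
#' @return A list with `cuspidatum_fraction` and `medium_fraction`
#'   (summing to 1), of class `"mixture_composition"`.
#' @export
mixture_composition <- function(cuspidatum_fraction) {
  if (!is.numeric(cuspidatum_fraction) || length(cuspidatum_fraction) != 1 ||
      is.na(cuspidatum_fraction) ||
      cuspidatum_fraction < 0 || cuspidatum_fraction > 1) {
    stop("`cuspidatum_fraction` must be a single number in [0, 1]",
         call. = FALSE)
  }
  structure(
    list(cuspidatum_fraction = cuspidatum_fraction,
         medium_fraction = 1 - cuspidatum_fraction),
    class = "mixture_composition"
  )
}

#' Build the replacement-series experimental design
#'
#' Creates the mesocosm table for a two-species replacement series: five
#' mixture compositions x two drawdown treatments x `n_replicates`
#' mesocosms. Within each mixture the `2 * n_replicates` cores are randomly
#' assigned to the mild or deep drawdown arm by a seeded permutation, so
#' the assignment (the `core` column) is reproducible for a fixed seed.
#'
#' @param n_replicates Mesocosms per mixture x treatment cell (the study
#'   design uses 4, i.e. 40 cores in total).
#' @param seed Integer seed for the random treatment assignment.
#' @return A `data.frame` with one row per mesocosm: `mesocosm_id`,
#'   `mixture` (factor, design order), `cuspidatum_fraction`, `treatment`
#'   (factor `mild`/`deep`), `replicate`, and `core` (the within-mixture
#'   core number the treatment was assigned to).
#' @examples
#' design <- build_design(4, seed = 1)
#' nrow(design)            # 40
#' table(design$mixture)   # 8 per mixture
#' @export
build_design <- function(n_replicates = 4, seed = 1) {
  if (!is.numeric(n_replicates) || length(n_replicates) != 1 ||
      is.na(n_replicates) || n_replicates < 1 ||
      n_replicates != round(n_replicates)) {
    stop("`n_replicates` must be a positive integer", call. = FALSE)
  }
  n_replicates <- as.integer(n_replicates)
  set.seed(seed)
  mixes <- mixture_levels()
  frac <- cuspidatum_fractions()
  rows <- lapply(mixes, function(mix) {
    n_cores <- 2L * n_replicates
    # seeded permutation: which core receives which treatment arm
    cores <- sample.int(n_cores)
    data.frame(
      mixture = mix,
      cuspidatum_fraction = unname(frac[mix]),
      treatment = rep(treatment_levels(), each = n_replicates),
      replicate = rep(seq_len(n_replicates), times = 2L),
      core = cores,
      stringsAsFactors = FALSE
    )
  })
  design <- do.call(rbind, rows)
  design$mesocosm_id <- sprintf("%s_%s_r%d", design$treatment,
                                design$mixture, design$replicate)
  design$mixture <- factor(design$mixture, levels = mixes)
  design$treatment <- factor(design$treatment, levels = treatment_levels())
  design <- design[, c("mesocosm_id", "mixture", "cuspidatum_fraction",
                       "treatment", "replicate", "core")]
  rownames(design) <- NULL
  design
}
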