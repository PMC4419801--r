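#' Simulate a matched sweep-versus-neutral panel study
#'
#' Generates replicate panels under a hard sweep and under neutrality with
#' matched drift time. Sweep eras end when the beneficial allele reaches
#' `cfg$fix_sample_freq` ("sampling near fixation"), which under strong
#' selection takes far fewer generations than a fixed-length neutral era;
#' comparing statistics across conditions is only fair when both
#' conditions have accumulated the same test-versus-reference divergence.
#' The sweep replicates are therefore simulated first, and the neutral
#' replicates (and the neutral background used to estimate the XP-CLR
#' drift variance) are run with an era equal to the mean realized sweep
#' duration.
#'
#' @param cfg a neutral [sim_config()] template; its `n_generations`
#'   bounds the sweep era.
#' @param sweep list with `position`, `selection_coefficient` and
#'   optionally `start_frequency`, as in [sim_config()].
#' @param n_replicates sweep and neutral replicates (default 50).
#' @param n_background neutral background regions for the drift-variance
#'   estimate (default 30).
#' @param seed integer seed (`NULL`: current RNG).
#' @return list with `sweep` and `neutral` (lists of panels carrying
#'   reference samples), `background`, `drift_variance`, and
#'   `matched_era` (generations used for the neutral condition).
#' @export
simulate_sweep_study <- function(cfg, sweep, n_replicates = 50,
                                 n_background = 30, seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  cfg$seed <- NULL
  sw_cfg <- cfg
  sw_cfg$sweep <- sweep
  sw_cfg <- do.call(sim_config, sw_cfg[setdiff(names(sw_cfg), "seed")])
  sw <- vector("list", n_replicates)
  gens <- numeric(n_replicates)
  for (i in seq_len(n_replicates)) {
    sw[[i]] <- simulate_panel(sw_cfg, sample_reference = TRUE)
    gens[i] <- attr(sw[[i]], "gens_run")
  }
  era <- max(1L, as.integer(round(mean(gens))))
  nt_cfg <- cfg
  nt_cfg$n_generations <- era
  nt <- lapply(seq_len(n_replicates), function(i)
    simulate_panel(nt_cfg, sample_reference = TRUE))
  bg <- lapply(seq_len(n_background), function(i)
    simulate_panel(nt_cfg, sample_reference = TRUE))
  list(sweep = sw, neutral = nt, background = bg,
       drift_variance = estimate_drift_variance(bg),
       matched_era = era)
}
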