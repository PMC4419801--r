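#' Simulation configuration for haplotype panels
#'
#' Bundles the parameters of the forward-in-time Wright-Fisher simulator.
#' Rates are per base pair and per generation; the population is diploid
#' with constant size. A neutral burn-in of `burnin_factor * population_size`
#' generations establishes mutation-drift equilibrium before the
#' `n_generations` "era" during which an optional hard sweep runs.
#'
#' Defaults describe a deliberately small, desk-scale population
#' (2N = 200 haplotypes) with per-site rates scaled up so that a 50 kb
#' region at equilibrium segregates on the order of 150 variants in a
#' sample of 40 haplotypes — enough for every downstream statistic while
#' keeping thousands of replicate regions affordable.
#'
#' @param n_haplotypes sample size (phased haplotypes drawn from the
#'   population, without replacement).
#' @param region_length region size in bp.
#' @param mutation_rate per-bp, per-generation mutation rate (infinite
#'   sites: every mutation hits a new position and the founding allele is
#'   the known ancestral state).
#' @param recombination_rate per-bp, per-generation crossover rate; also
#'   defines the uniform genetic map (`cM = bp * rate * 100`).
#' @param population_size diploid population size N (2N haplotypes).
#' @param n_generations length of the post-burn-in era in generations. With
#'   a sweep the era ends early once the beneficial allele reaches
#'   `fix_sample_freq`.
#' @param burnin_factor neutral burn-in length in units of
#'   `population_size` generations (default 16, i.e. four times the mean
#'   time to the most recent common ancestor).
#' @param sweep `NULL` for neutral evolution, or a list with elements
#'   `position` (bp, inside the region), `selection_coefficient` (s > 0,
#'   multiplicative fitness `(1+s)^copies`) and optionally
#'   `start_frequency` (default `1/(2N)`, a single new copy).
#' @param fix_sample_freq population frequency of the beneficial allele at
#'   which the era stops and the sample is drawn (default 1 = fixation).
#' @param max_retries number of resimulations allowed when the beneficial
#'   allele is lost (conditioning on establishment), default 100.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_haplotypes = 40, region_length = 50000,
                       mutation_rate = 2e-6, recombination_rate = 1e-6,
                       population_size = 100, n_generations = 500,
                       burnin_factor = 16, sweep = NULL,
                       fix_sample_freq = 1.0, max_retries = 100,
                       seed = NULL) {
  stopifnot(n_haplotypes >= 2, region_length > 0, mutation_rate >= 0,
            recombination_rate >= 0, population_size >= 2,
            n_generations >= 0, burnin_factor >= 0,
            fix_sample_freq > 0, fix_sample_freq <= 1)
  if (n_haplotypes > 2 * population_size)
    stop("n_haplotypes cannot exceed 2 * population_size")
  if (!is.null(sweep)) {
    stopifnot(is.list(sweep), !is.null(sweep$position),
              !is.null(sweep$selection_coefficient))
    if (is.null(sweep$start_frequency))
      sweep$start_frequency <- 1 / (2 * population_size)
    stopifnot(sweep$position > 0, sweep$position <= region_length,
              sweep$selection_coefficient > 0,
              sweep$start_frequency > 0, sweep$start_frequency < 1)
  }
  structure(list(n_haplotypes = as.integer(n_haplotypes),
                 region_length = region_length,
                 mutation_rate = mutation_rate,
                 recombination_rate = recombination_rate,
                 population_size = as.integer(population_size),
                 n_generations = as.integer(n_generations),
                 burnin_factor = burnin_factor,
                 sweep = sweep,
                 fix_sample_freq = fix_sample_freq,
                 max_retries = as.integer(max_retries),
                 seed = seed),
            class = "sim_config")
}

#' Construct a haplotype panel
#'
#' Low-level constructor for the container consumed by all polymorphism
#' statistics: a 0/1 matrix of phased haplotypes (rows) by biallelic
#' variants (columns, sorted by position), with physical and genetic
#' coordinates, a per-variant flag saying whether the ancestral state is
#' known, and the derived allele frequency.
#'
#' @param haplotypes integer/numeric 0-1 matrix, rows = haplotypes.
#' @param positions_bp integer physical positions (1-based), one per column.
#' @param positions_cM genetic positions; defaults to `positions_bp * 1e-6`
#'   (1 cM/Mb) when `NULL`.
#' @param ancestral_known logical per-variant flag (default all `TRUE`).
#' @param region_length region size in bp.
#' @param ref_haplotypes optional reference-population matrix over the same
#'   columns (for cross-population scans).
#' @param sweep_col optional column index of a known beneficial variant.
#' @return an object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(haplotypes, positions_bp, positions_cM = NULL,
                            ancestral_known = NULL,
                            region_length = max(positions_bp, 1),
                            ref_haplotypes = NULL, sweep_col = NA_integer_) {
  haplotypes <- as.matrix(haplotypes)
  storage.mode(haplotypes) <- "integer"
  S <- ncol(haplotypes)
  stopifnot(length(positions_bp) == S)
  if (S > 1 && is.unsorted(positions_bp))
    stop("variant columns must be sorted by position")
  if (S && !all(haplotypes %in% c(0L, 1L)))
    stop("haplotypes must be a 0/1 matrix (biallelic, ancestral = 0)")
  if (is.null(positions_cM)) positions_cM <- positions_bp * 1e-6
  if (is.null(ancestral_known)) ancestral_known <- rep(TRUE, S)
  stopifnot(length(positions_cM) == S, length(ancestral_known) == S)
  if (!is.null(ref_haplotypes)) {
    ref_haplotypes <- as.matrix(ref_haplotypes)
    storage.mode(ref_haplotypes) <- "integer"
    stopifnot(ncol(ref_haplotypes) == S)
  }
  structure(list(haplotypes = haplotypes,
                 positions_bp = as.integer(round(positions_bp)),
                 positions_cM = as.numeric(positions_cM),
                 ancestral_known = as.logical(ancestral_known),
                 derived_freq = if (S) colMeans(haplotypes) else numeric(0),
                 region_length = region_length,
                 ref_haplotypes = ref_haplotypes,
                 sweep_col = sweep_col),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("haplotype_panel: %d haplotypes x %d variants over %g bp\n",
              nrow(x$haplotypes), ncol(x$haplotypes), x$region_length))
  if (!is.null(x$ref_haplotypes))
    cat(sprintf("  + reference panel of %d haplotypes\n",
                nrow(x$ref_haplotypes)))
  if (!is.na(x$sweep_col))
    cat(sprintf("  beneficial variant at column %d (%d bp, DAF %.2f)\n",
                x$sweep_col, x$positions_bp[x$sweep_col],
                x$derived_freq[x$sweep_col]))
  invisible(x)
}

#' Simulate a phased haplotype panel
#'
#' Runs the forward Wright-Fisher simulator described in [sim_config()] and
#' draws a sample of phased haplotypes. Under a sweep configuration the
#' simulation conditions on establishment: if the beneficial allele is lost
#' the era is resimulated from the same equilibrium state, up to
#' `cfg$max_retries` times, after which an error is raised.
#'
#' @param cfg a [sim_config()].
#' @param sample_reference also draw an independent sample before the era
#'   starts, mimicking a non-swept reference population for XP-CLR.
#' @param ancestral_known_fraction fraction of variants whose ancestral
#'   state is marked known (default 1; unknown sites are skipped by
#'   unfolded-spectrum statistics and iHS).
#' @param mispolarized_fraction fraction of variants whose ancestral and
#'   derived alleles are deliberately swapped (polarization error model;
#'   default 0).
#' @return a [haplotype_panel()]; attribute `retries` records how many
#'   resimulations establishment needed.
#' @export
simulate_panel <- function(cfg, sample_reference = FALSE,
                           ancestral_known_fraction = 1,
                           mispolarized_fraction = 0) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  sw <- cfg$sweep
  res <- wf_simulate_cpp(
    n_sample = cfg$n_haplotypes, L = cfg$region_length,
    mu = cfg$mutation_rate, rec = cfg$recombination_rate,
    N = cfg$population_size,
    burnin_gens = as.integer(round(cfg$burnin_factor * cfg$population_size)),
    era_gens = cfg$n_generations,
    ben_pos = if (is.null(sw)) -1 else sw$position - 0.5,
    s = if (is.null(sw)) 0 else sw$selection_coefficient,
    start_freq = if (is.null(sw)) 0 else sw$start_frequency,
    max_retries = cfg$max_retries, sample_ref = sample_reference,
    fix_sample_freq = cfg$fix_sample_freq)
  if (isTRUE(res$lost))
    stop("beneficial allele lost in all ", cfg$max_retries + 1,
         " attempts; increase selection_coefficient or max_retries")

  pos <- res$positions
  bp <- floor(pos) + 1L
  # continuous positions mapped to integer bp; break rare collisions
  if (anyDuplicated(bp)) for (i in seq_along(bp)[-1])
    if (bp[i] <= bp[i - 1L]) bp[i] <- bp[i - 1L] + 1L
  S <- length(bp)
  anc_known <- rep(TRUE, S)
  hap <- res$haplotypes
  ref <- res$ref_haplotypes
  if (S > 0 && ancestral_known_fraction < 1)
    anc_known <- runif(S) < ancestral_known_fraction
  if (S > 0 && mispolarized_fraction > 0) {
    flip <- which(runif(S) < mispolarized_fraction)
    hap[, flip] <- 1L - hap[, flip]
    if (!is.null(ref)) ref[, flip] <- 1L - ref[, flip]
  }
  out <- haplotype_panel(
    haplotypes = hap, positions_bp = bp,
    positions_cM = bp * cfg$recombination_rate * 100,
    ancestral_known = anc_known, region_length = cfg$region_length,
    ref_haplotypes = ref,
    sweep_col = if (res$ben_col > 0) res$ben_col else NA_integer_)
  attr(out, "retries") <- res$retries
  attr(out, "fixed") <- res$fixed
  attr(out, "gens_run") <- res$gens_run
  out
}

#' Generate a set of neutral background regions
#'
#' Simulates independent neutral panels and keeps only regions passing the
#' eligibility rule of at least `min_snvs` segregating variants,
#' resimulating ineligible draws. Used to build the empirical genomic
#' background against which gene-level scores are ranked.
#'
#' @param cfg a neutral [sim_config()] (any sweep component is ignored).
#' @param n_regions number of regions to return (>= 1).
#' @param min_snvs eligibility threshold on segregating variants
#'   (default 10).
#' @param sample_reference forwarded to [simulate_panel()].
#' @return a named list of [haplotype_panel()] objects
#'   (`region_0001`, ...).
#' @export
generate_background <- function(cfg, n_regions, min_snvs = 10,
                                sample_reference = FALSE) {
  stopifnot(inherits(cfg, "sim_config"), n_regions >= 1)
  cfg$sweep <- NULL
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  cfg$seed <- NULL  # seed once, then draw sequentially
  out <- vector("list", n_regions)
  for (i in seq_len(n_regions)) {
    repeat {
      p <- simulate_panel(cfg, sample_reference = sample_reference)
      if (n_polymorphic(p) >= min_snvs) break
    }
    out[[i]] <- p
  }
  names(out) <- sprintf("region_%04d", seq_len(n_regions))
  out
}

#' Number of polymorphic variants in a panel
#' @param panel a [haplotype_panel()].
#' @return integer count of columns segregating in the sample.
#' @export
n_polymorphic <- function(panel) {
  stopifnot(inherits(panel, "haplotype_panel"))
  sum(panel$derived_freq > 0 & panel$derived_freq < 1)
}
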