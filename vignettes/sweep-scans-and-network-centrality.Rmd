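---
title: "Sweep scans, empirical outlier calling, and network centrality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sweep scans, empirical outlier calling, and network centrality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweepnet)
```

# The scientific problem

Recent positive selection leaves three distinct footprints in population
genomic data: a skewed site frequency spectrum (an excess of rare variants
and of high-frequency derived variants around a fixed or nearly fixed
beneficial allele), unusually long haplotypes carrying the selected allele
(extended haplotype homozygosity), and sharp allele-frequency
differentiation between the selected population and a reference
population. `sweepnet` implements per-gene statistics for all three
footprints, converts them to empirical P values against a genomic
background, combines them into a single score, and then asks a systems
question: do genes called as selected sit at particular positions —
central hubs or the periphery — of a protein–protein interaction network?

This vignette documents the models, the tunable parameters and their
defaults, the behaviour of the synthetic data generator, and the numerical
and design decisions a careful reader will want to audit. Every empirical
claim made here is recomputed by the package's test suite or by
`scripts/acceptance.R`; the vignette itself asserts nothing the code does
not check.

# The statistics

## Site-frequency-spectrum statistics

For a sample of $n$ phased haplotypes with $S$ segregating sites,
`sfs_summary()` returns the mean pairwise difference
$\theta_\pi = \frac{n}{n-1}\sum_j 2 p_j (1-p_j)$, Watterson's
$\theta_W = S / a_1$ with $a_1 = \sum_{i<n} 1/i$, and — over sites with
known ancestral state — the homozygosity-weighted
$\theta_H = \sum_i 2 S_i i^2 / (n(n-1))$, where $S_i$ counts sites with
derived-allele count $i$.

* **Tajima's D** = $(\theta_\pi - \theta_W)/\sqrt{e_1 S + e_2 S(S-1)}$,
  with the 1989 normalizing constants. Sweeps (and growth) push D
  negative.
* **Fay & Wu's H** = $\theta_\pi - \theta_H$, the unnormalized form;
  hitchhiking around a fixed beneficial allele loads the high-frequency
  derived classes and pushes H strongly negative. We use the
  unnormalized H because the joint DH comparison below is empirical:
  only ranks matter, and the original definition keeps the arithmetic
  exact.
* **DH**: `dh_pvalue()` compares the observed $(D, H)$ pair to an
  empirical background of pairs and returns the add-one-corrected
  fraction that is at least as extreme in *both* coordinates. Joint
  extremity is what gives DH its robustness: population growth depresses
  D but not H, background selection depresses H but not D; only sweeps
  depress both.

A point that matters for calibration: the bivariate corner probability is
a *depth score*, not a uniformly distributed P value. If D and H were
independent, the null CDF of the corner mass $u$ would be
$u(1 - \log u)$ — at a nominal 0.05 about 20% of neutral regions fall
below it. `dh_pvalue()` therefore reports the corner probability exactly
as defined, and the gene-scoring pipeline (`score_genes()`) ranks each
gene's corner probability against the corner probabilities of the
background regions themselves. That second, empirical transform is
uniform under exchangeability and is what enters the Fisher combination.

## EHH and iHS

`ehh()` computes, for the carriers of one allele at a core variant, the
probability that two randomly drawn carrier haplotypes are identical at
every marker between the core and a distance $x$. `ihs_raw()` integrates
the decay curves of the ancestral- and derived-allele carrier sets in
both directions by trapezoids over physical distance and reports
$\ln(\mathrm{iHH}_A / \mathrm{iHH}_D)$.

Numerical conventions:

* integration is truncated at the first crossing of the EHH threshold
  (default **0.15**), with the crossing point linearly interpolated, or
  at the edge of the analyzed window (default **0.2 Mb total**, i.e.
  $\pm 100$ kb around the core), or at the last marker in the region,
  whichever comes first;
* markers that do not split the current carrier set keep the previous
  EHH value but still serve as interpolation nodes (as in genotype-based
  scans); columns monomorphic in the whole panel are skipped, which
  makes the integral invariant to their presence;
* cores need a known ancestral state and at least two carriers of each
  allele, otherwise they are unscorable and skipped.

Raw scores are standardized within derived-allele-frequency bins of
width **0.05** (20 bins): subtract the bin mean, divide by the bin
standard deviation (population form, so the standardized set has exactly
mean 0 and SD 1). Bins with fewer than 2 scores or zero spread give
`NA`. Both strongly positive and strongly negative standardized scores
signal selection, so gene-level summaries use the mean of $|iHS|$.

## XP-CLR

`xpclr_scan()` evaluates, at grid points every **2 kb**, a composite
likelihood ratio contrasting neutral drift against a hard sweep at the
grid point, using SNVs within a flanking window of **0.2 cM** (total),
thinned at random to at most **200** per window. Under neutrality the
test-population frequency follows a normal around the reference
frequency $p_1$ with variance $\omega p_1(1-p_1)$, truncated to $(0,1)$
with the clipped tails as point masses at loss and fixation, and the
observed derived count is binomial. Under a sweep of strength $s$, a
lineage at map distance $r$ escapes with probability
$c = 1 - \exp(-(r/s)\log(2 N_e s))$, and the pre-sweep frequency $u$
maps to $cu$ (escape, probability $1-u$) or $1-c+cu$ (hitchhike,
probability $u$). The score is twice the composite log-likelihood gain
of the best $s$ on a 10-point logarithmic grid (default
$[0.005, 0.5]$), clamped at zero. The frequency integral uses 32
Gauss–Legendre nodes; likelihoods are floored at $10^{-300}$ before
logs.

Two practical points, both visible in the tests:

* $\omega$ must come from *neutral background* regions
  (`estimate_drift_variance()`, a sampling-variance-corrected
  ratio-of-sums moment estimator). Estimating it from the scanned
  region itself absorbs the sweep's differentiation into the neutral
  model and destroys power.
* at the scale of the bundled simulator the hitchhiking footprint
  $\sim s/(r \ln 2N_e s)$ exceeds a whole simulated region, so XP-CLR
  separates swept from neutral *regions* sharply but cannot localize
  the sweep *within* a region; the tests therefore assert elevation at
  the sweep's grid point and of the regional peak, not localization.

## Gene-level combination

`score_genes()` applies the outlier logic: summarize per gene (mean
$|iHS|$ over scorable SNVs, mean XP-CLR over grid points, the $(D,H)$
pair), turn each summary into an empirical P value against the
background distribution (add-one-corrected upper-tail rank;
the calibrated DH rank described above), and combine the three with
Fisher's method: $Z_F = -2\sum_{i=1}^{3}\ln P_i$, referred to
$\chi^2_6$. A gene is called selected when the combined P falls strictly
below $\alpha = 0.05$. Genes with fewer than 10 variants, or missing
any component, carry no call (no imputation). The combination assumes
the three P values are independent; the conditions under which that is
approximately true of the synthetic data are discussed below.

## McDonald–Kreitman, DAF, divergence and association modules

* `classify_degeneracy()` labels coding sites 0-fold (every change
  nonsynonymous) or 4-fold (every change synonymous) under the standard
  genetic code, dropping sites whose class depends on the transcript.
* `polarized_counts()` assigns fixed differences to the focal lineage
  when the focal base differs from two agreeing outgroups, splitting
  polymorphism and divergence counts into N/S classes;
  `neutrality_index()` returns $NI = (P_N/P_S)/(D_N/D_S)$, switching to
  the Haldane-corrected form (0.5 added to each cell) whenever any cell
  is zero; `mk_fisher()` is the two-sided exact test. Genes need more
  than three counts in every cell to be reported (`mk_eligible()`).
* `gene_daf_summary()` returns the mean derived-allele frequency per
  gene (purifying-selection proxy: constraint keeps derived alleles
  rare) or per-site-class maxima (cis-eQTL within 100 kb of the gene
  body, 0-fold, 4-fold), and `daf_class_test()` asks by permutation
  whether selected genes have higher class-maximum DAF medians than
  same-size random gene sets.
* `unique_substitution_flags()` / `window_mask()` / `apply_mask()`
  implement the alignment sanitizer: residues unique to one species in
  a column are flagged, and windows of 15 residues with ≥ 10 flags, or
  5 residues with 5 flags, in a single sequence mark their full
  alignment-column span for removal. Windows slide by one residue over
  the *ungapped* positions of the flagged sequence (a documented choice;
  the alternative — gapped coordinates — misses bursts interrupted by
  gaps). The mask is the union over rules and sequences.
* `m7m8_lrt()` computes $2\Delta\ell = 2(\ell_{M8} - \ell_{M7})$ from
  externally supplied log-likelihoods and refers it to $\chi^2_2$
  (upper tail $e^{-x/2}$), clamping negative differences to zero.
* the association module provides the permutation test on group mean
  degree, Spearman correlation with midranks and the t approximation,
  quartile binning (boundary values to the lower group), ANOVA and
  linear trend tests on ranks, OLS confounder residualization (protein
  length, expression level, expression breadth), and the two-sided
  Mann–Whitney test for essentiality contrasts. All empirical P values
  use the add-one correction and are two-sided unless stated.

# The synthetic-data generator

`simulate_panel()` runs a forward-in-time Wright–Fisher simulation:
diploid population of constant size $N$ (default 100; 2N = 200
haplotypes), infinite-sites mutation (per-bp rate, default
$2\times10^{-6}$), uniform crossover recombination (default
$10^{-6}$/bp, which also defines the genetic map), a neutral burn-in of
$16 N$ generations (four times the expected time to the most recent
common ancestor), then an "era" during which an optional beneficial
mutation with multiplicative fitness $(1+s)^{\text{copies}}$ runs from
a chosen starting frequency, conditioned on establishment by
resimulation (up to 100 retries). The founder allele is the known
ancestral state, so derived-allele frequencies are exact; optional
toggles hide or mispolarize a fraction of sites. A reference sample can
be drawn just before the era, mimicking a population that did not
experience the sweep.

The defaults are deliberately scaled down from human values: with
$2N = 200$, per-generation rates must be inflated so that
$\theta = 4N\mu L$ and $\rho = 4NrL$ per region land in a realistic
range (tens of segregating sites, several recombination units per
region). Equivalently, one simulated generation stands for many real
ones; selection coefficients of 0.25–0.5 in this scaled time correspond
to strong but plausible real-world sweeps. The generator does **not**
model demography (growth, bottlenecks), soft sweeps, polygenic
adaptation or sequencing error, so passing tests demonstrate
correctness of the statistics under the hard-sweep model, not
robustness to demographic confounding — the property the empirical
background approach is designed to supply with real data.

Two design points deserve emphasis:

* **Matched drift time.** A sweep era ends when the beneficial allele
  reaches near-fixation — tens of generations under strong selection —
  while a fixed-length neutral era accumulates far more
  reference-versus-test drift. Comparing sweep panels to neutral panels
  with unequal drift time biases every cross-population statistic.
  `simulate_sweep_study()` therefore simulates the sweep replicates
  first and gives the neutral replicates (and the background used for
  $\omega$) an era equal to the mean realized sweep duration.
* **Near-fixation sampling.** iHS contrasts ancestral and derived
  haplotype homozygosity, so it loses definition once the swept allele
  fixes. Sweep studies sample at a beneficial-allele frequency of 0.9
  by default (`fix_sample_freq`), where D, H, iHS and XP-CLR all carry
  signal.

`generate_background()` produces independent neutral regions satisfying
the eligibility rule of at least 10 variants (regenerating failures),
`generate_pin()` grows a Barabási–Albert scale-free network,
`assign_sweeps_by_centrality()` assigns ground-truth sweep status with
logit-linear coupling to standardized degree, `generate_msa()` builds
near-identical ortholog alignments with species-private error bursts
and a truth mask, and `generate_mk_counts()` draws Poisson MK tables.

# Calibration study conditions

The null-calibration check simulates 2,000 "gene" regions and 10,000
background regions under one neutral model (sample 20 haplotypes,
region 20 kb, $\mu = 2\times10^{-6}$, $r = 4\times10^{-6}$, $N = 50$,
era 4 generations) and requires the fraction of genes called selected
at $\alpha = 0.05$ to match 0.05 within three binomial standard errors.

Fisher's combination assumes the three per-gene P values are
independent. That assumption is a property of the data-generating
conditions, not of the code, and three features of the study design are
what make it hold approximately here; each is diagnosed by the
correlation structure of the component P values and documented so a
user can re-check it under other conditions.

* **SNV-stratified ranking.** The realized tree length of a region
  drives its SNV count together with D, H, haplotype homozygosity and
  frequency drift, making all three component P values co-vary with S.
  `score_genes()` therefore ranks each gene against background regions
  in the same SNV-count quantile stratum (10 strata by default),
  removing the common cause; pooled ranking (`snv_strata = 1`) remains
  available and is what a genome-scale analysis with hugely variable
  gene lengths would diagnose first.
* **Within-region recombination** ($\rho \approx 16$ per region here)
  prevents all statistics from riding a single shared genealogy.
* **Recent reference divergence** (era $\approx 0.02 \times 2N$
  generations, at the low end of human continental population-pair
  divergence) keeps the DH statistics and XP-CLR from sharing drift
  noise; with ten times that divergence the DH–XP-CLR rank correlation
  grows to $\sim 0.18$ and the caller over-rejects by one to two
  percentage points — a quantified warning about applying the plain
  Fisher combination to strongly diverged population pairs.

The problem sizes used throughout the tests (regions of 10–50 kb, $2N$
of 100–200, tens of replicates) were chosen as the smallest at which
the expected effects are comfortably resolved.

The second distributional check draws 100,000 uniform P-value triples,
applies the combination formula, and identifies the matching chi-square
reference distribution by moment matching (df = sample mean) with a
Kolmogorov–Smirnov confirmation; the selected df is 6.

# Known limitations

* Exchangeability, not realism: calibration holds because genes and
  background are simulated identically; with real data the background
  gene set carries its own ascertainment quirks, which the empirical
  ranking absorbs only to first order.
* Even under the calibration conditions a residual rank correlation of
  roughly 0.1 between the DH and iHS components remains — both read the
  same genealogy — so the combined caller can run mildly anticonservative
  (tenths of a percentage point to about one point at the 5% threshold).
* The XP-CLR neutral model treats the observed reference frequency as
  the true contemporary frequency; with small reference samples the
  unmodelled sampling noise inflates scores at ref-rare sites, which the
  background-estimated $\omega$ absorbs on average but not per site.
* Composite likelihoods are not likelihoods: XP-CLR scores are ranks,
  never nominal chi-square P values, and are only used empirically.
* The association stage treats gene scores as exchangeable units; it
  does not model linkage between neighbouring genes (the
  gene-thinning robustness analysis is out of scope).
* The M7-vs-M8 caller consumes external log-likelihoods; it does not
  refit codon models, and inherits whatever optimization noise the
  upstream fits carry (negative $2\Delta\ell$ is clamped to zero).
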