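test_that("zero mutation rate yields a variant-free panel", {
  cfg <- sim_config(n_haplotypes = 10, region_length = 1000,
                    mutation_rate = 0, recombination_rate = 1e-6,
                    population_size = 20, burnin_factor = 2,
                    n_generations = 10, seed = 1)
  p <- simulate_panel(cfg)
  expect_equal(ncol(p$haplotypes), 0)
  expect_equal(n_polymorphic(p), 0)
})

test_that("panels are deterministic under a fixed seed", {
  cfg <- small_cfg(seed = 11)
  p1 <- simulate_panel(cfg, sample_reference = TRUE)
  p2 <- simulate_panel(cfg, sample_reference = TRUE)
  expect_identical(p1$haplotypes, p2$haplotypes)
  expect_identical(p1$positions_bp, p2$positions_bp)
  expect_identical(p1$ref_haplotypes, p2$ref_haplotypes)
  cfg$seed <- 12
  p3 <- simulate_panel(cfg)
  expect_false(identical(p1$positions_bp, p3$positions_bp))
})

test_that("neutral equilibrium panels have mean D and H near zero", {
  cfg <- small_cfg()
  set.seed(2024)
  n_rep <- 200
  D <- H <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    s <- sfs_summary(simulate_panel(cfg))
    D[i] <- tajimas_d(s)
    H[i] <- fay_wu_h(s)
  }
  expect_lt(abs(mean(D, na.rm = TRUE)),
            3 * sd(D, na.rm = TRUE) / sqrt(sum(!is.na(D))))
  expect_lt(abs(mean(H, na.rm = TRUE)),
            3 * sd(H, na.rm = TRUE) / sqrt(sum(!is.na(H))))
})

test_that("sweep panels sampled near fixation depress D and H", {
  cfg <- small_cfg()
  cfg$fix_sample_freq <- 0.9
  cfg$sweep <- list(position = 5000, selection_coefficient = 0.5,
                    start_frequency = 0.01)
  cfg <- do.call(sim_config, unclass(cfg))
  set.seed(7)
  n_rep <- 30
  D <- H <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    s <- sfs_summary(simulate_panel(cfg))
    D[i] <- tajimas_d(s)
    H[i] <- fay_wu_h(s)
  }
  expect_lt(mean(D, na.rm = TRUE), -0.5)
  expect_lt(mean(H, na.rm = TRUE), 0)
})

test_that("background regions all pass the 10-variant eligibility rule", {
  cfg <- sim_config(n_haplotypes = 20, region_length = 2000,
                    mutation_rate = 2e-6, recombination_rate = 1e-6,
                    population_size = 50, burnin_factor = 8,
                    n_generations = 10, seed = 31)
  bg <- generate_background(cfg, 3)
  expect_length(bg, 3)
  expect_true(all(vapply(bg, n_polymorphic, integer(1)) >= 10))
  bg2 <- generate_background(cfg, 3)
  expect_identical(bg[[2]]$haplotypes, bg2[[2]]$haplotypes)
  expect_error(generate_background(cfg, 0))
})

test_that("scale-free network generation is connected and heavy-tailed", {
  g <- generate_pin(5, 1, seed = 3)
  expect_equal(igraph::ecount(g), 4)
  expect_true(igraph::is_connected(g))
  g2 <- generate_pin(2000, 3, seed = 4)
  deg <- igraph::degree(g2)
  expect_gt(max(deg), 10 * median(deg))
  g3 <- generate_pin(2000, 3, seed = 4)
  expect_identical(igraph::as_edgelist(g2), igraph::as_edgelist(g3))
})

test_that("sweep assignment couples to degree with the requested sign", {
  g <- generate_pin(1500, 3, seed = 9)
  deg <- igraph::degree(g)
  set.seed(10)
  d_pos <- d_neg <- rho0 <- numeric(10)
  for (i in 1:10) {
    fp <- assign_sweeps_by_centrality(g, coupling_effect = 2)
    fn <- assign_sweeps_by_centrality(g, coupling_effect = -2)
    f0 <- assign_sweeps_by_centrality(g, coupling_effect = 0)
    d_pos[i] <- mean(deg[fp]) - mean(deg[!fp])
    d_neg[i] <- mean(deg[fn]) - mean(deg[!fn])
    rho0[i] <- suppressWarnings(cor(deg, f0, method = "spearman"))
  }
  expect_gt(mean(d_pos), 0)
  expect_lt(mean(d_neg), 0)
  expect_lt(abs(mean(rho0)), 0.05)
})

test_that("synthetic alignments mark exactly the injected burst columns", {
  a0 <- generate_msa(5, 40, seed = 21)
  expect_false(any(attr(a0, "truth_mask")))
  bursts <- list(list(sequence = 3, start = 11, length = 10))
  a1 <- generate_msa(5, 40, error_bursts = bursts, seed = 21)
  expect_equal(which(attr(a1, "truth_mask")), 11:20)
  # burst residues are unique to that sequence in their columns
  for (j in 11:20)
    expect_false(a1[3, j] %in% a1[-3, j])
  a2 <- generate_msa(5, 40, error_bursts = bursts, seed = 21)
  expect_identical(unclass(a1)[, ], unclass(a2)[, ])
  expect_error(generate_msa(5, 40, error_bursts = list(
    list(sequence = 1, start = 1, length = 5),
    list(sequence = 1, start = 3, length = 5))), "overlap")
})

test_that("simulated MK tables follow their Poisson truth", {
  expect_equal(with(generate_mk_counts(c(0, 0), c(0, 0), seed = 1),
                    c(P_N, P_S, D_N, D_S)), c(0L, 0L, 0L, 0L))
  c1 <- generate_mk_counts(c(8, 4), c(6, 3), seed = 5)
  c2 <- generate_mk_counts(c(8, 4), c(6, 3), seed = 5)
  expect_identical(unclass(c1), unclass(c2))
  # balanced rates: mean NI over many replicates near 1 (Haldane-corrected
  # draws included); oracle is direct Monte-Carlo over the Poisson model
  set.seed(42)
  ni <- replicate(4000, generate_mk_counts(c(20, 20), c(20, 20))$NI)
  expect_lt(abs(median(ni) - 1), 0.1)
})

test_that("mispolarization and unknown-ancestral toggles behave", {
  cfg <- small_cfg(seed = 77)
  p <- simulate_panel(cfg)
  cfg$seed <- 77
  q <- simulate_panel(cfg, ancestral_known_fraction = 0.5)
  expect_lt(sum(q$ancestral_known), ncol(q$haplotypes))
  cfg$seed <- 77
  r <- simulate_panel(cfg, mispolarized_fraction = 1)
  expect_equal(r$derived_freq, 1 - p$derived_freq, tolerance = 1e-12)
})
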