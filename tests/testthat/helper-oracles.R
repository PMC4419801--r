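# Independent brute-force oracles used to pin down expected values.
# These deliberately avoid the package's own computation paths.

# mean number of pairwise differences between haplotype rows
pairwise_pi_oracle <- function(hap) {
  n <- nrow(hap)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    tot <- tot + sum(hap[i, ] != hap[j, ])
  tot / choose(n, 2)
}

# betweenness by exhaustive enumeration of all shortest paths between all
# unordered pairs (endpoint-excluded, unnormalized)
betweenness_oracle <- function(adj) {
  n <- nrow(adj)
  btw <- numeric(n)
  all_shortest <- function(s, t) {
    # BFS from s recording predecessors, then enumerate paths to t
    dist <- rep(Inf, n); dist[s] <- 0
    preds <- vector("list", n)
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in which(adj[v, ] == 1)) {
        if (dist[w] == Inf) {
          dist[w] <- dist[v] + 1
          preds[[w]] <- v
          queue <- c(queue, w)
        } else if (dist[w] == dist[v] + 1) {
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    if (!is.finite(dist[t])) return(list())
    walk <- function(v) {
      if (v == s) return(list(s))
      unlist(lapply(preds[[v]], function(p)
        lapply(walk(p), function(pp) c(pp, v))), recursive = FALSE)
    }
    walk(t)
  }
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    paths <- all_shortest(s, t)
    if (length(paths) == 0) next
    inner <- unlist(lapply(paths, function(p) p[-c(1, length(p))]))
    if (length(inner))
      for (v in unique(inner))
        btw[v] <- btw[v] + sum(inner == v) / length(paths)
  }
  btw
}

# two-sided Fisher exact P by hypergeometric enumeration
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exhaustive two-sided permutation P for a mean difference
perm_exact_oracle <- function(values, labels) {
  k <- sum(labels)
  obs <- mean(values[labels]) - mean(values[!labels])
  combs <- combn(length(values), k)
  ge <- 0
  for (i in seq_len(ncol(combs))) {
    idx <- combs[, i]
    d <- mean(values[idx]) - mean(values[-idx])
    if (abs(d) >= abs(obs) - 1e-12) ge <- ge + 1
  }
  ge / ncol(combs)
}

# exhaustive sliding-window mask (no gap handling)
window_mask_oracle <- function(flags, rules) {
  L <- ncol(flags)
  mask <- rep(FALSE, L)
  for (i in seq_len(nrow(flags))) for (rule in rules) {
    w <- rule[["window"]]; mf <- rule[["min_flags"]]
    if (L < w) next
    for (s in seq_len(L - w + 1))
      if (sum(flags[i, s:(s + w - 1)]) >= mf)
        mask[s:(s + w - 1)] <- TRUE
  }
  mask
}

# build a small panel by hand; rows of `hap` are haplotypes
make_panel <- function(hap, pos = NULL, region_length = NULL, ...) {
  hap <- as.matrix(hap)
  if (is.null(pos)) pos <- seq_len(ncol(hap)) * 100L
  if (is.null(region_length)) region_length <- max(pos) + 100
  haplotype_panel(hap, pos, region_length = region_length, ...)
}

# fast neutral config used across tests
small_cfg <- function(...) {
  sim_config(n_haplotypes = 40, region_length = 10000,
             mutation_rate = 2e-6, recombination_rate = 1e-6,
             population_size = 50, burnin_factor = 10,
             n_generations = 50, ...)
}
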