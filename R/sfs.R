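#' Site-frequency-spectrum summary of a panel region
#'
#' Computes the classical diversity estimators from a [haplotype_panel()]:
#' segregating sites S, mean pairwise differences (theta-pi), Watterson's
#' theta (S/a1), and the homozygosity-weighted theta-H of the unfolded
#' spectrum. S, theta-pi and theta-W use every polymorphic site; the
#' unfolded quantities (`xi`, `theta_H`, `theta_pi_unfolded`) use only
#' sites with known ancestral state, since the derived-allele count is
#' undefined elsewhere.
#'
#' theta-pi is computed as `sum(2 * p * (1-p)) * n/(n-1)` over sites
#' (p = sample derived/minor frequency), which equals the average number of
#' pairwise differences between haplotypes.
#'
#' @param panel a [haplotype_panel()].
#' @param region optional `c(start, end)` in bp (1-based, inclusive)
#'   restricting the variants used.
#' @return an object of class `sfs_summary` with fields `n`, `S`,
#'   `theta_pi`, `theta_W`, `theta_H`, `theta_pi_unfolded`, `xi`
#'   (unfolded SFS counts for derived counts 1..n-1) and `S_unfolded`.
#' @export
sfs_summary <- function(panel, region = NULL) {
  stopifnot(inherits(panel, "haplotype_panel"))
  keep <- panel$derived_freq > 0 & panel$derived_freq < 1
  if (!is.null(region))
    keep <- keep & panel$positions_bp >= region[1] &
      panel$positions_bp <= region[2]
  h <- panel$haplotypes[, keep, drop = FALSE]
  n <- nrow(panel$haplotypes)
  S <- ncol(h)
  a1 <- sum(1 / seq_len(n - 1))
  p <- if (S) colMeans(h) else numeric(0)
  theta_pi <- sum(2 * p * (1 - p)) * n / (n - 1)
  anc <- panel$ancestral_known[keep]
  cnt <- round(p[anc] * n)                       # derived-allele counts
  xi <- tabulate(cnt, nbins = n - 1)
  theta_H <- sum(2 * xi * seq_len(n - 1)^2) / (n * (n - 1))
  theta_pi_unf <- sum(2 * xi * seq_len(n - 1) * (n - seq_len(n - 1))) /
    (n * (n - 1))
  structure(list(n = n, S = S,
                 theta_pi = theta_pi,
                 theta_W = S / a1,
                 theta_H = theta_H,
                 theta_pi_unfolded = theta_pi_unf,
                 xi = xi, S_unfolded = sum(xi)),
            class = "sfs_summary")
}

#' @export
print.sfs_summary <- function(x, ...) {
  cat(sprintf(
    "sfs_summary: n=%d S=%d theta_pi=%.4f theta_W=%.4f theta_H=%.4f\n",
    x$n, x$S, x$theta_pi, x$theta_W, x$theta_H))
  invisible(x)
}

#' Tajima's D
#'
#' The normalized difference between mean pairwise diversity and
#' Watterson's theta, using the 1989 constants (a1, a2, b1, b2, c1, c2,
#' e1, e2). Negative values indicate an excess of rare variants, the
#' footprint expected under a recent hard sweep (or population growth).
#'
#' @param summary an [sfs_summary()].
#' @return Tajima's D, or `NA_real_` when undefined (S = 0 or n < 4);
#'   regions that sparse are excluded upstream by the 10-variant filter.
#' @export
tajimas_d <- function(summary) {
  stopifnot(inherits(summary, "sfs_summary"))
  n <- summary$n; S <- summary$S
  if (S < 1 || n < 4) return(NA_real_)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (summary$theta_pi - summary$theta_W) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Fay and Wu's H
#'
#' The unnormalized H = theta-pi - theta-H over sites with known ancestral
#' state. Strongly negative values indicate an excess of high-frequency
#' derived alleles, the signature of hitchhiking after a sweep.
#'
#' @param summary an [sfs_summary()].
#' @return H, or `NA_real_` when no ancestral-informed segregating site is
#'   available.
#' @export
fay_wu_h <- function(summary) {
  stopifnot(inherits(summary, "sfs_summary"))
  if (summary$S_unfolded < 1) return(NA_real_)
  summary$theta_pi_unfolded - summary$theta_H
}

#' Empirical bivariate DH P value
#'
#' Joint test of Tajima's D and Fay and Wu's H: the observed pair is
#' compared with an empirical background of (D, H) pairs, and the P value
#' is the add-one-corrected fraction of background pairs at least as
#' extreme in BOTH coordinates (both D and H less than or equal to the
#' observed values). Requiring joint extremity gives DH its robustness to
#' demography, since growth depresses D and background selection depresses
#' H, but only sweeps depress both.
#'
#' @param observed numeric `c(D, H)`.
#' @param background two-column matrix or data.frame of background (D, H)
#'   pairs; rows with non-finite entries are dropped.
#' @return P in (0, 1]: `(1 + k) / (1 + N)` where k counts jointly
#'   more-extreme background pairs.
#' @export
dh_pvalue <- function(observed, background) {
  stopifnot(length(observed) == 2, all(is.finite(observed)))
  bg <- as.matrix(background)
  stopifnot(ncol(bg) == 2)
  bg <- bg[is.finite(bg[, 1]) & is.finite(bg[, 2]), , drop = FALSE]
  if (nrow(bg) == 0) stop("empty background distribution")
  k <- sum(bg[, 1] <= observed[1] & bg[, 2] <= observed[2])
  (1 + k) / (1 + nrow(bg))
}
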