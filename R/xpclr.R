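#' Configuration for the XP-CLR scan
#'
#' @param grid_spacing_bp spacing of the grid points at which the composite
#'   likelihood ratio is evaluated (default 2,000 bp).
#' @param window_cM total genetic width of the flanking window around each
#'   grid point (default 0.2 cM, i.e. +/- 0.1 cM).
#' @param max_snvs maximum number of SNVs used per window; windows with
#'   more are randomly thinned (default 200).
#' @param s_grid candidate selection coefficients over which the sweep
#'   model is maximized; default a 10-point logarithmic grid on
#'   [0.005, 0.5].
#' @param drift_variance the variance inflation omega of the test
#'   population's allele frequency around the reference frequency
#'   (frequency variance = omega * p * (1-p)); `NULL` estimates it from
#'   the scanned region by method of moments, see
#'   [estimate_drift_variance()].
#' @param ne effective diploid size entering the sweep-duration
#'   approximation (default 100, matching the simulator's default).
#' @param quad_points Gauss-Legendre nodes for the frequency integral
#'   (default 32).
#' @param seed integer seed controlling SNV thinning (`NULL`: current RNG).
#' @return an object of class `xpclr_config`.
#' @export
xpclr_config <- function(grid_spacing_bp = 2000, window_cM = 0.2,
                         max_snvs = 200, s_grid = NULL,
                         drift_variance = NULL, ne = 100,
                         quad_points = 32, seed = NULL) {
  stopifnot(grid_spacing_bp > 0, window_cM > 0, max_snvs >= 1,
            ne >= 2, quad_points >= 8)
  if (is.null(s_grid))
    s_grid <- exp(seq(log(0.005), log(0.5), length.out = 10))
  stopifnot(all(s_grid > 0))
  structure(list(grid_spacing_bp = grid_spacing_bp, window_cM = window_cM,
                 max_snvs = as.integer(max_snvs), s_grid = s_grid,
                 drift_variance = drift_variance, ne = ne,
                 quad_points = as.integer(quad_points), seed = seed),
            class = "xpclr_config")
}

#' Method-of-moments estimate of the drift variance omega
#'
#' Under neutral drift the test-population frequency p2 scatters around the
#' reference frequency p1 with variance omega * p1 * (1 - p1). Using sites
#' polymorphic in the reference sample, the estimator averages
#' `(p1 - p2)^2` corrected for binomial sampling noise in both samples and
#' divides by the average `p1 * (1 - p1)` (a ratio of sums, which is robust
#' to near-fixed sites). Pool several neutral background panels for a
#' stable genome-wide estimate.
#'
#' @param panels a [haplotype_panel()] with a reference sample, or a list
#'   of such panels.
#' @return omega (clamped below at 1e-3).
#' @export
estimate_drift_variance <- function(panels) {
  if (inherits(panels, "haplotype_panel")) panels <- list(panels)
  num <- 0; den <- 0
  for (p in panels) {
    if (is.null(p$ref_haplotypes)) stop("panel lacks a reference sample")
    p1 <- colMeans(p$ref_haplotypes)
    p2 <- p$derived_freq
    n1 <- nrow(p$ref_haplotypes); n2 <- nrow(p$haplotypes)
    use <- p1 > 0 & p1 < 1
    num <- num + sum((p1[use] - p2[use])^2 -
                       p1[use] * (1 - p1[use]) / n1 -
                       p2[use] * (1 - p2[use]) / n2)
    den <- den + sum(p1[use] * (1 - p1[use]))
  }
  if (den <= 0) stop("no reference-polymorphic sites to estimate omega")
  max(num / den, 1e-3)
}

# run expr with a temporary RNG stream; leaves the caller's RNG untouched
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", globalenv())) runif(1)
  old <- get(".Random.seed", globalenv())
  on.exit(assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

#' Cross-population composite likelihood ratio (XP-CLR) scan
#'
#' At regularly spaced grid points, contrasts a hard-sweep model of
#' allele-frequency differentiation against neutral drift, composited over
#' the SNVs of a flanking genetic window. Under neutrality the test
#' frequency is modelled as a normal around the reference frequency with
#' variance `omega * p1 * (1-p1)`, truncated to (0, 1) with the clipped
#' tails as point masses at fixation/loss, and the observed derived count
#' is binomial. Under a sweep of strength s at the grid point, a lineage at
#' map distance r escapes the sweep with probability
#' `c = 1 - exp(-(r/s) * log(2*Ne*s))`; the pre-sweep frequency u is
#' distorted to `c*u` (escaped, probability 1-u) or `1 - c + c*u`
#' (hitchhiked, probability u). The score is
#' `2 * (max over s of the sweep composite log-likelihood - the neutral
#' composite log-likelihood)`, clamped at zero.
#'
#' @param test_panel a [haplotype_panel()] for the test population.
#' @param ref_panel a [haplotype_panel()] for the reference population, or
#'   `NULL` to use `test_panel$ref_haplotypes`. Only sites polymorphic in
#'   the reference sample are used.
#' @param cfg an [xpclr_config()].
#' @return data.frame with `pos_bp`, `xpclr`, `n_snvs` and `s_hat` (the
#'   maximizing selection coefficient); `xpclr` is `NA` where a window
#'   holds no usable SNV.
#' @export
xpclr_scan <- function(test_panel, ref_panel = NULL, cfg = xpclr_config()) {
  stopifnot(inherits(test_panel, "haplotype_panel"))
  if (is.null(ref_panel)) {
    if (is.null(test_panel$ref_haplotypes))
      stop("no reference panel supplied and test panel carries none")
    ref_hap <- test_panel$ref_haplotypes
  } else {
    stopifnot(inherits(ref_panel, "haplotype_panel"),
              ncol(ref_panel$haplotypes) == ncol(test_panel$haplotypes))
    ref_hap <- ref_panel$haplotypes
  }
  n2 <- nrow(test_panel$haplotypes)
  p1 <- colMeans(ref_hap)
  usable <- which(p1 > 0 & p1 < 1)
  pos_bp <- test_panel$positions_bp[usable]
  pos_cM <- test_panel$positions_cM[usable]
  p1 <- p1[usable]
  k2 <- round(test_panel$derived_freq[usable] * n2)

  omega <- cfg$drift_variance
  if (is.null(omega)) {
    tmp <- test_panel
    tmp$ref_haplotypes <- ref_hap
    omega <- estimate_drift_variance(tmp)
  }

  gl <- pracma::gaussLegendre(cfg$quad_points, 0, 1)
  u <- gl$x; w <- gl$w
  S <- length(usable)
  sdv <- sqrt(omega * p1 * (1 - p1))
  dens <- matrix(0, S, cfg$quad_points)
  for (q in seq_along(u)) dens[, q] <- dnorm(u[q], p1, sdv)
  m0 <- pnorm(0, p1, sdv)
  m1 <- pnorm(1, p1, sdv, lower.tail = FALSE)
  mass <- m0 * (k2 == 0) + m1 * (k2 == n2)

  kmat <- matrix(k2, S, cfg$quad_points)
  bin_neut <- dbinom(kmat, n2, matrix(u, S, cfg$quad_points, byrow = TRUE))
  ll_neut_site <- as.numeric(log(pmax(
    (dens * bin_neut) %*% w + mass, 1e-300)))

  # grid bp mapped to cM with the panel's (uniform) map scale
  cm_per_bp <- if (ncol(test_panel$haplotypes) > 1 &&
                   diff(range(test_panel$positions_bp)) > 0)
    diff(range(test_panel$positions_cM)) /
      diff(range(test_panel$positions_bp)) else 1e-6
  grid <- seq(cfg$grid_spacing_bp, test_panel$region_length,
              by = cfg$grid_spacing_bp)
  grid_cM <- grid * cm_per_bp
  out <- data.frame(pos_bp = grid, xpclr = NA_real_, n_snvs = 0L,
                    s_hat = NA_real_)
  if (S == 0) return(out)
  half_cM <- cfg$window_cM / 2
  for (g in seq_along(grid)) {
    win <- which(abs(pos_cM - grid_cM[g]) <= half_cM)
    if (length(win) == 0) next
    if (length(win) > cfg$max_snvs)
      win <- sort(with_local_seed(
        if (is.null(cfg$seed)) NULL else cfg$seed + g,
        sample(win, cfg$max_snvs)))
    r <- abs(pos_cM[win] - grid_cM[g]) / 100      # Morgans
    ll0 <- sum(ll_neut_site[win])
    best <- -Inf; best_s <- NA_real_
    for (s in cfg$s_grid) {
      cc <- 1 - exp(-(r / s) * log(max(2 * cfg$ne * s, 1.0001)))
      cc <- pmin(pmax(cc, 1e-8), 1)
      q1m <- cc %o% u                    # escaped branch frequencies
      q2m <- 1 - cc + q1m                # hitchhiked branch
      kw <- matrix(k2[win], length(win), cfg$quad_points)
      b1 <- dbinom(kw, n2, q1m)
      b2 <- dbinom(kw, n2, pmin(q2m, 1))
      integrand <- dens[win, , drop = FALSE] *
        (b1 * matrix(1 - u, length(win), cfg$quad_points, byrow = TRUE) +
           b2 * matrix(u, length(win), cfg$quad_points, byrow = TRUE))
      lik <- as.numeric(integrand %*% w) + mass[win]
      ll <- sum(log(pmax(lik, 1e-300)))
      if (ll > best) { best <- ll; best_s <- s }
    }
    out$xpclr[g] <- max(0, 2 * (best - ll0))
    out$n_snvs[g] <- length(win)
    out$s_hat[g] <- best_s
  }
  out
}
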