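#' Configuration for EHH/iHS scans
#'
#' @param ehh_truncation EHH level at which the integration of the decay
#'   curve stops (default 0.15).
#' @param max_extent_bp total size of the analyzed region centred on the
#'   core variant (default 200,000 bp, i.e. +/- 100 kb).
#' @param daf_bin_width width of the derived-allele-frequency bins used to
#'   standardize raw scores (default 0.05, giving 20 bins).
#' @param min_bin_count minimum number of scores an occupied bin needs for
#'   standardization (default 2).
#' @return an object of class `ihs_config`.
#' @export
ihs_config <- function(ehh_truncation = 0.15, max_extent_bp = 200000,
                       daf_bin_width = 0.05, min_bin_count = 2) {
  stopifnot(ehh_truncation > 0, ehh_truncation < 1, max_extent_bp > 0,
            daf_bin_width > 0, min_bin_count >= 2)
  if (abs((1 / daf_bin_width) - round(1 / daf_bin_width)) > 1e-9)
    stop("daf_bin_width must divide 1 evenly")
  structure(list(ehh_truncation = ehh_truncation,
                 max_extent_bp = max_extent_bp,
                 daf_bin_width = daf_bin_width,
                 min_bin_count = min_bin_count),
            class = "ihs_config")
}

# EHH decay over the panel's segregating markers in one direction. Returns
# distance (bp, >= 0) and EHH at each marker, starting with the core itself
# at distance 0 and EHH 1. Columns monomorphic in the whole panel carry no
# information and are skipped (so the integral is invariant to their
# presence); markers monomorphic within the carrier set keep the previous
# EHH but still serve as interpolation nodes, as in genotype-array scans.
ehh_curve <- function(panel, core, carriers, direction, max_extent_bp) {
  pos <- panel$positions_bp
  half <- max_extent_bp / 2
  poly <- panel$derived_freq > 0 & panel$derived_freq < 1
  if (direction == "right")
    idx <- which(poly & pos > pos[core] & pos <= pos[core] + half)
  else
    idx <- rev(which(poly & pos < pos[core] & pos >= pos[core] - half))
  k <- length(carriers)
  groups <- rep(1L, k)
  npairs <- choose(k, 2)
  dist <- numeric(length(idx)); e <- numeric(length(idx))
  m <- 0L
  cur <- 1
  for (j in idx) {
    al <- panel$haplotypes[carriers, j]
    if (any(al != al[1L])) {           # marker splits the carrier set
      key <- groups * 2L + al
      groups <- match(key, unique(key))
      cur <- sum(choose(tabulate(groups), 2)) / npairs
    }
    m <- m + 1L
    dist[m] <- abs(pos[j] - pos[core])
    e[m] <- cur
    if (cur == 0) break                # can only stay at zero
  }
  list(distance_bp = c(0, dist[seq_len(m)]), ehh = c(1, e[seq_len(m)]))
}

#' Extended haplotype homozygosity decay curve
#'
#' EHH at distance x is the probability that two distinct haplotypes drawn
#' at random among the carriers of the chosen core allele are identical at
#' every informative variant between the core and x. The curve starts at 1
#' and is non-increasing.
#'
#' @param panel a [haplotype_panel()].
#' @param core column index of the core variant.
#' @param allele `"derived"` or `"ancestral"`: which carriers to follow.
#' @param direction `"right"` or `"left"` of the core.
#' @param cfg an [ihs_config()].
#' @return data.frame with `distance_bp` and `ehh`.
#' @export
ehh <- function(panel, core, allele = c("derived", "ancestral"),
                direction = c("right", "left"), cfg = ihs_config()) {
  stopifnot(inherits(panel, "haplotype_panel"))
  allele <- match.arg(allele)
  direction <- match.arg(direction)
  a <- if (allele == "derived") 1L else 0L
  carriers <- which(panel$haplotypes[, core] == a)
  if (length(carriers) < 2)
    stop("fewer than 2 carriers of the ", allele, " allele at the core")
  as.data.frame(ehh_curve(panel, core, carriers, direction,
                          cfg$max_extent_bp))
}

# integrate an EHH curve by trapezoids, truncating at the first crossing
# below `trunc` (linear interpolation to the crossing point) or at the last
# marker inside the window, whichever comes first
ihh_integral <- function(curve, trunc) {
  d <- curve$distance_bp; e <- curve$ehh
  total <- 0
  for (i in seq_along(d)[-1]) {
    if (e[i] >= trunc) {
      total <- total + (d[i] - d[i - 1]) * (e[i] + e[i - 1]) / 2
    } else {
      xc <- d[i - 1] + (d[i] - d[i - 1]) * (e[i - 1] - trunc) /
        (e[i - 1] - e[i])
      total <- total + (xc - d[i - 1]) * (e[i - 1] + trunc) / 2
      break
    }
  }
  total
}

#' Raw (unstandardized) iHS at a core variant
#'
#' Integrates the EHH decay curves of the ancestral- and derived-allele
#' carrier sets in both directions (trapezoids over physical distance,
#' truncated where EHH drops below `cfg$ehh_truncation` or at the edge of
#' the `cfg$max_extent_bp` window) and returns
#' `log(iHH_ancestral / iHH_derived)`. Strongly negative values mean
#' unusually long derived-allele haplotypes (an ongoing sweep); strongly
#' positive values, long ancestral haplotypes.
#'
#' @param panel a [haplotype_panel()].
#' @param core column index of the core variant; its ancestral state must
#'   be known and both alleles must have at least 2 carriers.
#' @param cfg an [ihs_config()].
#' @return the raw iHS, or `NA_real_` when either integral is zero or the
#'   core is unscorable.
#' @export
ihs_raw <- function(panel, core, cfg = ihs_config()) {
  stopifnot(inherits(panel, "haplotype_panel"))
  if (!panel$ancestral_known[core]) return(NA_real_)
  al <- panel$haplotypes[, core]
  der <- which(al == 1L); anc <- which(al == 0L)
  if (length(der) < 2 || length(anc) < 2) return(NA_real_)
  ihh <- function(carriers) {
    ihh_integral(ehh_curve(panel, core, carriers, "left", cfg$max_extent_bp),
                 cfg$ehh_truncation) +
      ihh_integral(ehh_curve(panel, core, carriers, "right",
                             cfg$max_extent_bp),
                   cfg$ehh_truncation)
  }
  ia <- ihh(anc); id <- ihh(der)
  if (!is.finite(ia) || !is.finite(id) || ia <= 0 || id <= 0)
    return(NA_real_)
  log(ia / id)
}

#' Raw iHS for every scorable variant of a panel
#'
#' Applies [ihs_raw()] to each variant with known ancestral state and at
#' least two carriers of each allele; other variants are skipped as
#' unscorable.
#'
#' @param panel a [haplotype_panel()].
#' @param cfg an [ihs_config()].
#' @return data.frame with `col`, `pos_bp`, `daf`, `ihs_raw` (may have
#'   zero rows).
#' @export
ihs_scan <- function(panel, cfg = ihs_config()) {
  stopifnot(inherits(panel, "haplotype_panel"))
  n <- nrow(panel$haplotypes)
  cnt <- panel$derived_freq * n
  ok <- which(panel$ancestral_known & cnt >= 2 & cnt <= n - 2)
  raw <- vapply(ok, function(j) ihs_raw(panel, j, cfg), numeric(1))
  keep <- is.finite(raw)
  data.frame(col = ok[keep], pos_bp = panel$positions_bp[ok][keep],
             daf = panel$derived_freq[ok][keep], ihs_raw = raw[keep])
}

#' Standardize raw iHS scores within derived-allele-frequency bins
#'
#' Groups scores into bins of width `cfg$daf_bin_width` (20 bins by
#' default), subtracts the bin mean and divides by the bin standard
#' deviation (population form, so the standardized scores have mean 0 and
#' SD 1 exactly on the standardization set). Bins with fewer than
#' `cfg$min_bin_count` scores, or zero spread, yield `NA`.
#'
#' @param scores raw iHS values.
#' @param daf matching derived allele frequencies in (0, 1).
#' @param cfg an [ihs_config()].
#' @param bins optional bin table (as returned in the `bins` attribute)
#'   fitted on a reference score set — typically the genomic background —
#'   whose means and SDs are then applied to `scores` instead of
#'   refitting, the usual genome-wide workflow.
#' @return numeric vector of standardized scores, with attribute `bins`
#'   (data.frame of bin, count, mean, sd).
#' @export
standardize_ihs <- function(scores, daf, cfg = ihs_config(), bins = NULL) {
  stopifnot(length(scores) == length(daf), all(daf > 0 & daf < 1))
  nb <- round(1 / cfg$daf_bin_width)
  bin <- pmin(ceiling(daf / cfg$daf_bin_width), nb)  # (0,w], (w,2w], ...
  out <- rep(NA_real_, length(scores))
  if (!is.null(bins)) {
    i <- match(bin, bins$bin)
    ok <- !is.na(i) & bins$count[i] >= cfg$min_bin_count & bins$sd[i] > 0
    out[ok] <- (scores[ok] - bins$mean[i[ok]]) / bins$sd[i[ok]]
    attr(out, "bins") <- bins
    return(out)
  }
  stats <- data.frame(bin = seq_len(nb), count = 0L,
                      mean = NA_real_, sd = NA_real_)
  for (b in unique(bin)) {
    i <- which(bin == b)
    m <- mean(scores[i])
    s <- sqrt(mean((scores[i] - m)^2))
    stats$count[b] <- length(i)
    stats$mean[b] <- m; stats$sd[b] <- s
    if (length(i) >= cfg$min_bin_count && s > 0)
      out[i] <- (scores[i] - m) / s
  }
  attr(out, "bins") <- stats[stats$count > 0, ]
  out
}
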