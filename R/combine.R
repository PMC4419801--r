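#' Gene-level summary of per-variant or per-grid scores
#'
#' Collapses the scores observed inside a gene region to a single value by
#' the arithmetic mean, optionally of absolute values (the convention for
#' iHS, where both tails signal selection).
#'
#' @param values numeric scores (per-variant iHS or per-grid XP-CLR);
#'   non-finite entries are dropped.
#' @param absolute take `abs()` first (default `FALSE`).
#' @return the mean, or `NA_real_` when no scorable value remains (the
#'   gene is then unscorable).
#' @export
gene_summary <- function(values, absolute = FALSE) {
  v <- values[is.finite(values)]
  if (length(v) == 0) return(NA_real_)
  if (absolute) v <- abs(v)
  mean(v)
}

#' Empirical P value against a genomic background
#'
#' Upper-tail rank of a gene-level score in the background score
#' distribution, with add-one correction so that P is never zero:
#' `P = (1 + #{background >= score}) / (1 + N)`. Ties count as at least as
#' extreme.
#'
#' @param score gene-level score.
#' @param background_scores numeric background distribution (non-finite
#'   entries dropped).
#' @return P in (0, 1].
#' @export
empirical_pvalue <- function(score, background_scores) {
  bg <- background_scores[is.finite(background_scores)]
  if (length(bg) == 0) stop("empty background distribution")
  if (!is.finite(score)) return(NA_real_)
  (1 + sum(bg >= score)) / (1 + length(bg))
}

#' Fisher combination of per-test P values
#'
#' Combines k independent P values into `Z_F = -2 * sum(log(P_i))`, which
#' is chi-square distributed with 2k degrees of freedom under the joint
#' null (6 df for the three selection tests combined here).
#'
#' @param p_values numeric vector of P values in (0, 1].
#' @return list with `z_f` and `combined_p` (upper chi-square tail at
#'   2k df).
#' @export
fisher_combine <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values <= 0) ||
      any(p_values > 1))
    stop("P values must lie in (0, 1]")
  z <- -2 * sum(log(p_values))
  list(z_f = z,
       combined_p = pchisq(z, df = 2 * length(p_values),
                           lower.tail = FALSE))
}

#' Call positively selected genes
#'
#' Flags genes whose combined P value falls strictly below the threshold.
#'
#' @param combined_p numeric vector of combined P values.
#' @param alpha calling threshold (default 0.05).
#' @return logical vector (`NA` where the combined P is missing).
#' @export
call_selected <- function(combined_p, alpha = 0.05) {
  ifelse(is.na(combined_p), NA, combined_p < alpha)
}

#' Score genes against a neutral genomic background
#'
#' The gene-level outlier pipeline: for each gene panel and each background
#' panel it computes Tajima's D, Fay and Wu's H, raw iHS per scorable SNV
#' and the mean XP-CLR over the region's grid; standardizes iHS in DAF bins
#' on the pooled set of SNVs (genes plus background, emulating genome-wide
#' standardization); summarizes per gene (mean |iHS|, mean XP-CLR);
#' converts the two summaries to upper-tail empirical P values against the
#' background distributions and the (D, H) pair to the joint empirical DH
#' comparison; combines the three P values by Fisher's method; and calls
#' selection at `alpha`. Genes (and background regions) with fewer than
#' `min_snvs` variants, or missing any component score, carry no call.
#'
#' The bivariate DH corner probability (reported as `dh_corner`) is not
#' uniform under neutrality, so before combination it is itself ranked
#' against the corner probabilities of the background regions; `dh_p` is
#' that calibrated rank, uniform under exchangeability with the
#' background.
#'
#' All three empirical rankings are performed within strata of the
#' background defined by segregating-site count (`snv_strata` quantile
#' bins). The realized tree length of a region drives S, D, H, haplotype
#' homozygosity and allele-frequency drift simultaneously, so ranking
#' against a SNV-matched background removes the dominant shared component
#' among the three tests — the independence that their Fisher combination
#' assumes. Set `snv_strata = 1` for plain pooled ranking.
#'
#' @param gene_panels named list of [haplotype_panel()] objects, one per
#'   gene.
#' @param background_panels list of neutral background panels (each with a
#'   reference sample when `use_xpclr` is `TRUE`).
#' @param ihs_cfg an [ihs_config()].
#' @param xpclr_cfg an [xpclr_config()]; its drift variance, when `NULL`,
#'   is estimated once from the pooled background panels.
#' @param alpha calling threshold on the combined P (default 0.05).
#' @param min_snvs minimum polymorphic variants per region (default 10).
#' @param use_xpclr include the XP-CLR component (default `TRUE`).
#' @param snv_strata number of SNV-count quantile strata for the
#'   empirical rankings (default 10; 1 disables stratification).
#' @return data.frame (one row per gene): `gene`, `n_snvs`, `D`, `H`,
#'   `mean_abs_ihs`, `mean_xpclr`, `dh_corner`, `dh_p`, `ihs_p`,
#'   `xpclr_p`, `z_f`, `combined_p`, `selected`.
#' @export
score_genes <- function(gene_panels, background_panels,
                        ihs_cfg = ihs_config(), xpclr_cfg = xpclr_config(),
                        alpha = 0.05, min_snvs = 10, use_xpclr = TRUE,
                        snv_strata = 10) {
  stopifnot(length(gene_panels) > 0, length(background_panels) > 0)
  if (is.null(names(gene_panels)))
    names(gene_panels) <- sprintf("gene_%04d", seq_along(gene_panels))

  if (use_xpclr && is.null(xpclr_cfg$drift_variance)) {
    with_ref <- Filter(function(p) !is.null(p$ref_haplotypes),
                       background_panels)
    if (length(with_ref))
      xpclr_cfg$drift_variance <- estimate_drift_variance(with_ref)
  }

  measure <- function(panel) {
    if (n_polymorphic(panel) < min_snvs)
      return(list(ok = FALSE))
    sfs <- sfs_summary(panel)
    scan <- ihs_scan(panel, ihs_cfg)
    xp <- if (use_xpclr && !is.null(panel$ref_haplotypes))
      gene_summary(xpclr_scan(panel, cfg = xpclr_cfg)$xpclr)
    else NA_real_
    list(ok = TRUE, n_snvs = sfs$S, D = tajimas_d(sfs),
         H = fay_wu_h(sfs), ihs = scan, mean_xpclr = xp)
  }
  gm <- lapply(gene_panels, measure)
  bm <- lapply(background_panels, measure)

  # pooled DAF-bin standardization of raw iHS across all regions
  pool <- function(ms) do.call(rbind, lapply(ms, function(m)
    if (isTRUE(m$ok) && nrow(m$ihs)) m$ihs else NULL))
  gi <- pool(gm); bi <- pool(bm)
  all_ihs <- rbind(if (!is.null(gi)) cbind(gi, set = "gene"),
                   if (!is.null(bi)) cbind(bi, set = "bg"))
  if (is.null(all_ihs))
    all_ihs <- data.frame(col = integer(0), pos_bp = integer(0),
                          daf = numeric(0), ihs_raw = numeric(0),
                          set = character(0))
  all_ihs$std <- if (nrow(all_ihs))
    standardize_ihs(all_ihs$ihs_raw, all_ihs$daf, ihs_cfg) else numeric(0)
  split_std <- function(ms, set) {
    idx <- which(all_ihs$set == set)
    rows <- all_ihs[idx, ]
    counts <- vapply(ms, function(m)
      if (isTRUE(m$ok)) nrow(m$ihs) else 0L, integer(1))
    split(rows$std, rep(seq_along(ms), counts))
  }
  g_std <- split_std(gm, "gene")
  b_std <- split_std(bm, "bg")

  summ <- function(ms, std_list) {
    t(vapply(seq_along(ms), function(i) {
      m <- ms[[i]]
      if (!isTRUE(m$ok))
        return(c(NA_real_, NA_real_, NA_real_, NA_real_, NA_real_))
      s <- std_list[[as.character(i)]]
      c(m$n_snvs, m$D, m$H,
        gene_summary(if (is.null(s)) numeric(0) else s, absolute = TRUE),
        m$mean_xpclr)
    }, numeric(5)))
  }
  gs <- summ(gm, g_std)
  bs <- summ(bm, b_std)
  colnames(gs) <- colnames(bs) <-
    c("n_snvs", "D", "H", "mean_abs_ihs", "mean_xpclr")

  bg_dh <- bs[, c("D", "H"), drop = FALSE]
  res <- data.frame(gene = names(gene_panels), gs, row.names = NULL)

  # SNV-count strata for the empirical rankings (common-cause removal)
  bgS <- bs[, "n_snvs"]
  qs <- quantile(bgS[is.finite(bgS)],
                 probs = seq(0, 1, length.out = max(1, snv_strata) + 1),
                 na.rm = TRUE, names = FALSE)
  breaks <- unique(qs)
  stratum_of <- function(S) {
    s <- findInterval(S, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
    s[!is.finite(S)] <- NA_integer_
    s
  }
  bg_str <- stratum_of(bgS)
  gene_str <- stratum_of(res$n_snvs)

  # The bivariate corner probability is a depth score, not a calibrated P
  # (for independent D and H its null distribution is u*(1-log u), far
  # from uniform). Rank the gene's corner probability against the corner
  # probabilities of the background regions themselves, so that the DH
  # component entering the Fisher combination is uniform under the null.
  bg_corner <- vapply(seq_len(nrow(bg_dh)), function(i) {
    if (!all(is.finite(bg_dh[i, ]))) return(NA_real_)
    dh_pvalue(bg_dh[i, ], bg_dh)
  }, numeric(1))
  res$dh_corner <- vapply(seq_len(nrow(res)), function(i) {
    if (is.na(res$D[i]) || is.na(res$H[i])) return(NA_real_)
    dh_pvalue(c(res$D[i], res$H[i]), bg_dh)
  }, numeric(1))
  strat_rank <- function(values, bg_values, lower_tail = FALSE) {
    vapply(seq_along(values), function(i) {
      v <- values[i]
      if (!is.finite(v) || is.na(gene_str[i])) return(NA_real_)
      bgv <- bg_values[bg_str == gene_str[i] & is.finite(bg_values)]
      if (length(bgv) == 0) return(NA_real_)
      k <- if (lower_tail) sum(bgv <= v) else sum(bgv >= v)
      (1 + k) / (1 + length(bgv))
    }, numeric(1))
  }
  res$dh_p <- strat_rank(res$dh_corner, bg_corner, lower_tail = TRUE)
  res$ihs_p <- strat_rank(res$mean_abs_ihs, bs[, "mean_abs_ihs"])
  res$xpclr_p <- if (use_xpclr)
    strat_rank(res$mean_xpclr, bs[, "mean_xpclr"]) else NA_real_
  pcols <- if (use_xpclr) c("dh_p", "ihs_p", "xpclr_p")
  else c("dh_p", "ihs_p")
  comb <- t(vapply(seq_len(nrow(res)), function(i) {
    ps <- unlist(res[i, pcols])
    if (any(is.na(ps))) return(c(NA_real_, NA_real_))
    fc <- fisher_combine(ps)
    c(fc$z_f, fc$combined_p)
  }, numeric(2)))
  res$z_f <- comb[, 1]
  res$combined_p <- comb[, 2]
  res$selected <- call_selected(res$combined_p, alpha)
  attr(res, "background") <- as.data.frame(bs)
  attr(res, "drift_variance") <- xpclr_cfg$drift_variance
  res
}
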