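# standard genetic code, codon -> one-letter amino acid (stop = "*")
codon_table <- function() {
  bases <- c("T", "C", "A", "G")
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "")[[1]]
  codons <- apply(expand.grid(bases, bases, bases)[, 3:1], 1, paste0,
                  collapse = "")
  setNames(aa, codons)
}
.CODON_AA <- codon_table()

# degeneracy fold of one codon position: "zero_fold" if every nucleotide
# change alters the amino acid, "four_fold" if none does, else "other"
codon_fold <- function(codon, pos) {
  codon <- toupper(chartr("U", "T", codon))
  aa <- .CODON_AA[[codon]]
  alt <- setdiff(c("T", "C", "A", "G"), substr(codon, pos, pos))
  changed <- vapply(alt, function(b) {
    cd <- codon
    substr(cd, pos, pos) <- b
    .CODON_AA[[cd]] != aa
  }, logical(1))
  if (all(changed)) "zero_fold" else if (!any(changed)) "four_fold"
  else "other"
}

#' Classify coding sites as 0-fold or 4-fold degenerate
#'
#' For each transcript (a CDS sequence plus the genomic position of each
#' base), every site is classified under the standard genetic code:
#' 0-fold if all three possible substitutions change the amino acid
#' (nonsynonymous site), 4-fold if none does (synonymous site), otherwise
#' "other". Sites whose 0-/4-fold classification differs between
#' transcripts are dropped ("conflict"), since their synonymous status is
#' ambiguous. Transcripts with an internal stop codon are rejected with a
#' warning.
#'
#' @param transcripts list of transcripts, each a list with `seq` (CDS
#'   string, length a multiple of 3) and `pos` (integer genomic positions,
#'   one per base).
#' @return data.frame with `pos` and `class` in
#'   `{"zero_fold", "four_fold", "other"}`; conflicting sites are absent.
#' @export
classify_degeneracy <- function(transcripts) {
  stopifnot(length(transcripts) >= 1)
  per_tx <- list()
  for (t in seq_along(transcripts)) {
    tx <- transcripts[[t]]
    s <- toupper(chartr("U", "T", tx$seq))
    L <- nchar(s)
    if (L %% 3 != 0) stop("CDS length must be a multiple of 3")
    stopifnot(length(tx$pos) == L)
    codons <- substring(s, seq(1, L, 3), seq(3, L, 3))
    aas <- .CODON_AA[codons]
    if (any(aas[-length(aas)] == "*")) {
      warning("transcript ", t, " has an internal stop codon; rejected")
      next
    }
    cls <- character(L)
    for (i in seq_len(L)) {
      cp <- ((i - 1) %% 3) + 1
      cls[i] <- codon_fold(codons[(i - 1) %/% 3 + 1], cp)
    }
    per_tx[[length(per_tx) + 1]] <- data.frame(pos = tx$pos, class = cls)
  }
  if (length(per_tx) == 0) stop("no usable transcript")
  all <- do.call(rbind, per_tx)
  agg <- tapply(all$class, all$pos, function(cl) {
    u <- unique(cl)
    fold <- intersect(u, c("zero_fold", "four_fold"))
    if (length(fold) > 1) "conflict"
    else if (length(u) > 1 && length(fold) == 1) "conflict"
    else u
  })
  out <- data.frame(pos = as.integer(names(agg)),
                    class = unname(as.character(agg)))
  out[out$class != "conflict", ]
}

#' Polarized polymorphism and divergence counts
#'
#' Builds the 2x2 McDonald-Kreitman table for the focal (human) lineage:
#' fixed differences D are sites where the focal sequence differs from
#' both outgroups while the two outgroups agree (the substitution is then
#' assigned to the focal lineage); polymorphic counts P come from the
#' supplied segregating-site positions. Both are split into nonsynonymous
#' (0-fold) and synonymous (4-fold) classes; sites with alignment gaps in
#' any species, or without a fold class, are ignored.
#'
#' @param focal,outgroup1,outgroup2 aligned same-length sequences
#'   (character strings; gaps as "-").
#' @param poly_pos integer positions (1-based, alignment coordinates) of
#'   sites segregating in the focal population.
#' @param annotation data.frame from [classify_degeneracy()] with `pos`
#'   (alignment coordinates) and `class`.
#' @return an `mk_counts` object: list with `P_N`, `P_S`, `D_N`, `D_S`,
#'   `NI` and `fisher_p`.
#' @export
polarized_counts <- function(focal, outgroup1, outgroup2, poly_pos,
                             annotation) {
  L <- nchar(focal)
  if (nchar(outgroup1) != L || nchar(outgroup2) != L)
    stop("aligned sequences must have equal length")
  h <- strsplit(toupper(focal), "")[[1]]
  c1 <- strsplit(toupper(outgroup1), "")[[1]]
  c2 <- strsplit(toupper(outgroup2), "")[[1]]
  cls <- rep(NA_character_, L)
  keep <- annotation$pos >= 1 & annotation$pos <= L
  cls[annotation$pos[keep]] <- annotation$class[keep]
  ok <- h != "-" & c1 != "-" & c2 != "-"
  fixed <- ok & h != c1 & h != c2 & c1 == c2
  D_N <- sum(fixed & cls == "zero_fold", na.rm = TRUE)
  D_S <- sum(fixed & cls == "four_fold", na.rm = TRUE)
  pp <- unique(poly_pos[poly_pos >= 1 & poly_pos <= L])
  P_N <- sum(cls[pp] == "zero_fold", na.rm = TRUE)
  P_S <- sum(cls[pp] == "four_fold", na.rm = TRUE)
  mk_counts(P_N, P_S, D_N, D_S)
}

#' McDonald-Kreitman count table with NI and exact-test P
#'
#' @param P_N,P_S nonsynonymous/synonymous polymorphic-site counts.
#' @param D_N,D_S nonsynonymous/synonymous fixed differences.
#' @return an `mk_counts` object with the neutrality index
#'   ([neutrality_index()]) and the two-sided Fisher exact P
#'   ([mk_fisher()]).
#' @export
mk_counts <- function(P_N, P_S, D_N, D_S) {
  stopifnot(P_N >= 0, P_S >= 0, D_N >= 0, D_S >= 0)
  x <- list(P_N = as.integer(P_N), P_S = as.integer(P_S),
            D_N = as.integer(D_N), D_S = as.integer(D_S))
  x$NI <- neutrality_index(x)
  x$fisher_p <- mk_fisher(x)
  structure(x, class = "mk_counts")
}

#' @export
print.mk_counts <- function(x, ...) {
  cat(sprintf("MK table: P_N=%d P_S=%d D_N=%d D_S=%d  NI=%.4f  P=%.4g\n",
              x$P_N, x$P_S, x$D_N, x$D_S, x$NI, x$fisher_p))
  invisible(x)
}

#' Neutrality index
#'
#' `NI = (P_N/P_S) / (D_N/D_S)`; when any of the four counts is zero the
#' Haldane-corrected form with 0.5 added to every cell is used instead,
#' which keeps NI finite and positive. NI > 1 indicates an excess of
#' amino-acid polymorphism (segregating weakly deleterious variants,
#' i.e. constraint); NI < 1 an excess of amino-acid fixation (adaptive
#' evolution).
#'
#' @param counts an `mk_counts` object or list with `P_N`, `P_S`, `D_N`,
#'   `D_S`.
#' @return NI (finite, > 0).
#' @export
neutrality_index <- function(counts) {
  with(counts, {
    if (P_N > 0 && P_S > 0 && D_N > 0 && D_S > 0)
      (P_N / P_S) / (D_N / D_S)
    else
      ((P_N + 0.5) / (P_S + 0.5)) / ((D_N + 0.5) / (D_S + 0.5))
  })
}

#' Fisher exact test on the MK table
#'
#' Two-sided exact test of independence between site class (N vs S) and
#' state (polymorphic vs fixed).
#'
#' @param counts an `mk_counts` object or list with the four counts.
#' @return P in (0, 1], or `NA_real_` for an all-zero table.
#' @export
mk_fisher <- function(counts) {
  m <- with(counts, matrix(c(P_N, P_S, D_N, D_S), nrow = 2))
  if (sum(m) == 0) return(NA_real_)
  fisher.test(m)$p.value
}

#' MK eligibility filter
#'
#' The pipeline only reports NI and the exact-test P for genes with more
#' than `min_count` observations in each of the four cells, where power
#' is adequate.
#'
#' @param counts an `mk_counts` object.
#' @param min_count exclusive threshold (default 3: requires > 3).
#' @return `TRUE` when all four counts exceed `min_count`.
#' @export
mk_eligible <- function(counts, min_count = 3) {
  with(counts, all(c(P_N, P_S, D_N, D_S) > min_count))
}

#' Simulate an MK count table with known rates
#'
#' Independent Poisson draws of the four MK cells, for calibrating
#' NI-based analyses against a known truth.
#'
#' @param theta_poly expected `c(P_N, P_S)`.
#' @param theta_div expected `c(D_N, D_S)`.
#' @param seed integer seed (`NULL`: current RNG).
#' @return an `mk_counts` object.
#' @export
generate_mk_counts <- function(theta_poly, theta_div, seed = NULL) {
  stopifnot(length(theta_poly) == 2, length(theta_div) == 2,
            all(theta_poly >= 0), all(theta_div >= 0))
  if (!is.null(seed)) set.seed(seed)
  mk_counts(rpois(1, theta_poly[1]), rpois(1, theta_poly[2]),
            rpois(1, theta_div[1]), rpois(1, theta_div[2]))
}

#' Gene-level derived-allele-frequency summaries
#'
#' Two modes. `"mean"`: the average DAF over ancestral-informed variants
#' in the gene region, a proxy for the strength of purifying selection
#' (constraint keeps derived alleles rare). `"max_by_class"`: the maximum
#' DAF per site class (cis-eQTL within `max_eqtl_dist` of the gene body,
#' 0-fold, 4-fold), used to ask which functional class carries the
#' presumptive sweep-driving variant; genes missing any of the three
#' classes return `NA` for it and are excluded upstream.
#'
#' @param variants data.frame with `pos` (bp), `daf` in [0, 1], and (for
#'   `max_by_class`) `class` in
#'   `{"cis_eQTL", "zero_fold", "four_fold", "other"}`.
#' @param gene_start,gene_end gene body in bp (used for the eQTL distance
#'   rule).
#' @param mode `"mean"` or `"max_by_class"`.
#' @param max_eqtl_dist maximum distance from the gene body for a
#'   cis-eQTL to count (default 100,000 bp; distance is 0 inside the
#'   body).
#' @return the mean DAF, or a named numeric `c(cis_eQTL, zero_fold,
#'   four_fold)` of class maxima.
#' @export
gene_daf_summary <- function(variants, gene_start, gene_end,
                             mode = c("mean", "max_by_class"),
                             max_eqtl_dist = 1e5) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(variants), all(c("pos", "daf") %in%
                                           names(variants)))
  if (mode == "mean") {
    inside <- variants$pos >= gene_start & variants$pos <= gene_end
    v <- variants$daf[inside]
    if (length(v) == 0) return(NA_real_)
    return(mean(v))
  }
  stopifnot("class" %in% names(variants))
  dist <- pmax(gene_start - variants$pos, variants$pos - gene_end, 0)
  mx <- function(sel) if (any(sel)) max(variants$daf[sel]) else NA_real_
  c(cis_eQTL = mx(variants$class == "cis_eQTL" & dist <= max_eqtl_dist),
    zero_fold = mx(variants$class == "zero_fold" & dist == 0),
    four_fold = mx(variants$class == "four_fold" & dist == 0))
}

#' Permutation test of site-class maximum DAF in selected genes
#'
#' For each site class, the observed statistic is the median over the
#' selected genes of the per-gene maximum DAF; the null distribution is
#' obtained by drawing random gene sets of the same size from the eligible
#' table. P is the add-one-corrected fraction of null medians at least as
#' large as the observed one (upper tail: selection should push the
#' sweep-driving class to high frequency).
#'
#' @param selected_genes character vector, a subset of
#'   `rownames(eligible_table)`.
#' @param eligible_table numeric matrix/data.frame (genes x site classes)
#'   of per-gene maximum DAF, complete cases only.
#' @param n_perm number of permutations (default 10,000).
#' @param seed integer seed (`NULL`: current RNG).
#' @return data.frame with `class`, `observed_median`, `p_value`.
#' @export
daf_class_test <- function(selected_genes, eligible_table, n_perm = 10000,
                           seed = NULL) {
  tab <- as.matrix(eligible_table)
  stopifnot(length(selected_genes) >= 1,
            all(selected_genes %in% rownames(tab)))
  if (!is.null(seed)) set.seed(seed)
  k <- length(selected_genes)
  obs <- apply(tab[selected_genes, , drop = FALSE], 2, median)
  ge <- numeric(ncol(tab))
  for (b in seq_len(n_perm)) {
    idx <- sample(nrow(tab), k)
    nm <- apply(tab[idx, , drop = FALSE], 2, median)
    ge <- ge + (nm >= obs)
  }
  data.frame(class = colnames(tab), observed_median = unname(obs),
             p_value = unname((1 + ge) / (1 + n_perm)), row.names = NULL)
}
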