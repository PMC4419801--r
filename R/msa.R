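AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Construct a protein alignment
#'
#' @param mat character matrix of single residues, rows = species
#'   (rownames are the species labels), columns = alignment positions;
#'   gaps as "-".
#' @return an object of class `protein_alignment`.
#' @export
protein_alignment <- function(mat) {
  mat <- as.matrix(mat)
  stopifnot(is.character(mat), nrow(mat) >= 1)
  if (is.null(rownames(mat)))
    rownames(mat) <- sprintf("species_%02d", seq_len(nrow(mat)))
  structure(mat, class = c("protein_alignment", class(mat)))
}

#' @export
print.protein_alignment <- function(x, ...) {
  cat(sprintf("protein_alignment: %d sequences x %d columns\n",
              nrow(x), ncol(x)))
  for (i in seq_len(min(nrow(x), 10)))
    cat(sprintf("  %-12s %s%s\n", rownames(x)[i],
                paste(x[i, seq_len(min(60, ncol(x)))], collapse = ""),
                if (ncol(x) > 60) "..." else ""))
  invisible(x)
}

#' Generate a synthetic ortholog alignment with annotation-error bursts
#'
#' Background columns are drawn nearly identically across species (each
#' species copies a per-column consensus residue, replaced by a random
#' different residue with probability `background_mismatch`, emulating
#' genuine sparse divergence). Each error burst overwrites a stretch of
#' one sequence with residues guaranteed to be unique to that sequence in
#' their column, the pattern produced by mis-annotated exon boundaries or
#' frameshifted gene models. The returned truth mask marks burst columns
#' so filter recovery can be scored.
#'
#' @param n_species number of sequences (>= 3).
#' @param n_columns alignment length.
#' @param error_bursts list of `list(sequence =, start =, length =)`;
#'   bursts in the same sequence must not overlap.
#' @param seed integer seed (`NULL`: current RNG).
#' @param background_mismatch per-residue probability of a species-private
#'   substitution outside bursts (default 0.01).
#' @return a `protein_alignment`; attribute `truth_mask` is a logical
#'   vector marking burst columns.
#' @export
generate_msa <- function(n_species, n_columns, error_bursts = list(),
                         seed = NULL, background_mismatch = 0.01) {
  stopifnot(n_species >= 3, n_columns >= 1)
  if (!is.null(seed)) set.seed(seed)
  for (b in error_bursts)
    stopifnot(b$sequence >= 1, b$sequence <= n_species, b$start >= 1,
              b$start + b$length - 1 <= n_columns)
  for (s in unique(vapply(error_bursts, `[[`, 1, "sequence"))) {
    bs <- Filter(function(b) b$sequence == s, error_bursts)
    iv <- sort(unlist(lapply(bs, function(b)
      seq(b$start, b$start + b$length - 1))))
    if (anyDuplicated(iv)) stop("overlapping bursts in sequence ", s)
  }
  consensus <- sample(AA_ALPHABET, n_columns, replace = TRUE)
  aln <- matrix(rep(consensus, each = n_species), n_species, n_columns)
  miss <- which(matrix(runif(n_species * n_columns) < background_mismatch,
                       n_species, n_columns), arr.ind = TRUE)
  for (i in seq_len(nrow(miss))) {
    alt <- setdiff(AA_ALPHABET, consensus[miss[i, 2]])
    aln[miss[i, 1], miss[i, 2]] <- sample(alt, 1)
  }
  truth <- rep(FALSE, n_columns)
  for (b in error_bursts) {
    cols <- seq(b$start, b$start + b$length - 1)
    for (j in cols) {
      used <- aln[-b$sequence, j]
      aln[b$sequence, j] <- sample(setdiff(AA_ALPHABET, used), 1)
    }
    truth[cols] <- TRUE
  }
  rownames(aln) <- sprintf("species_%02d", seq_len(n_species))
  out <- protein_alignment(aln)
  attr(out, "truth_mask") <- truth
  out
}

#' Flag species-unique residues per alignment column
#'
#' A (column, species) pair is flagged when that species' residue occurs
#' in no other sequence at that column; gap characters are never flagged.
#' Runs of such unique substitutions concentrated in one sequence are the
#' fingerprint of annotation error rather than genuine divergence between
#' closely related species.
#'
#' @param alignment a [protein_alignment()] with >= 3 sequences.
#' @return logical matrix of the same dimensions.
#' @export
unique_substitution_flags <- function(alignment) {
  stopifnot(inherits(alignment, "protein_alignment"),
            nrow(alignment) >= 3)
  flags <- matrix(FALSE, nrow(alignment), ncol(alignment),
                  dimnames = dimnames(alignment))
  for (j in seq_len(ncol(alignment))) {
    col <- alignment[, j]
    for (i in seq_len(nrow(alignment))) {
      if (col[i] == "-") next
      flags[i, j] <- !(col[i] %in% col[-i])
    }
  }
  flags
}

#' Sliding-window mask of suspicious alignment regions
#'
#' Slides windows of `window` residues (by steps of one, over the
#' ungapped positions of each sequence) and marks for removal the full
#' alignment-column span of every window holding at least `min_flags`
#' unique substitutions in that single sequence. The default rules are
#' (15 residues, >= 10 flags) and (5 residues, 5 flags); the mask is the
#' union over rules and sequences.
#'
#' @param flags logical matrix from [unique_substitution_flags()].
#' @param alignment the matching [protein_alignment()], used to skip gap
#'   positions when windows are laid out; `NULL` treats every position as
#'   ungapped.
#' @param rules list of `c(window =, min_flags =)` pairs.
#' @return logical vector over alignment columns (`TRUE` = remove).
#' @export
window_mask <- function(flags, alignment = NULL,
                        rules = list(c(window = 15, min_flags = 10),
                                     c(window = 5, min_flags = 5))) {
  stopifnot(is.matrix(flags), is.logical(flags))
  L <- ncol(flags)
  mask <- rep(FALSE, L)
  for (i in seq_len(nrow(flags))) {
    cols <- if (is.null(alignment)) seq_len(L)
    else which(alignment[i, ] != "-")
    if (length(cols) == 0) next
    f <- flags[i, cols]
    for (rule in rules) {
      wdw <- rule[["window"]]; mf <- rule[["min_flags"]]
      if (length(cols) < wdw) next
      cs <- cumsum(c(0, f))
      counts <- cs[(wdw + 1):length(cs)] - cs[seq_len(length(cs) - wdw)]
      for (start in which(counts >= mf))
        mask[cols[start]:cols[start + wdw - 1]] <- TRUE
    }
  }
  mask
}

#' Remove masked columns from an alignment
#'
#' @param alignment a [protein_alignment()].
#' @param mask logical vector over columns (`TRUE` = remove).
#' @return the filtered `protein_alignment`; attribute `removed_fraction`
#'   reports the fraction of columns removed.
#' @export
apply_mask <- function(alignment, mask) {
  stopifnot(inherits(alignment, "protein_alignment"),
            length(mask) == ncol(alignment))
  if (all(mask)) stop("mask removes every column")
  out <- protein_alignment(alignment[, !mask, drop = FALSE])
  attr(out, "removed_fraction") <- mean(mask)
  out
}

#' Filter an alignment with the sliding-window sanitizer
#'
#' Convenience wrapper: [unique_substitution_flags()] then
#' [window_mask()] then [apply_mask()].
#'
#' @inheritParams apply_mask
#' @inheritParams window_mask
#' @return the filtered alignment, with attributes `mask` and
#'   `removed_fraction`.
#' @export
filter_alignment <- function(alignment,
                             rules = list(c(window = 15, min_flags = 10),
                                          c(window = 5, min_flags = 5))) {
  mask <- window_mask(unique_substitution_flags(alignment), alignment,
                      rules)
  out <- apply_mask(alignment, mask)
  attr(out, "mask") <- mask
  out
}

#' M7-versus-M8 likelihood-ratio test for positive selection
#'
#' Contrasts the beta-distributed-omega codon model (M7) with its
#' extension allowing a class of codons with omega > 1 (M8), from
#' externally fitted log-likelihoods: `2 * (lnL_M8 - lnL_M7)` is referred
#' to a chi-square distribution with 2 degrees of freedom (upper tail
#' `exp(-x/2)`). Negative differences — possible only through numerical
#' optimization noise, since the models are nested — are clamped to zero.
#'
#' @param lnl_m7,lnl_m8 numeric vectors of per-gene log-likelihoods.
#' @param alpha calling threshold on P (default 0.05).
#' @param omega_m0 optional per-gene omega from the one-ratio model,
#'   carried through as metadata.
#' @return data.frame with `lnl_m7`, `lnl_m8`, `two_delta_l`, `p_value`,
#'   `div_psg` (P < alpha) and optionally `omega_m0`.
#' @export
m7m8_lrt <- function(lnl_m7, lnl_m8, alpha = 0.05, omega_m0 = NULL) {
  stopifnot(length(lnl_m7) == length(lnl_m8))
  if (any(!is.finite(lnl_m7)) || any(!is.finite(lnl_m8)))
    stop("log-likelihoods must be finite")
  two_delta <- pmax(0, 2 * (lnl_m8 - lnl_m7))
  p <- pchisq(two_delta, df = 2, lower.tail = FALSE)
  out <- data.frame(lnl_m7 = lnl_m7, lnl_m8 = lnl_m8,
                    two_delta_l = two_delta, p_value = p,
                    div_psg = p < alpha)
  if (!is.null(omega_m0)) out$omega_m0 <- omega_m0
  out
}
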