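#' Write a haplotype panel as a minimal VCF
#'
#' Phased biallelic genotypes (GT with "|"), ancestral allele in INFO/AA.
#' The ancestral allele is written as REF ("A") and the derived allele as
#' ALT ("T"); variants with unknown ancestral state get `AA=.`. Haplotypes
#' are paired into diploid samples (an odd trailing haplotype is padded
#' into a haploid call).
#'
#' @param panel a [haplotype_panel()].
#' @param path output file path (plain text).
#' @param chrom chromosome label (default "1").
#' @return `path`, invisibly.
#' @export
write_panel_vcf <- function(panel, path, chrom = "1") {
  stopifnot(inherits(panel, "haplotype_panel"))
  n <- nrow(panel$haplotypes)
  ns <- ceiling(n / 2)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", chrom,
            as.integer(panel$region_length)),
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", sprintf("sample_%03d", seq_len(ns))),
          collapse = "\t")), con)
  for (j in seq_len(ncol(panel$haplotypes))) {
    al <- panel$haplotypes[, j]
    gts <- vapply(seq_len(ns), function(s) {
      i <- 2 * s - 1
      if (i + 1 <= n) paste0(al[i], "|", al[i + 1]) else
        as.character(al[i])
    }, character(1))
    writeLines(paste(c(chrom, panel$positions_bp[j],
                       sprintf("var_%05d", j), "A", "T", ".", "PASS",
                       if (panel$ancestral_known[j]) "AA=A" else "AA=.",
                       "GT", gts), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a minimal VCF into a haplotype panel
#'
#' Parses phased biallelic GT fields and the INFO/AA ancestral-allele tag
#' written by [write_panel_vcf()] (or any VCF restricted to those
#' features). When AA equals the ALT allele the 0/1 coding is flipped so
#' that 0 is always ancestral; `AA=.` marks the ancestral state unknown.
#'
#' @param path VCF file path (uncompressed).
#' @param genetic_map optional data.frame from [read_genetic_map()] used
#'   to interpolate cM positions; default 1 cM/Mb.
#' @param region_length region size; defaults to the contig length header
#'   or the maximum position.
#' @return a [haplotype_panel()].
#' @export
read_panel_vcf <- function(path, genetic_map = NULL,
                           region_length = NULL) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "##")]
  body <- lines[!startsWith(lines, "##")]
  if (is.null(region_length)) {
    ct <- grep("^##contig=", hdr, value = TRUE)
    if (length(ct))
      region_length <- as.numeric(sub(".*length=([0-9]+).*", "\\1",
                                      ct[1]))
  }
  cols <- strsplit(body, "\t")
  stopifnot(length(cols) >= 1, startsWith(body[1], "#CHROM"))
  rows <- cols[-1]
  pos <- vapply(rows, function(r) as.numeric(r[2]), numeric(1))
  ref <- vapply(rows, `[`, character(1), 4)
  alt <- vapply(rows, `[`, character(1), 5)
  aa <- sub("^.*AA=([^;]*).*$", "\\1", vapply(rows, `[`, character(1), 8))
  gt <- lapply(rows, function(r)
    as.integer(unlist(strsplit(r[-(1:9)], "[|/]"))))
  hap <- do.call(cbind, gt)
  anc_known <- aa != "."
  flip <- anc_known & aa == alt
  if (any(flip)) hap[, flip] <- 1L - hap[, flip]
  o <- order(pos)
  hap <- hap[, o, drop = FALSE]; pos <- pos[o]; anc_known <- anc_known[o]
  cm <- if (is.null(genetic_map)) pos * 1e-6
  else interpolate_cM(pos, genetic_map)
  haplotype_panel(hap, pos, positions_cM = cm,
                  ancestral_known = anc_known,
                  region_length = if (is.null(region_length)) max(pos)
                  else region_length)
}

#' Write / read a genetic map
#'
#' Three-column TSV: chromosome, physical position (bp), cumulative
#' genetic position (cM).
#'
#' @param panel a [haplotype_panel()] (its variant coordinates define the
#'   map) or a data.frame with `chrom`, `pos_bp`, `cM`.
#' @param path file path.
#' @param chrom chromosome label for panel input.
#' @return `path` invisibly, or for the reader a data.frame with `chrom`,
#'   `pos_bp`, `cM`.
#' @export
write_genetic_map <- function(panel, path, chrom = "1") {
  df <- if (inherits(panel, "haplotype_panel"))
    data.frame(chrom = chrom, pos_bp = panel$positions_bp,
               cM = panel$positions_cM)
  else panel
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genetic_map
#' @export
read_genetic_map <- function(path) {
  read.table(path, header = TRUE, sep = "\t",
             col.names = c("chrom", "pos_bp", "cM"))
}

# linear interpolation of cM at arbitrary bp positions
interpolate_cM <- function(pos_bp, genetic_map) {
  stats::approx(genetic_map$pos_bp, genetic_map$cM, xout = pos_bp,
                rule = 2)$y
}

#' Write / read gene regions as BED
#'
#' BED semantics: 0-based, half-open intervals. The writer takes 1-based
#' inclusive `start`/`end` columns and converts; the reader converts
#' back.
#'
#' @param regions data.frame with `chrom`, `start`, `end` (1-based,
#'   inclusive) and optionally `name`.
#' @param path file path.
#' @return `path` invisibly; the reader returns the 1-based data.frame.
#' @export
write_bed <- function(regions, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(regions)))
  df <- data.frame(chrom = regions$chrom, start = regions$start - 1L,
                   end = regions$end)
  if (!is.null(regions$name)) df$name <- regions$name
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  df <- read.table(path, header = FALSE, sep = "\t")
  names(df) <- c("chrom", "start", "end", "name")[seq_len(ncol(df))]
  df$chrom <- as.character(df$chrom)
  df$start <- df$start + 1L
  df
}

#' Write / read a network edge list
#'
#' Two-column TSV of gene-ID pairs with a header.
#'
#' @param network an `igraph` graph or a two-column data.frame.
#' @param path file path.
#' @return `path` invisibly; the reader returns a two-column data.frame.
#' @export
write_edge_list <- function(network, path) {
  el <- if (igraph::is_igraph(network))
    as.data.frame(igraph::as_edgelist(network))
  else as.data.frame(network)[, 1:2]
  names(el) <- c("gene_a", "gene_b")
  write.table(el, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  read.table(path, header = TRUE, sep = "\t",
             colClasses = "character")
}

#' Write / read a protein alignment as FASTA
#'
#' @param alignment a [protein_alignment()].
#' @param path file path.
#' @return `path` invisibly; the reader returns a `protein_alignment`.
#' @export
write_alignment_fasta <- function(alignment, path) {
  stopifnot(inherits(alignment, "protein_alignment"))
  seqinr::write.fasta(lapply(seq_len(nrow(alignment)),
                             function(i) alignment[i, ]),
                      names = rownames(alignment), file.out = path)
  invisible(path)
}

#' @rdname write_alignment_fasta
#' @export
read_alignment_fasta <- function(path) {
  seqs <- seqinr::read.fasta(path, seqtype = "AA", set.attributes = FALSE)
  mat <- do.call(rbind, lapply(seqs, toupper))
  rownames(mat) <- names(seqs)
  protein_alignment(mat)
}

#' Write / read a simulation configuration as flat key=value text
#'
#' Sweep fields are flattened with a `sweep_` prefix; absent sweep means
#' neutral.
#'
#' @param cfg a [sim_config()].
#' @param path file path.
#' @return `path` invisibly; the reader returns a `sim_config`.
#' @export
write_sim_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  kv <- c(n_haplotypes = cfg$n_haplotypes,
          region_length = cfg$region_length,
          mutation_rate = cfg$mutation_rate,
          recombination_rate = cfg$recombination_rate,
          population_size = cfg$population_size,
          n_generations = cfg$n_generations,
          burnin_factor = cfg$burnin_factor,
          fix_sample_freq = cfg$fix_sample_freq,
          max_retries = cfg$max_retries)
  if (!is.null(cfg$seed)) kv <- c(kv, seed = cfg$seed)
  if (!is.null(cfg$sweep))
    kv <- c(kv, sweep_position = cfg$sweep$position,
            sweep_selection_coefficient = cfg$sweep$selection_coefficient,
            sweep_start_frequency = cfg$sweep$start_frequency)
  writeLines(sprintf("%s=%.15g", names(kv), as.numeric(kv)), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- setNames(as.numeric(vapply(kv, `[`, character(1), 2)),
                   vapply(kv, `[`, character(1), 1))
  sweep <- if ("sweep_position" %in% names(vals))
    list(position = vals[["sweep_position"]],
         selection_coefficient = vals[["sweep_selection_coefficient"]],
         start_frequency = vals[["sweep_start_frequency"]])
  else NULL
  sim_config(n_haplotypes = vals[["n_haplotypes"]],
             region_length = vals[["region_length"]],
             mutation_rate = vals[["mutation_rate"]],
             recombination_rate = vals[["recombination_rate"]],
             population_size = vals[["population_size"]],
             n_generations = vals[["n_generations"]],
             burnin_factor = vals[["burnin_factor"]],
             sweep = sweep,
             fix_sample_freq = vals[["fix_sample_freq"]],
             max_retries = vals[["max_retries"]],
             seed = if ("seed" %in% names(vals)) vals[["seed"]] else NULL)
}

#' Write a gene score table as TSV
#'
#' @param table data.frame from [score_genes()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_score_table
#' @export
read_score_table <- function(path) {
  read.table(path, header = TRUE, sep = "\t")
}
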