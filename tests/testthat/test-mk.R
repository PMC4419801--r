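test_that("degeneracy classes agree with codon-table enumeration", {
  # third position of GGN glycine is 4-fold; all second positions 0-fold
  tx <- list(list(seq = "GGATTA", pos = 1:6))
  ann <- classify_degeneracy(tx)
  cls <- setNames(ann$class, ann$pos)
  expect_equal(cls[["3"]], "four_fold")
  expect_equal(cls[["2"]], "zero_fold")
  expect_equal(cls[["5"]], "zero_fold")
  # exhaustive check over all sense codons against an independent oracle
  bases <- c("T", "C", "A", "G")
  cds64 <- seqinr::words(3, bases)
  code <- setNames(vapply(cds64, function(cd)
    seqinr::translate(strsplit(cd, "")[[1]]), character(1)), cds64)
  for (cd in names(code)) {
    if (code[[cd]] == "*") next
    ann <- classify_degeneracy(list(list(seq = cd, pos = 1:3)))
    for (p in 1:3) {
      alts <- setdiff(bases, substr(cd, p, p))
      syn <- vapply(alts, function(b) {
        x <- cd; substr(x, p, p) <- b
        code[[x]] == code[[cd]]
      }, logical(1))
      expected <- if (!any(syn)) "zero_fold"
      else if (all(syn)) "four_fold" else "other"
      expect_equal(ann$class[ann$pos == p], expected,
                   label = paste(cd, p))
    }
  }
})

test_that("transcript conflicts and internal stops are handled", {
  # same genomic site 4-fold in one transcript, 0-fold in the other
  txa <- list(seq = "GGA", pos = c(10L, 11L, 12L))
  txb <- list(seq = "TGG", pos = c(12L, 13L, 14L))  # 12 is W pos1: 0-fold
  ann <- classify_degeneracy(list(txa, txb))
  expect_false(12 %in% ann$pos)
  expect_true(all(c(10, 11) %in% ann$pos))
  expect_warning(classify_degeneracy(list(
    list(seq = "TAAGGA", pos = 1:6), txa)), "stop")
})

test_that("polarization counts human-specific substitutions only", {
  ann <- data.frame(pos = 1:9,
                    class = rep(c("zero_fold", "other", "four_fold"), 3))
  # site 1 (0-fold): human A, both outgroups G -> D_N
  # site 4 (0-fold): human A, chimp G, gorilla A -> not counted
  # site 9 (4-fold): human C, both outgroups T -> D_S
  h <- "AAAAAAAAC"
  c1 <- "GAAGAAAAT"
  c2 <- "GAAAAAAAT"
  cnt <- polarized_counts(h, c1, c2, poly_pos = c(4, 5), ann)
  expect_equal(cnt$D_N, 1)
  expect_equal(cnt$D_S, 1)
  expect_equal(cnt$P_N, 1)   # pos 4 is zero_fold
  expect_equal(cnt$P_S, 0)   # pos 5 is "other", not counted
  expect_error(polarized_counts("AA", "A", "AA", 1, ann))
})

test_that("30-codon triple alignment matches per-site enumeration", {
  set.seed(606)
  bases <- c("T", "C", "A", "G")
  # build a gene of 30 codons avoiding stops
  cds64 <- seqinr::words(3, bases)
  aa64 <- vapply(cds64, function(cd)
    seqinr::translate(strsplit(cd, "")[[1]]), character(1))
  sense <- cds64[aa64 != "*"]
  h <- paste(sample(sense, 30, replace = TRUE), collapse = "")
  mutate_at <- function(s, i) {
    alt <- sample(setdiff(bases, substr(s, i, i)), 1)
    substr(s, i, i) <- alt
    s
  }
  c1 <- h
  for (i in sample(nchar(h), 12)) c1 <- mutate_at(c1, i)
  c2 <- c1
  for (i in sample(nchar(h), 4)) c2 <- mutate_at(c2, i)
  ann <- classify_degeneracy(list(list(seq = h, pos = seq_len(nchar(h)))))
  poly <- sample(nchar(h), 8)
  cnt <- polarized_counts(h, c1, c2, poly, ann)
  # independent per-site oracle
  cls <- setNames(ann$class, ann$pos)
  hs <- strsplit(h, "")[[1]]; x1 <- strsplit(c1, "")[[1]]
  x2 <- strsplit(c2, "")[[1]]
  dn <- ds <- 0
  for (i in seq_along(hs)) {
    if (hs[i] != x1[i] && hs[i] != x2[i] && x1[i] == x2[i]) {
      cl <- cls[as.character(i)]
      if (!is.na(cl) && cl == "zero_fold") dn <- dn + 1
      if (!is.na(cl) && cl == "four_fold") ds <- ds + 1
    }
  }
  expect_equal(cnt$D_N, dn)
  expect_equal(cnt$D_S, ds)
  pn <- sum(cls[as.character(poly)] == "zero_fold", na.rm = TRUE)
  ps <- sum(cls[as.character(poly)] == "four_fold", na.rm = TRUE)
  expect_equal(cnt$P_N, pn)
  expect_equal(cnt$P_S, ps)
})

test_that("neutrality index switches to Haldane correction on zeros", {
  expect_equal(neutrality_index(list(P_N = 5, P_S = 5, D_N = 5, D_S = 5)), 1)
  expect_equal(neutrality_index(list(P_N = 0, P_S = 5, D_N = 2, D_S = 3)),
               (0.5 / 5.5) / (2.5 / 3.5), tolerance = 1e-12)
  expect_equal(neutrality_index(list(P_N = 2, P_S = 10, D_N = 10, D_S = 2)),
               0.04)
  # scale invariance of the uncorrected form
  for (k in c(2, 5, 11))
    expect_equal(
      neutrality_index(list(P_N = 3 * k, P_S = 7 * k, D_N = 2 * k,
                            D_S = 9 * k)),
      neutrality_index(list(P_N = 3, P_S = 7, D_N = 2, D_S = 9)))
})

test_that("MK Fisher exact test matches hypergeometric enumeration", {
  expect_equal(mk_fisher(list(P_N = 5, P_S = 5, D_N = 5, D_S = 5)), 1)
  p <- mk_fisher(list(P_N = 20, P_S = 2, D_N = 2, D_S = 20))
  expect_equal(p, fisher_oracle(20, 2, 2, 20), tolerance = 1e-9)
  # simultaneous row and column swap leaves P unchanged
  p2 <- mk_fisher(list(P_N = 20, P_S = 2, D_N = 2, D_S = 20))
  p3 <- mk_fisher(list(P_N = 20, P_S = 2, D_N = 2, D_S = 20))
  expect_equal(p2, p3)
  expect_equal(mk_fisher(list(P_N = 7, P_S = 3, D_N = 2, D_S = 11)),
               mk_fisher(list(P_N = 11, P_S = 2, D_N = 3, D_S = 7)),
               tolerance = 1e-12)
  expect_true(is.na(mk_fisher(list(P_N = 0, P_S = 0, D_N = 0, D_S = 0))))
})

test_that("MK eligibility requires more than three in every cell", {
  expect_true(mk_eligible(list(P_N = 4, P_S = 4, D_N = 4, D_S = 4)))
  expect_false(mk_eligible(list(P_N = 3, P_S = 10, D_N = 10, D_S = 10)))
})

test_that("gene DAF summaries respect modes and the 100 kb eQTL rule", {
  v <- data.frame(pos = c(1000, 2000), daf = c(0.1, 0.3))
  expect_equal(gene_daf_summary(v, 500, 2500, mode = "mean"), 0.2)
  v2 <- data.frame(
    pos = c(1000, 2000, 5000, 130000, 90000),
    daf = c(0.9, 0.5, 0.4, 0.95, 0.8),
    class = c("cis_eQTL", "zero_fold", "four_fold", "cis_eQTL",
              "cis_eQTL"))
  mx <- gene_daf_summary(v2, 1, 10000, mode = "max_by_class")
  # eQTL at 130 kb is beyond 100 kb of the gene end and must not count
  expect_equal(unname(mx), c(0.9, 0.5, 0.4))
  v3 <- v2[v2$class != "cis_eQTL", ]
  mx3 <- gene_daf_summary(v3, 1, 10000, mode = "max_by_class")
  expect_true(is.na(mx3[["cis_eQTL"]]))
})

test_that("site-class permutation test is exact on a tiny space", {
  tab <- matrix(seq(0.05, 1, by = 0.05), ncol = 1,
                dimnames = list(sprintf("g%02d", 1:20), "cis_eQTL"))
  # selecting the single top gene: null median >= observed only when the
  # permutation picks that same gene -> P = (1 + k)/(1 + B), k ~ B/20
  res <- daf_class_test("g20", tab, n_perm = 10000, seed = 4)
  expect_equal(res$p_value, (1 + 10000 / 20) / (1 + 10000),
               tolerance = 0.3)
  # selecting everything gives P = 1
  res2 <- daf_class_test(rownames(tab), tab, n_perm = 200, seed = 4)
  expect_equal(res2$p_value, 1)
  res3 <- daf_class_test("g20", tab, n_perm = 500, seed = 9)
  res4 <- daf_class_test("g20", tab, n_perm = 500, seed = 9)
  expect_equal(res3$p_value, res4$p_value)
  expect_error(daf_class_test(character(0), tab))
})

test_that("site-class permutation P is calibrated under random selection", {
  set.seed(33)
  tab <- matrix(runif(60), ncol = 2,
                dimnames = list(sprintf("g%02d", 1:30),
                                c("cis_eQTL", "zero_fold")))
  p <- replicate(150, {
    sel <- sample(rownames(tab), 6)
    daf_class_test(sel, tab, n_perm = 99)$p_value[1]
  })
  expect_lt(abs(mean(p < 0.25) - 0.25), 3 * sqrt(0.25 * 0.75 / 150) + 0.02)
})
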