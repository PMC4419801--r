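# 8-haplotype fixture: derived carriers (rows 1-4) stay identical over the
# flanking variants, ancestral carriers (rows 5-8) are maximally diverse
sweep_fixture <- function() {
  hap <- matrix(0L, 8, 5)
  hap[1:4, 3] <- 1L                       # core at column 3
  hap[5, 1] <- 1L; hap[6, 2] <- 1L        # ancestral diversity left
  hap[7, 4] <- 1L; hap[8, 5] <- 1L        # and right
  make_panel(hap, pos = c(100L, 200L, 300L, 400L, 500L))
}

test_that("EHH starts at 1 and matches pair enumeration", {
  hap <- matrix(0L, 8, 3)
  hap[1:4, 2] <- 1L            # core: carriers rows 1-4
  hap[4, 3] <- 1L              # next site splits carriers 3 + 1
  p <- make_panel(hap)
  curve <- ehh(p, core = 2, allele = "derived", direction = "right")
  expect_equal(curve$ehh[1], 1)
  expect_equal(curve$distance_bp[1], 0)
  expect_equal(curve$ehh[2], choose(3, 2) / choose(4, 2))  # = 0.5
  expect_error(ehh(make_panel(matrix(c(0, 0, 0, 1), 4, 1)), 1,
                   allele = "derived"))
})

test_that("EHH is non-increasing, bounded, and 1 for identical carriers", {
  set.seed(5)
  for (rep in 1:10) {
    hap <- matrix(rbinom(16 * 12, 1, 0.3), 16, 12)
    hap[, 6] <- rep(c(0L, 1L), each = 8)
    p <- make_panel(hap)
    for (dir in c("left", "right")) {
      cv <- ehh(p, 6, "derived", dir)
      expect_true(all(diff(cv$ehh) <= 1e-12))
      expect_true(all(cv$ehh >= 0 & cv$ehh <= 1))
    }
  }
  hap <- matrix(0L, 6, 4)
  hap[1:3, 2] <- 1L
  cv <- ehh(make_panel(hap), 2, "derived", "right")
  expect_true(all(cv$ehh == 1))
})

test_that("mirror-symmetric haplotype structure gives raw iHS of zero", {
  hap <- matrix(0L, 8, 3)
  hap[1:4, 2] <- 1L
  hap[1, 1] <- 1L              # one derived carrier differs left
  hap[5, 3] <- 1L              # one ancestral carrier differs right
  hap[1, 3] <- 1L; hap[5, 1] <- 1L  # complete the mirror
  p <- make_panel(hap)
  expect_equal(ihs_raw(p, 2), 0, tolerance = 1e-12)
})

test_that("homogeneous derived haplotypes drive raw iHS negative", {
  p <- sweep_fixture()
  raw <- ihs_raw(p, 3)
  expect_lt(raw, 0)
  # direct integral oracle: trapezoid evaluation by hand.
  # derived carriers identical at all flanking sites -> EHH stays 1 on
  # both sides out to the last variant (200 bp each way).
  ihh_d <- 200 + 200
  # ancestral carriers: left at 100 bp EHH drops to C(3,2)/C(4,2) = 0.5,
  # then 100 bp further to C(2,2)/C(4,2) = 1/6, crossing 0.15 never; the
  # curve integrates trapezoidally.
  ihh_a_left <- 100 * (1 + 0.5) / 2 + 100 * (0.5 + 1 / 6) / 2
  expect_equal(log(2 * ihh_a_left / ihh_d), raw, tolerance = 1e-12)
})

test_that("integration ignores everything beyond the 0.15 crossing", {
  # derived EHH crosses 0.15 between 200 and 300 bp; a variant at 400 bp
  # seen only by derived carriers must not change the score
  base <- function(col4_rows) {
    hap <- matrix(0L, 12, 4)
    hap[1:6, 1] <- 1L                   # core, derived rows 1-6
    hap[c(1, 2, 7, 8), 2] <- 1L         # splits both carrier sets
    hap[c(1, 3, 5), 3] <- 1L            # derived EHH -> 2/15 < 0.15
    hap[col4_rows, 4] <- 1L             # beyond the crossing
    make_panel(hap, pos = c(100L, 200L, 300L, 400L))
  }
  a <- ihs_raw(base(2), 1)
  b <- ihs_raw(base(c(4, 6)), 1)
  expect_equal(a, b, tolerance = 1e-12)
  # and the value matches the trapezoid-with-interpolated-crossing oracle:
  # derived truncates at the 0.15 crossing; ancestral stays at 7/15 over
  # the carrier-uninformative markers at 300 and 400 bp
  e1 <- 7 / 15; e2 <- 2 / 15
  xc <- 100 + 100 * (e1 - 0.15) / (e1 - e2)
  ihh_d <- 100 * (1 + e1) / 2 + (xc - 100) * (e1 + 0.15) / 2
  ihh_a <- 100 * (1 + e1) / 2 + 100 * e1 + 100 * e1
  expect_equal(a, log(ihh_a / ihh_d), tolerance = 1e-12)
})

test_that("iHS is invariant to inserted monomorphic columns", {
  p <- sweep_fixture()
  raw0 <- ihs_raw(p, 3)
  hap2 <- cbind(p$haplotypes[, 1:2], 0L, p$haplotypes[, 3:5], 0L)
  p2 <- make_panel(hap2, pos = c(100L, 200L, 250L, 300L, 400L, 500L, 550L))
  expect_equal(ihs_raw(p2, 4), raw0, tolerance = 1e-12)
})

test_that("standardization centres and scales within DAF bins", {
  out <- standardize_ihs(c(1, 3), c(0.02, 0.03))
  expect_equal(as.numeric(out), c(-1, 1))
  # 20 bins all occupied -> 20 (mean, sd) rows
  set.seed(8)
  daf <- rep(seq(0.025, 0.975, by = 0.05), each = 5)
  sc <- rnorm(length(daf))
  out2 <- standardize_ihs(sc, daf)
  bins <- attr(out2, "bins")
  expect_equal(nrow(bins), 20)
  # exact zero mean / unit sd per occupied bin
  for (b in unique(ceiling(daf / 0.05))) {
    v <- out2[ceiling(daf / 0.05) == b]
    expect_equal(mean(v), 0, tolerance = 1e-12)
    expect_equal(sqrt(mean(v^2)), 1, tolerance = 1e-12)
  }
  # order invariance
  perm <- sample(length(daf))
  out3 <- standardize_ihs(sc[perm], daf[perm])
  expect_equal(as.numeric(out3), as.numeric(out2)[perm], tolerance = 1e-12)
  # idempotence
  out4 <- standardize_ihs(as.numeric(out2), daf)
  expect_equal(as.numeric(out4), as.numeric(out2), tolerance = 1e-12)
  # degenerate bin -> NA
  out5 <- standardize_ihs(c(2, 2), c(0.12, 0.13))
  expect_true(all(is.na(out5)))
})
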