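test_that("permutation mean-difference P matches exhaustive enumeration", {
  v <- c(3.2, 1.1, 4.8, 0.5, 2.9, 7.7)
  lab <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  exact <- perm_exact_oracle(v, lab)
  res <- permutation_mean_diff(v, lab, n_perm = 40000, seed = 2)
  expect_equal(res$p_value, exact, tolerance = 0.05)
  same <- permutation_mean_diff(rep(2, 8), rep(c(TRUE, FALSE), 4),
                                n_perm = 500, seed = 1)
  expect_equal(same$p_value, 1)
  r1 <- permutation_mean_diff(v, lab, n_perm = 300, seed = 7)
  r2 <- permutation_mean_diff(v, lab, n_perm = 300, seed = 7)
  expect_equal(r1$p_value, r2$p_value)
  expect_error(permutation_mean_diff(v, rep(TRUE, 6)))
})

test_that("permutation P is calibrated under the null", {
  set.seed(404)
  p <- replicate(200, {
    v <- rnorm(30)
    lab <- sample(rep(c(TRUE, FALSE), 15))
    permutation_mean_diff(v, lab, n_perm = 99)$p_value
  })
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 1e-3)
  expect_lt(abs(mean(p < 0.25) - 0.25), 3 * sqrt(0.25 * 0.75 / 200))
})

test_that("Spearman correlation handles ties by midranks", {
  x <- 1:10
  expect_equal(spearman_assoc(x, x)$rho, 1)
  expect_equal(spearman_assoc(x, rev(x))$rho, -1)
  set.seed(5)
  xf <- c(1, 2, 2, 3, 4, 4, 4, 5, 6, 7, 8, 8)
  yf <- c(2, 1, 3, 3, 5, 4, 6, 5, 7, 9, 8, 10)
  res <- spearman_assoc(xf, yf)
  # midrank oracle through Pearson on explicit midranks
  oracle <- cor(rank(xf, ties.method = "average"),
                rank(yf, ties.method = "average"))
  expect_equal(res$rho, oracle, tolerance = 1e-12)
  ct <- suppressWarnings(cor.test(xf, yf, method = "spearman"))
  expect_equal(res$rho, unname(ct$estimate), tolerance = 1e-12)
  expect_error(spearman_assoc(rep(1, 6), 1:6))
})

test_that("quartile grouping uses lower-closed boundaries", {
  expect_equal(quartile_groups(1:8), rep(1:4, each = 2))
  v <- c(10, 10, 10, 10)
  expect_equal(quartile_groups(v), rep(1L, 4))
  x <- rexp(40)
  expect_equal(quartile_groups(x), quartile_groups(rank(x)))
})

test_that("rank tests detect a monotone trend and are calibrated", {
  g <- rep(1:4, each = 10)
  set.seed(8)
  sc <- g + rnorm(40, sd = 0.3)
  res <- rank_group_tests(g, sc)
  expect_gt(res$slope, 0)
  expect_lt(res$p_trend, 1e-6)
  expect_lt(res$p_anova, 1e-4)
  # two groups: ANOVA-on-ranks F is the square of the rank-sum t
  g2 <- rep(1:2, each = 8)
  sc2 <- rnorm(16)
  res2 <- rank_group_tests(g2, sc2)
  r <- rank(sc2)
  tt <- t.test(r[g2 == 1], r[g2 == 2], var.equal = TRUE)
  expect_equal(res2$f_anova, unname(tt$statistic)^2, tolerance = 1e-10)
  # calibration under exchangeability
  p <- replicate(200, rank_group_tests(sample(g), rnorm(40))$p_anova)
  expect_lt(abs(mean(p < 0.25) - 0.25), 3 * sqrt(0.25 * 0.75 / 200))
  expect_error(rank_group_tests(rep(1, 10), rnorm(10)))
})

test_that("confounder residuals solve the normal equations", {
  set.seed(12)
  n <- 50
  cov <- data.frame(len = rnorm(n), expr = rnorm(n), breadth = rnorm(n))
  beta <- c(2, -1, 0.5)
  y <- 1 + as.matrix(cov) %*% beta + rnorm(n, sd = 0.1)
  r <- confounder_residuals(as.numeric(y), cov)
  X <- cbind(1, as.matrix(cov))
  r_oracle <- as.numeric(y - X %*% solve(t(X) %*% X, t(X) %*% y))
  expect_equal(as.numeric(r), r_oracle, tolerance = 1e-8)
  # exact linear score -> residuals ~ 0
  y2 <- as.numeric(1 + as.matrix(cov) %*% beta)
  expect_lt(max(abs(confounder_residuals(y2, cov))), 1e-8)
  # covariate orthogonal to the score -> residuals = centred score
  covo <- data.frame(a = rep(c(-1, 1), 24))
  y3 <- 5.5 + rep(c(1, -1, -1, 1), 12)
  r3 <- confounder_residuals(y3, covo)
  expect_equal(as.numeric(r3), y3 - mean(y3), tolerance = 1e-10)
  # collinear covariates are reported
  cov_bad <- data.frame(a = 1:n, b = 2 * (1:n))
  expect_error(confounder_residuals(rnorm(n), cov_bad), "collinear")
  # missing covariates drop only those genes
  cov_na <- cov; cov_na$len[3] <- NA
  rr <- confounder_residuals(as.numeric(y), cov_na)
  expect_true(is.na(rr[3]))
  expect_equal(sum(is.na(rr)), 1)
})

test_that("Mann-Whitney matches exact enumeration for separated groups", {
  sc <- c(1:5, 11:15)
  tr <- rep(c(FALSE, TRUE), each = 5)
  res <- two_group_test(sc, tr)
  expect_equal(res$p_value, 2 / choose(10, 5), tolerance = 1e-12)
  expect_equal(res$u, 25)
  same <- two_group_test(rep(1:6, 2), rep(c(TRUE, FALSE), each = 6))
  expect_gt(same$p_value, 0.99)
  # power grows with the shift
  set.seed(3)
  pv <- vapply(c(0, 1, 3), function(d) {
    mean(replicate(50, {
      two_group_test(c(rnorm(12), rnorm(12, d)),
                     rep(c(FALSE, TRUE), each = 12))$p_value
    }) < 0.05)
  }, numeric(1))
  expect_true(pv[1] < pv[2] && pv[2] <= pv[3])
  expect_error(two_group_test(1:4, rep(TRUE, 4)))
})

test_that("tests are invariant to row order", {
  set.seed(21)
  v <- rnorm(24); lab <- rep(c(TRUE, FALSE), 12)
  perm <- sample(24)
  a <- permutation_mean_diff(v, lab, n_perm = 200, seed = 5)$statistic
  b <- permutation_mean_diff(v[perm], lab[perm], n_perm = 200,
                             seed = 5)$statistic
  expect_equal(a, b)
  expect_equal(spearman_assoc(v, v^3 + 1)$rho,
               spearman_assoc(v[perm], (v^3 + 1)[perm])$rho)
})
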