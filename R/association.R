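#' Permutation test for a difference in group means
#'
#' Observed statistic: `mean(values[labels]) - mean(values[!labels])`.
#' The null distribution is built by randomly permuting the labels; the
#' two-sided P value is the add-one-corrected fraction of permuted
#' |differences| at least as large as the observed one. This is the test
#' used to ask whether selected genes have an unusual mean degree.
#'
#' @param values numeric vector (e.g. degrees).
#' @param labels logical (or 0/1) vector of the same length; both groups
#'   must be non-empty.
#' @param n_perm number of permutations (default 10,000).
#' @param seed integer seed (`NULL`: current RNG).
#' @return list with `statistic` (observed difference), `p_value`,
#'   `n_perm`, `group_means`, `seed`.
#' @export
permutation_mean_diff <- function(values, labels, n_perm = 10000,
                                  seed = NULL) {
  labels <- as.logical(labels)
  stopifnot(length(values) == length(labels), !any(is.na(values)),
            !any(is.na(labels)))
  if (!any(labels) || all(labels)) stop("both groups must be non-empty")
  if (!is.null(seed)) set.seed(seed)
  obs <- mean(values[labels]) - mean(values[!labels])
  k <- sum(labels)
  ge <- 0L
  for (b in seq_len(n_perm)) {
    idx <- sample(length(values), k)
    d <- mean(values[idx]) - mean(values[-idx])
    if (abs(d) >= abs(obs)) ge <- ge + 1L
  }
  list(statistic = obs, p_value = (1 + ge) / (1 + n_perm),
       n_perm = n_perm,
       group_means = c(group1 = mean(values[labels]),
                       group0 = mean(values[!labels])),
       seed = seed)
}

#' Spearman rank correlation with midrank ties
#'
#' Pearson correlation of midranks, with the large-sample t approximation
#' `t = rho * sqrt((n-2)/(1-rho^2))` on n-2 degrees of freedom
#' (two-sided).
#'
#' @param x,y paired numeric vectors, n >= 5.
#' @return list with `rho`, `p_value`, `n`.
#' @export
spearman_assoc <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  stopifnot(n >= 5)
  if (sd(x) == 0 || sd(y) == 0)
    stop("constant vector: rank correlation undefined")
  rho <- stats::cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0
  else 2 * pt(-abs(rho * sqrt((n - 2) / (1 - rho^2))), df = n - 2)
  list(rho = rho, p_value = p, n = n)
}

#' Quartile group codes
#'
#' Bins values into four ordered groups (low to high) at the first,
#' second and third quartiles; values falling exactly on a cut point go
#' to the lower group, a deterministic, order-independent convention.
#'
#' @param values numeric vector, n >= 4.
#' @return integer codes 1..4.
#' @export
quartile_groups <- function(values) {
  stopifnot(length(values) >= 4, !any(is.na(values)))
  q <- quantile(values, c(0.25, 0.5, 0.75), names = FALSE)
  1L + (values > q[1]) + (values > q[2]) + (values > q[3])
}

#' Nonparametric ANOVA and linear trend test on ranks
#'
#' Scores are midrank-transformed; the ANOVA F statistic tests any
#' difference in mean rank across the (ordered) groups, and the trend F
#' tests the slope of the regression of ranks on the numeric group codes
#' — the more powerful test when the alternative is monotone in
#' centrality class.
#'
#' @param groups integer/factor group codes (ordered 1..k); at least two
#'   non-empty groups.
#' @param scores numeric scores of the same length.
#' @return list with `f_anova`, `p_anova`, `f_trend`, `p_trend`,
#'   `slope` (trend slope on ranks), `n`.
#' @export
rank_group_tests <- function(groups, scores) {
  g <- as.integer(as.factor(groups))
  stopifnot(length(g) == length(scores), !any(is.na(scores)))
  if (length(unique(g)) < 2) stop("need at least two non-empty groups")
  r <- rank(scores)
  fit_a <- lm(r ~ factor(g))
  aov_tab <- anova(fit_a)
  code <- as.numeric(groups)
  fit_t <- lm(r ~ code)
  trend_tab <- anova(fit_t)
  list(f_anova = aov_tab$`F value`[1], p_anova = aov_tab$`Pr(>F)`[1],
       f_trend = trend_tab$`F value`[1], p_trend = trend_tab$`Pr(>F)`[1],
       slope = unname(coef(fit_t)[2]), n = length(r))
}

#' Residualize a selection score on confounders
#'
#' Ordinary least-squares regression of the score on the supplied
#' covariates (protein length, expression level, expression breadth, ...)
#' with an intercept; the residuals are returned for use in partial
#' analyses, removing variation attributable to the confounders before
#' any rank test is run. Rows with missing values are dropped from the
#' fit and carry `NA` residuals.
#'
#' @param score numeric response.
#' @param covariates data.frame of numeric covariates.
#' @return numeric vector of residuals aligned with `score` (`NA` for
#'   incomplete rows); attribute `coefficients` holds the fit.
#' @export
confounder_residuals <- function(score, covariates) {
  covariates <- as.data.frame(covariates)
  stopifnot(nrow(covariates) == length(score))
  d <- cbind(.score = score, covariates)
  cc <- complete.cases(d)
  if (sum(cc) <= ncol(covariates) + 1)
    stop("too few complete cases for the regression")
  fit <- lm(.score ~ ., data = d[cc, ])
  if (any(is.na(coef(fit)))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop("collinear covariates: ", paste(bad, collapse = ", "))
  }
  out <- rep(NA_real_, length(score))
  out[cc] <- stats::residuals(fit)
  attr(out, "coefficients") <- coef(fit)
  out
}

#' Mann-Whitney two-group test
#'
#' Two-sided rank-sum comparison of scores between the two levels of a
#' binary trait (e.g. essential versus non-essential genes): exact
#' enumeration when both groups have at most `exact_max` observations and
#' no ties, otherwise the normal approximation with midranks.
#'
#' @param scores numeric vector.
#' @param binary_trait logical (or 0/1) vector; both levels must occur.
#' @param exact_max exact-enumeration size limit per group (default 10).
#' @return list with `u` (Mann-Whitney U for the `TRUE` group),
#'   `p_value`, `group_medians`, `n`.
#' @export
two_group_test <- function(scores, binary_trait, exact_max = 10) {
  tr <- as.logical(binary_trait)
  stopifnot(length(scores) == length(tr), !any(is.na(scores)),
            !any(is.na(tr)))
  if (!any(tr) || all(tr)) stop("both trait levels must be present")
  x <- scores[tr]; y <- scores[!tr]
  use_exact <- max(length(x), length(y)) <= exact_max &&
    !any(duplicated(scores))
  wt <- suppressWarnings(wilcox.test(x, y, exact = use_exact,
                                     correct = !use_exact))
  list(u = unname(wt$statistic), p_value = wt$p.value,
       group_medians = c(group1 = median(x), group0 = median(y)),
       n = length(scores))
}
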