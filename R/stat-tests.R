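# Paired-model comparison tests and the correlation matrix.

#' Two-sided mid-P McNemar test
#'
#' Compares two classifiers on the same observations through their
#' discordant pairs: with b = (A correct, B wrong), c = (A wrong, B
#' correct), n = b + c and k = max(b, c), the two-sided mid-P value is
#' 2 * (P(X >= k) - P(X = k) / 2) for X ~ Binomial(n, 1/2), capped at 1;
#' n = 0 gives p = 1. The mid-P variant halves the weight of the observed
#' count, removing the conservatism of the exact test on discrete data.
#'
#' @param correct_a,correct_b Logical vectors: per-observation correctness
#'   of models A and B, aligned.
#' @return Two-sided mid-P value.
#' @examples
#' mcnemar_midp(c(TRUE, TRUE, FALSE), c(TRUE, TRUE, FALSE))  # 1
#' @export
mcnemar_midp <- function(correct_a, correct_b) {
  if (length(correct_a) != length(correct_b)) stop("length mismatch")
  correct_a <- as.logical(correct_a)
  correct_b <- as.logical(correct_b)
  b <- sum(correct_a & !correct_b)
  c_ <- sum(!correct_a & correct_b)
  n <- b + c_
  if (n == 0) return(1)
  k <- max(b, c_)
  p <- 2 * (pbinom(k - 1, n, 0.5, lower.tail = FALSE) -
              0.5 * dbinom(k, n, 0.5))
  min(1, max(0, p))
}

#' DeLong's test for two correlated AUCs
#'
#' Nonparametric comparison of the AUCs of two score sets over the same
#' observations, using the structural-component (placement-value) estimate
#' of Var(AUC_a - AUC_b) that accounts for their correlation. The z
#' statistic is referred to the standard normal, two-sided. When the
#' estimated SE is zero and the AUCs are equal the p-value is 1.
#'
#' @param scores_a,scores_b Score vectors over the same observations.
#' @param truth Binary labels; at least 2 observations per class.
#' @param positive Positive-class label.
#' @return List: `auc_a`, `auc_b`, `z`, `p`, `se`.
#' @export
delong_paired_test <- function(scores_a, scores_b, truth,
                               positive = "noxious") {
  truth <- as.character(truth)
  stopifnot(length(scores_a) == length(truth),
            length(scores_b) == length(truth))
  pos <- truth == positive
  m <- sum(pos)
  n <- sum(!pos)
  if (m < 2 || n < 2) stop("need at least 2 observations per class")

  psi <- function(x_pos, x_neg) {
    # m x n matrix of Mann-Whitney kernel values
    outer(x_pos, x_neg, function(a, b) (a > b) + 0.5 * (a == b))
  }
  comp <- function(s) {
    k <- psi(s[pos], s[!pos])
    list(auc = mean(k), v10 = rowMeans(k), v01 = colMeans(k))
  }
  A <- comp(scores_a)
  B <- comp(scores_b)
  s10 <- stats::cov(cbind(A$v10, B$v10))
  s01 <- stats::cov(cbind(A$v01, B$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  se <- sqrt(max(0, var_diff))
  d <- A$auc - B$auc
  if (se == 0) {
    z <- if (d == 0) 0 else sign(d) * Inf
  } else {
    z <- d / se
  }
  p <- if (is.infinite(z)) 0 else 2 * pnorm(-abs(z))
  list(auc_a = A$auc, auc_b = B$auc, z = z, p = p, se = se)
}

#' @rdname delong_paired_test
#' @param scores Scores of a single classifier.
#' @return `delong_auc_variance()`: the structural-component estimate of
#'   Var(AUC) for one score set.
#' @export
delong_auc_variance <- function(scores, truth, positive = "noxious") {
  truth <- as.character(truth)
  pos <- truth == positive
  m <- sum(pos)
  n <- sum(!pos)
  if (m < 2 || n < 2) stop("need at least 2 observations per class")
  k <- outer(scores[pos], scores[!pos],
             function(a, b) (a > b) + 0.5 * (a == b))
  stats::var(rowMeans(k)) / m + stats::var(colMeans(k)) / n
}

#' Exact two-sided binomial test against a fixed proportion
#'
#' Two-sided p-value by the sum-of-smaller-probabilities rule: the sum of
#' P(X = i) over all i with P(X = i) <= P(X = k), X ~ Binomial(n, p0).
#' Used to compare a classifier's accuracy to chance (p0 = 0.5).
#'
#' @param k Successes.
#' @param n Trials.
#' @param p0 Null proportion (default 0.5).
#' @return Two-sided p-value.
#' @export
exact_binomial_two_sided <- function(k, n, p0 = 0.5) {
  if (k < 0 || k > n || n < 1) stop("need 0 <= k <= n, n >= 1")
  binom.test(k, n, p = p0)$p.value
}

#' Chi-square comparison of two accuracies
#'
#' Yates-corrected 2x2 chi-square test (df = 1) of correct/incorrect counts
#' across two strata (e.g. term vs preterm infants). Tables with an
#' expected cell below 5 carry a small-sample warning flag.
#'
#' @param correct1,correct2 Correct counts per group.
#' @param n1,n2 Group sizes.
#' @return List: `statistic`, `p`, `table`, `small_sample` flag.
#' @export
chi_square_accuracy <- function(correct1, n1, correct2, n2) {
  tab <- rbind(group1 = c(correct = correct1, incorrect = n1 - correct1),
               group2 = c(correct = correct2, incorrect = n2 - correct2))
  if (any(tab < 0)) stop("counts exceed group sizes")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero-margin table: chi-square undefined")
  }
  ht <- suppressWarnings(chisq.test(tab, correct = TRUE))
  list(statistic = unname(ht$statistic), p = ht$p.value, table = tab,
       small_sample = any(ht$expected < 5))
}

#' Pairwise-complete Spearman correlation matrix
#'
#' Spearman rho with mid-rank ties over pairwise-complete observations,
#' two-sided p by the t approximation t = rho * sqrt((n-2)/(1-rho^2)), and
#' a mask of nonsignificant pairs (p >= .05). Pairs with fewer than 3
#' complete rows are `NA`.
#'
#' @param feature_table Data frame or matrix of numeric measures (non-
#'   numeric columns are dropped).
#' @param alpha Significance threshold for the `ns` mask.
#' @return List of matrices: `rho`, `p`, `ns` (logical mask), `n`
#'   (pairwise-complete counts).
#' @export
spearman_matrix <- function(feature_table, alpha = 0.05) {
  x <- as.data.frame(feature_table)
  x <- x[vapply(x, is.numeric, logical(1))]
  x <- as.matrix(x)
  p_feat <- ncol(x)
  nm <- colnames(x)
  rho <- matrix(NA_real_, p_feat, p_feat, dimnames = list(nm, nm))
  pmat <- rho
  nmat <- matrix(0L, p_feat, p_feat, dimnames = list(nm, nm))
  for (i in seq_len(p_feat)) {
    rho[i, i] <- 1
    nmat[i, i] <- sum(!is.na(x[, i]))
    for (j in seq_len(p_feat)) {
      if (j <= i) next
      ok <- !is.na(x[, i]) & !is.na(x[, j])
      n <- sum(ok)
      nmat[i, j] <- nmat[j, i] <- n
      if (n < 3) next
      r <- cor(rank(x[ok, i]), rank(x[ok, j]))
      if (is.na(r)) next  # zero variance after ranking
      rho[i, j] <- rho[j, i] <- r
      pv <- if (abs(r) >= 1) 0 else {
        tstat <- r * sqrt((n - 2) / (1 - r^2))
        2 * pt(-abs(tstat), n - 2)
      }
      pmat[i, j] <- pmat[j, i] <- pv
    }
  }
  list(rho = rho, p = pmat, ns = !is.na(pmat) & pmat >= alpha, n = nmat)
}
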