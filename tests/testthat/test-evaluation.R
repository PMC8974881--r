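test_that("confusion metrics count the 2x2 table correctly", {
  all_right <- confusion_metrics(rep(c("noxious", "control"), 5),
                                 rep(c("noxious", "control"), 5))
  expect_equal(all_right$accuracy, 1)
  expect_equal(all_right$sensitivity, 1)
  expect_equal(all_right$specificity, 1)

  all_nox <- confusion_metrics(rep("noxious", 10),
                               rep(c("noxious", "control"), 5))
  expect_equal(all_nox$sensitivity, 1)
  expect_equal(all_nox$specificity, 0)

  # constructed table: TP 25, FN 7, TN 27, FP 5
  truth <- c(rep("noxious", 32), rep("control", 32))
  pred <- c(rep("noxious", 25), rep("control", 7),
            rep("control", 27), rep("noxious", 5))
  cm <- confusion_metrics(pred, truth)
  expect_equal(cm$accuracy, 52 / 64)
  expect_equal(cm$sensitivity, 25 / 32)
  expect_equal(cm$specificity, 27 / 32)

  one_class <- confusion_metrics(rep("noxious", 4), rep("noxious", 4))
  expect_true(is.na(one_class$specificity))
  expect_identical(one_class$undefined, "specificity")
  expect_error(confusion_metrics(character(0), character(0)), "empty")
})

test_that("wilson interval matches its closed form and contains k/n", {
  expect_equal(wilson_interval(0, 10)[["lower"]], 0)
  expect_equal(wilson_interval(10, 10)[["upper"]], 1)
  ci <- wilson_interval(52, 64)
  expect_equal(round(ci[["lower"]], 3), 0.700)
  expect_equal(round(ci[["upper"]], 3), 0.889)
  # exhaustive containment for n up to 200
  for (n in c(1:30, seq(40, 200, by = 10))) {
    for (k in 0:n) {
      ci <- wilson_interval(k, n)
      expect_true(ci[["lower"]] <= k / n + 1e-12 &&
                    k / n <= ci[["upper"]] + 1e-12)
    }
  }
  expect_error(wilson_interval(5, 4), "k <= n")
})

test_that("ROC/AUC equals the pairwise Mann-Whitney oracle", {
  perf <- roc_and_auc(c(0.9, 0.8, 0.2, 0.1),
                      c("noxious", "noxious", "control", "control"))
  expect_equal(perf$auc, 1)
  flat <- roc_and_auc(rep(0.5, 6), rep(c("noxious", "control"), 3))
  expect_equal(flat$auc, 0.5)

  set.seed(61)
  for (i in 1:100) {
    n <- 20
    scores <- sample(round(runif(n), 1))  # ties likely
    truth <- sample(rep(c("noxious", "control"), n / 2))
    perf <- roc_and_auc(scores, truth)
    expect_equal(perf$auc, oracle_auc(scores, truth == "noxious"))
    # monotone curve
    expect_true(all(diff(perf$curve$fpr) >= 0))
    expect_true(all(diff(perf$curve$tpr) >= 0))
    # complement symmetry for tie-free scores
    s2 <- runif(n)
    expect_equal(roc_and_auc(s2, truth)$auc +
                   roc_and_auc(-s2, truth)$auc, 1)
  }
  expect_error(roc_and_auc(1:4, rep("noxious", 4)), "both classes")
})

test_that("ROC agrees with the reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(7)
  scores <- runif(40)
  truth <- sample(rep(c("noxious", "control"), 20))
  ours <- roc_and_auc(scores, truth)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(truth, scores, levels = c("control",
                                                                  "noxious"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(ours, ref)
})

test_that("bootstrap AUC interval is deterministic and degenerate-safe", {
  scores <- c(0.9, 0.1, 0.8, 0.2, 0.95, 0.05, 0.7, 0.3)
  truth <- rep(c("noxious", "control"), 4)
  subj <- rep(1:4, each = 2)
  ci1 <- bootstrap_auc_ci(scores, truth, subj, n_boot = 200, seed = 9)
  ci2 <- bootstrap_auc_ci(scores, truth, subj, n_boot = 200, seed = 9)
  expect_identical(ci1, ci2)
  # separation survives any subject resample (pairs move together)
  expect_equal(unname(ci1[["lower"]]), 1)
  expect_equal(unname(ci1[["upper"]]), 1)
})

test_that("mid-P McNemar matches exact enumeration and its bounds", {
  expect_equal(mcnemar_midp(c(TRUE, FALSE, TRUE), c(TRUE, FALSE, TRUE)), 1)
  # b = 5, c = 1: enumerated Binomial(6, 1/2) tail
  a <- c(rep(TRUE, 5), FALSE, TRUE, TRUE)
  b <- c(rep(FALSE, 5), TRUE, TRUE, TRUE)
  expect_equal(mcnemar_midp(a, b), 0.125)
  expect_equal(mcnemar_midp(logical(0), logical(0)), 1)
  expect_error(mcnemar_midp(c(TRUE), c(TRUE, FALSE)), "length")

  # exhaustive: for all b + c <= 30, mid-p lies in [exact/2, exact]
  for (n in 1:30) {
    for (b_ in 0:n) {
      c_ <- n - b_
      k <- max(b_, c_)
      exact <- min(1, 2 * pbinom(k - 1, n, 0.5, lower.tail = FALSE))
      mid <- mcnemar_midp(c(rep(TRUE, b_), rep(FALSE, c_)),
                          c(rep(FALSE, b_), rep(TRUE, c_)))
      expect_lte(mid, exact + 1e-12)
      expect_gte(mid, exact / 2 - 1e-12)
      # direct enumeration of the mid-p definition
      want <- min(1, 2 * (sum(dbinom(k:n, n, 0.5)) - 0.5 * dbinom(k, n, 0.5)))
      expect_equal(mid, want)
    }
  }
})

test_that("DeLong test handles identity, crossings and small samples", {
  set.seed(17)
  truth <- rep(c("noxious", "control"), 15)
  s <- runif(30)
  same <- delong_paired_test(s, s, truth)
  expect_equal(same$auc_a, same$auc_b)
  expect_equal(same$p, 1)

  sa <- c(rnorm(30, 1), rnorm(30))
  tr <- c(rep("noxious", 30), rep("control", 30))
  sb <- c(rnorm(30, 0.5), rnorm(30))
  got <- delong_paired_test(sa, sb, tr)
  expect_true(got$p >= 0 && got$p <= 1)
  expect_equal(got$auc_a, oracle_auc(sa, tr == "noxious"))

  expect_error(delong_paired_test(c(1, 2, 3), c(1, 2, 3),
                                  c("noxious", "control", "control")),
               "at least 2")
})

test_that("DeLong single-AUC variance tracks the bootstrap variance", {
  set.seed(19)
  sa <- c(rnorm(30, 1), rnorm(30))
  tr <- c(rep("noxious", 30), rep("control", 30))
  v_delong <- delong_auc_variance(sa, tr)
  boots <- replicate(4000, {
    ip <- sample(30, replace = TRUE)
    in_ <- 30 + sample(30, replace = TRUE)
    painforest:::auc_fast(sa[c(ip, in_)],
                          c(rep(TRUE, 30), rep(FALSE, 30)))
  })
  expect_equal(v_delong, var(boots), tolerance = 0.15)
})

test_that("paired DeLong p is close to an exhaustive swap-permutation oracle", {
  truth <- rep(c("noxious", "control"), each = 4)
  sa <- c(0.49, 3.49, 2.01, 1.29, -0.21, 1.86, -0.07, -0.16)
  sb <- c(0.33, 3.73, 1.40, 1.36, 0.38, 1.79, -0.70, -0.90)
  got <- delong_paired_test(sa, sb, truth)
  obs <- abs(got$auc_a - got$auc_b)
  n <- length(truth)
  count <- 0L
  total <- 2^n
  for (mask in 0:(total - 1)) {
    swap <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
    a <- ifelse(swap, sb, sa)
    b <- ifelse(swap, sa, sb)
    d <- abs(oracle_auc(a, truth == "noxious") -
               oracle_auc(b, truth == "noxious"))
    if (d >= obs - 1e-12) count <- count + 1L
  }
  p_perm <- count / total
  expect_lt(abs(got$p - p_perm), 0.05)
})

test_that("DeLong agrees with the reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  truth <- rep(c("noxious", "control"), each = 20)
  sa <- c(rnorm(20, 1.2), rnorm(20))
  sb <- c(rnorm(20, 0.6), rnorm(20))
  ours <- delong_paired_test(sa, sb, truth)
  ra <- pROC::roc(truth, sa, levels = c("control", "noxious"),
                  direction = "<", quiet = TRUE)
  rb <- pROC::roc(truth, sb, levels = c("control", "noxious"),
                  direction = "<", quiet = TRUE)
  ref <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  expect_equal(ours$p, as.numeric(ref$p.value), tolerance = 1e-9)
})

test_that("exact binomial test follows the smaller-probability rule", {
  expect_equal(exact_binomial_two_sided(5, 10), 1)
  expect_equal(exact_binomial_two_sided(10, 10), 2 / 1024, tolerance = 1e-9)
  for (k in 0:12) {
    expect_equal(exact_binomial_two_sided(k, 12),
                 exact_binomial_two_sided(12 - k, 12))
  }
  expect_error(exact_binomial_two_sided(-1, 10), "k <= n")
})

test_that("chi-square accuracy comparison matches the textbook formula", {
  same <- chi_square_accuracy(20, 40, 10, 20)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)

  # hand-computed Yates chi-square for (30/40 vs 15/35)
  got <- chi_square_accuracy(30, 40, 15, 35)
  tab <- rbind(c(30, 10), c(15, 20))
  n <- sum(tab)
  e <- outer(rowSums(tab), colSums(tab)) / n
  want <- sum((abs(tab - e) - 0.5)^2 / e)
  expect_equal(got$statistic, want, tolerance = 1e-9)
  expect_false(got$small_sample)

  small <- chi_square_accuracy(3, 6, 2, 5)
  expect_true(small$small_sample)
  expect_error(chi_square_accuracy(0, 0, 3, 5), "zero-margin")
})

test_that("spearman matrix equals the rank-Pearson oracle under ties", {
  x <- data.frame(up = 1:10, down = 10:1)
  sm <- spearman_matrix(x)
  expect_equal(sm$rho["up", "down"], -1)
  expect_equal(sm$rho["up", "up"], 1)

  set.seed(41)
  d <- data.frame(a = sample(1:4, 10, TRUE), b = sample(1:3, 10, TRUE),
                  c = rnorm(10))
  sm2 <- spearman_matrix(d)
  for (i in c("a", "b")) {
    for (j in c("b", "c")) {
      if (i == j) next
      want <- cor(rank(d[[i]]), rank(d[[j]]))
      expect_equal(sm2$rho[i, j], want)
    }
  }
  # missing handling: pairs with < 3 complete rows are NA
  d2 <- data.frame(a = c(1, 2, NA, NA, NA), b = c(2, 1, NA, NA, NA),
                   c = 1:5)
  sm3 <- spearman_matrix(d2)
  expect_true(is.na(sm3$rho["a", "b"]))
  expect_identical(sm3$n["a", "b"], 2L)
})

test_that("model_metrics assembles a coherent bundle", {
  scores <- c(0.9, 0.2, 0.8, 0.4, 0.6, 0.1)
  truth <- rep(c("noxious", "control"), 3)
  mm <- model_metrics(scores, truth, subjects = rep(1:3, each = 2),
                      n_boot = 100, seed = 2)
  expect_true(mm$accuracy >= 0 && mm$accuracy <= 1)
  expect_true(mm$accuracy_ci[["lower"]] <= mm$accuracy)
  expect_true(mm$accuracy_ci[["upper"]] >= mm$accuracy)
  expect_true(mm$auc_ci[["lower"]] <= mm$auc + 1e-9)
  expect_output(print(mm), "accuracy")
})
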