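test_that("gini impurity matches its closed form", {
  expect_equal(gini_impurity(c(5, 5)), 0.5)
  expect_equal(gini_impurity(c(10, 0)), 0)
  expect_equal(gini_impurity(c(3, 1)), 0.375)
  expect_error(gini_impurity(c(0, 0)), "at least 1")
})

test_that("best_split matches an exhaustive oracle on random tables", {
  set.seed(99)
  for (i in 1:150) {
    n <- sample(4:12, 1)
    x <- matrix(round(rnorm(n * 3), 2), n, 3,
                dimnames = list(NULL, c("a", "b", "c")))
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    got <- best_split(x, y)
    want <- oracle_best_split(x, y)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_identical(match(got$feature, colnames(x)), want$feature)
      expect_equal(got$threshold, want$threshold)
      expect_equal(got$decrease, want$decrease)
    }
  }
})

test_that("degenerate split inputs behave per contract", {
  x <- matrix(1, 6, 2, dimnames = list(NULL, c("a", "b")))
  expect_null(best_split(x, c(0, 1, 0, 1, 0, 1)))
  # perfectly separated single feature: children pure, decrease = parent gini
  x2 <- matrix(c(1, 2, 3, 10, 11, 12), ncol = 1,
               dimnames = list(NULL, "f"))
  got <- best_split(x2, c(0, 0, 0, 1, 1, 1))
  expect_equal(got$decrease, 0.5)
  expect_equal(got$threshold, 6.5)
})

test_that("subject bootstrap is a bootstrap of subjects", {
  set.seed(5)
  bag1 <- subject_bootstrap(letters[1:10])
  expect_length(bag1, 10)
  expect_true(all(bag1 %in% letters[1:10]))
  set.seed(5)
  expect_identical(subject_bootstrap(letters[1:10]), bag1)
  expect_identical({set.seed(1); subject_bootstrap("s1")}, "s1")

  # inclusion counts fit Binomial(S, 1/S) over many draws
  S <- 20
  counts <- integer(S + 1)
  set.seed(123)
  for (i in 1:10000) {
    k <- sum(subject_bootstrap(seq_len(S)) == 1L)
    counts[k + 1] <- counts[k + 1] + 1L
  }
  probs <- dbinom(0:S, S, 1 / S)
  keep <- probs * 10000 >= 5
  chi <- sum((counts[keep] - 10000 * probs[keep])^2 / (10000 * probs[keep])) +
    (sum(counts[!keep]) - 10000 * sum(probs[!keep]))^2 /
    (10000 * sum(probs[!keep]))
  p <- pchisq(chi, df = sum(keep), lower.tail = FALSE)
  expect_gt(p, 0.01)
})

test_that("every tree keeps paired observations jointly in or out of bag", {
  d <- separable_data(30)
  fit <- subject_rf(d$x, d$y, d$subjects, n_trees = 100, seed = 2)
  for (b in seq_along(fit$trees)) {
    bag <- fit$inbag_subjects[[b]]
    expect_length(bag, 30)
    # training rows of the tree = all observations of bagged subjects,
    # with multiplicity; support check:
    expect_true(all(bag %in% unique(as.character(d$subjects))))
  }
  # OOB eligibility is identical for the two observations of each subject
  oob <- fit$oob
  per_subj <- tapply(oob$n_eligible, oob$subject_id,
                     function(v) length(unique(v)))
  expect_true(all(per_subj == 1))
})

test_that("a separable cohort reaches high OOB accuracy; fits are deterministic", {
  d <- separable_data(60)
  fit <- subject_rf(d$x, d$y, d$subjects, n_trees = 300, seed = 11)
  acc <- mean(as.character(fit$oob$label) == as.character(d$y))
  expect_gte(acc, 0.95)
  fit2 <- subject_rf(d$x, d$y, d$subjects, n_trees = 300, seed = 11)
  expect_identical(fit$trees, fit2$trees)
  expect_identical(fit$inbag_subjects, fit2$inbag_subjects)
  expect_identical(fit$oob, fit2$oob)
})

test_that("label permutation sends OOB accuracy to chance", {
  d <- separable_data(60, seed = 21)
  set.seed(33)
  y_perm <- d$y
  flip <- as.logical(rbinom(60, 1, 0.5))
  for (s in which(flip)) {
    rows <- which(d$subjects == s)
    y_perm[rows] <- rev(y_perm[rows])
  }
  x_noise <- data.frame(a = rnorm(120), b = rnorm(120))
  fit <- subject_rf(x_noise, y_perm, d$subjects, n_trees = 300, seed = 10)
  acc <- mean(as.character(fit$oob$label) == as.character(y_perm))
  band <- qnorm(0.995) * sqrt(0.25 / 120)
  expect_lt(abs(acc - 0.5), band)
})

test_that("OOB votes error out when an observation has no eligible tree", {
  d <- separable_data(5, seed = 9)
  expect_error(subject_rf(d$x, d$y, d$subjects, n_trees = 1, seed = 1),
               "n_trees")
})

test_that("the eligible-tree fraction approaches exp(-1)", {
  d <- separable_data(50, seed = 14)
  fit <- subject_rf(d$x, d$y, d$subjects, n_trees = 400, seed = 3)
  frac <- mean(fit$oob$n_eligible) / 400
  expect_gt(frac, 0.33)
  expect_lt(frac, 0.41)
})

test_that("prediction handles pure regions, all-missing rows and empty input", {
  d <- separable_data(40, seed = 4)
  fit <- subject_rf(d$x, d$y, d$subjects, n_trees = 200, seed = 6)
  # deep inside the positive region every tree votes noxious
  newdata <- data.frame(sep = c(3, 0), noise = c(0, 0))
  sc <- predict(fit, newdata, type = "score")
  expect_equal(sc[1], 1)
  expect_equal(sc[2], 0)
  # all-missing row: every tree imputes its in-bag medians at the root,
  # reproducing the forest-wide prior vote; verify against a per-tree trace
  miss <- data.frame(sep = NA_real_, noise = NA_real_)
  got <- predict(fit, miss, type = "score")
  trace <- mean(vapply(seq_along(fit$trees), function(b) {
    as.numeric(painforest:::.cpp_predict_tree(
      fit$trees[[b]], matrix(fit$medians[b, ], nrow = 1), fit$medians[b, ]))
  }, numeric(1)))
  expect_equal(got, trace)
  # empty table
  empty <- predict(fit, d$x[0, ], type = "vote")
  expect_identical(nrow(empty), 0L)
  # unknown layout
  expect_error(predict(fit, data.frame(bogus = 1)), "lacks")
})

test_that("with one observation per subject the bootstrap is the classical one", {
  set.seed(88)
  subj <- as.character(1:25)
  draws <- replicate(4000, sort(table(factor(subject_bootstrap(subj),
                                             levels = subj))[1]))
  # per-subject inclusion count distribution matches Binomial(25, 1/25)
  expect_equal(mean(draws == 0), dbinom(0, 25, 1 / 25), tolerance = 0.05)
})

test_that("JSON serialization round-trips a forest exactly", {
  d <- separable_data(20, seed = 16)
  fit <- subject_rf(d$x, d$y, d$subjects, n_trees = 50, seed = 8)
  path <- withr::local_tempfile(fileext = ".json")
  write_subject_rf(fit, path)
  back <- read_subject_rf(path)
  expect_equal(back$trees, fit$trees)
  expect_identical(back$inbag_subjects, fit$inbag_subjects)
  expect_equal(back$medians, fit$medians)
  expect_identical(predict(back, d$x, type = "score"),
                   predict(fit, d$x, type = "score"))
})

test_that("OOB honesty: relabelling one subject leaves others' eligibility unchanged", {
  d <- separable_data(25, seed = 18)
  fit1 <- subject_rf(d$x, d$y, d$subjects, n_trees = 150, seed = 5)
  y2 <- d$y
  y2[d$subjects == 1] <- rev(y2[d$subjects == 1])
  fit2 <- subject_rf(d$x, y2, d$subjects, n_trees = 150, seed = 5)
  keep <- d$subjects != 1
  expect_identical(fit1$oob$n_eligible[keep], fit2$oob$n_eligible[keep])
  expect_identical(fit1$inbag_subjects, fit2$inbag_subjects)
})

test_that("missing-feature columns are tolerated per tree", {
  d <- separable_data(20, seed = 26)
  x <- d$x
  x$ghost <- NA_real_  # missing everywhere: unusable in every tree
  expect_message(fit <- subject_rf(x, d$y, d$subjects, n_trees = 60,
                                   seed = 2), "unusable")
  acc <- mean(as.character(fit$oob$label) == as.character(d$y))
  expect_gte(acc, 0.9)
})

test_that("OOB accuracy sits in the corridor of a reference implementation", {
  skip_if_not_installed("randomForest")
  set.seed(55)
  n <- 80
  x <- data.frame(f1 = rnorm(n) + rep(c(0, 1.6), n / 2),
                  f2 = rnorm(n) + rep(c(0, 0.8), n / 2),
                  f3 = rnorm(n))
  y <- factor(rep(c("control", "noxious"), n / 2), c("control", "noxious"))
  subj <- as.character(seq_len(n))  # one observation per subject
  ours <- subject_rf(x, y, subj, n_trees = 1000, mtry = 2, seed = 12)
  ours_acc <- mean(as.character(ours$oob$label) == as.character(y))
  rf <- randomForest::randomForest(x, y, ntree = 1000, mtry = 2)
  ref_acc <- mean(rf$predicted == y)
  expect_lt(abs(ours_acc - ref_acc), 0.05)
})

test_that("the formula interface matches the default interface", {
  d <- separable_data(20, seed = 31)
  df <- cbind(d$x, condition = d$y, subject_id = d$subjects)
  f1 <- subject_rf(condition ~ sep + noise, data = df,
                   subjects = "subject_id", n_trees = 50, seed = 3)
  f2 <- subject_rf(d$x, d$y, d$subjects, n_trees = 50, seed = 3)
  expect_equal(f1$trees, f2$trees)
  expect_equal(f1$oob$score, f2$oob$score)
})
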