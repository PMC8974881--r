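#' Gini impurity of a node
#'
#' `1 - sum(p_i^2)` over the class proportions implied by `class_counts`.
#'
#' @param class_counts Nonnegative counts per class, summing to at least 1.
#' @return Impurity in \[0, 1 - 1/k\].
#' @examples
#' gini_impurity(c(5, 5))   # 0.5
#' gini_impurity(c(10, 0))  # 0
#' @export
gini_impurity <- function(class_counts) {
  stopifnot(all(class_counts >= 0))
  n <- sum(class_counts)
  if (n < 1) stop("class counts must sum to at least 1")
  1 - sum((class_counts / n)^2)
}

#' Best Gini split of a feature table
#'
#' Exhaustive search over the supplied features: candidate thresholds are
#' midpoints between consecutive distinct observed values, and the split
#' maximising the weighted Gini impurity decrease wins. Ties are broken by
#' feature order, then by the lower threshold. Rows missing a feature are
#' assigned that feature's median over the supplied rows before evaluation
#' (the same imputation rule the forest applies per tree).
#'
#' @param x Numeric matrix or data frame of features.
#' @param y Binary labels (factor or 0/1); the second level / 1 is treated
#'   as the positive class.
#' @param features Columns to consider (names or indices); default all.
#' @return List `(feature, threshold, decrease)` or `NULL` when no split
#'   reduces impurity.
#' @export
best_split <- function(x, y, features = colnames(x)) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y01 <- as_binary_labels(y)
  if (is.character(features)) features <- match(features, colnames(x))
  stopifnot(!anyNA(features))
  for (j in features) {
    v <- x[, j]
    if (anyNA(v)) {
      x[is.na(v), j] <- median(v, na.rm = TRUE)
    }
  }
  res <- .cpp_best_split(x, y01, seq_len(nrow(x)) - 1L,
                         as.integer(features) - 1L)
  if (res$feature < 0) return(NULL)
  list(feature = colnames(x)[res$feature + 1L] %||% (res$feature + 1L),
       threshold = res$threshold, decrease = res$decrease)
}

as_binary_labels <- function(y) {
  if (is.factor(y)) {
    if (nlevels(y) != 2) stop("y must have exactly 2 classes")
    as.integer(y) - 1L
  } else {
    u <- sort(unique(y))
    if (length(u) > 2) stop("y must have exactly 2 classes")
    as.integer(y == u[length(u)])
  }
}

#' Subject-level bootstrap draw
#'
#' Draws S subjects with replacement from the S distinct subjects using the
#' current RNG state; a subject drawn k times contributes each of its
#' observations k times to a tree's training rows. This keeps the two paired
#' observations of a subject on the same side of every bag boundary.
#'
#' @param subject_ids Vector of distinct subject identifiers (duplicates are
#'   collapsed).
#' @return The in-bag multiset: a vector of length S of drawn subject ids.
#' @export
subject_bootstrap <- function(subject_ids) {
  u <- unique(subject_ids)
  u[sample.int(length(u), length(u), replace = TRUE)]
}

#' Subject-bootstrapped random forest for paired observations
#'
#' A random forest classifier re-implemented from scratch with three
#' departures from the textbook algorithm, all motivated by paired repeated
#' measures: (1) each tree's bootstrap resamples whole subjects, not
#' observations, so a subject's noxious and control observations are always
#' jointly in-bag or jointly out-of-bag; (2) out-of-bag predictions for an
#' observation use only trees whose bag excludes its subject, so the paired
#' observation can never leak into training; (3) missing values are handled
#' by per-tree median imputation computed from in-bag rows only, with the
#' medians stored for prediction. Trees are grown to purity (minimum leaf
#' size 1) with Gini splitting and per-node feature subsampling of size
#' `mtry`.
#'
#' @param x Feature matrix or data frame (numeric; `NA` allowed), or a
#'   formula.
#' @param ... Passed between methods.
#' @return Object of class `subject_rf` with components `trees`,
#'   `inbag_subjects` (per-tree multisets), `medians` (per-tree imputation
#'   values), `feature_names`, `levels`, `mtry`, `n_trees`, `seed`, the
#'   training data, and `oob` (a vote table, see [oob_votes()]).
#' @seealso [oob_votes()], [predict.subject_rf()], [write_subject_rf()]
#' @examples
#' set.seed(1)
#' n <- 40
#' df <- data.frame(f = rnorm(2 * n) + rep(c(0, 2), n))
#' y <- factor(rep(c("control", "noxious"), n), c("control", "noxious"))
#' subj <- rep(seq_len(n), each = 2)
#' fit <- subject_rf(df, y, subj, n_trees = 100, seed = 7)
#' summary(fit)
#' @export
subject_rf <- function(x, ...) UseMethod("subject_rf")

#' @rdname subject_rf
#' @param formula Model formula such as `condition ~ .`.
#' @param data Data frame holding the formula's variables.
#' @param subjects Subject identifier per observation (or, for the formula
#'   method, the name of the identifier column in `data`, which is then
#'   excluded from the predictors).
#' @export
subject_rf.formula <- function(formula, data, subjects, ...) {
  if (is.character(subjects) && length(subjects) == 1L &&
      subjects %in% names(data)) {
    subj <- data[[subjects]]
    data <- data[setdiff(names(data), subjects)]
  } else {
    subj <- subjects
  }
  mf <- model.frame(formula, data, na.action = na.pass)
  y <- model.response(mf)
  x <- mf[-1L]
  fit <- subject_rf.default(x, y, subj, ...)
  fit$call <- match.call()
  fit
}

#' @rdname subject_rf
#' @param y Binary condition labels; a factor whose second level (or the
#'   level `"noxious"` when present) is the positive class.
#' @param n_trees Number of trees (default 1000).
#' @param mtry Features sampled per node; default `ceiling(sqrt(p))`.
#' @param seed Integer seed; fitting is deterministic given it.
#' @param compute_oob Compute out-of-bag votes at fit time (default TRUE).
#' @export
subject_rf.default <- function(x, y, subjects, n_trees = 1000L, mtry = NULL,
                               seed = 1L, compute_oob = TRUE, ...) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  y <- as_condition_factor(y)
  stopifnot(nrow(x) == length(y), nrow(x) == length(subjects))
  if (nlevels(droplevels(y)) < 2) stop("need both classes in y")
  subjects <- as.character(subjects)
  usubj <- unique(subjects)
  if (length(usubj) < 2) stop("need at least 2 distinct subjects")
  p <- ncol(x)
  if (is.null(mtry)) mtry <- ceiling(sqrt(p))
  mtry <- max(1L, min(as.integer(mtry), p))
  n_trees <- as.integer(n_trees)

  y01 <- as.integer(y) - 1L
  rows_of <- split(seq_len(nrow(x)), factor(subjects, levels = usubj))

  fit <- with_preserved_rng({
    set.seed(as.integer(seed))
    tree_seeds <- sample.int(2147483646L, n_trees)
    trees <- vector("list", n_trees)
    inbag <- vector("list", n_trees)
    medians <- matrix(NA_real_, n_trees, p,
                      dimnames = list(NULL, colnames(x)))
    unusable_logged <- FALSE
    for (b in seq_len(n_trees)) {
      bag <- subject_bootstrap(usubj)
      rows <- unlist(rows_of[bag], use.names = FALSE)
      med <- apply(x[rows, , drop = FALSE], 2, median, na.rm = TRUE)
      usable <- which(!is.na(med))
      if (length(usable) < p && !unusable_logged) {
        message(sprintf(
          "tree %d: %d feature(s) missing for all in-bag rows; unusable in affected trees",
          b, p - length(usable)))
        unusable_logged <- TRUE
      }
      xi <- x
      for (j in usable) {
        nai <- is.na(xi[, j])
        if (any(nai)) xi[nai, j] <- med[j]
      }
      trees[[b]] <- .cpp_grow_tree(xi, y01, rows - 1L, usable - 1L,
                                   mtry, tree_seeds[b])
      inbag[[b]] <- bag
      medians[b, ] <- med
    }
    list(trees = trees, inbag = inbag, medians = medians)
  })

  obj <- structure(list(
    trees = fit$trees,
    inbag_subjects = fit$inbag,
    medians = fit$medians,
    feature_names = colnames(x),
    levels = levels(y),
    mtry = mtry,
    n_trees = n_trees,
    seed = as.integer(seed),
    x = x, y = y, subjects = subjects,
    call = match.call()
  ), class = "subject_rf")

  if (compute_oob) obj$oob <- oob_votes(obj)
  obj
}

as_condition_factor <- function(y) {
  if (!is.factor(y)) y <- factor(y)
  if (nlevels(y) != 2) stop("y must have exactly 2 classes")
  if ("noxious" %in% levels(y) && levels(y)[2] != "noxious") {
    y <- factor(y, levels = c(setdiff(levels(y), "noxious"), "noxious"))
  }
  y
}

#' Out-of-bag votes of a subject-bootstrapped forest
#'
#' For every training observation, aggregates the votes of the trees whose
#' in-bag subject multiset excludes that observation's subject. The score is
#' the fraction of eligible trees voting for the positive (noxious) class;
#' the label is positive iff score > 0.5, with exact ties labelled control
#' and flagged. Both paired observations of a subject have identical
#' eligible-tree sets by construction.
#'
#' @param forest A `subject_rf`.
#' @param x Feature table of the training observations (defaults to the one
#'   stored at fit time).
#' @param subjects Matching subject ids.
#' @return Data frame: `subject_id`, `truth`, `score`, `n_eligible`,
#'   `label`, `tie`.
#' @export
oob_votes <- function(forest, x = forest$x, subjects = forest$subjects) {
  stopifnot(inherits(forest, "subject_rf"))
  x <- as.matrix(x)[, forest$feature_names, drop = FALSE]
  storage.mode(x) <- "double"
  subjects <- as.character(subjects)
  n <- nrow(x)
  votes <- numeric(n)
  elig <- integer(n)
  for (b in seq_along(forest$trees)) {
    out_rows <- which(!(subjects %in% forest$inbag_subjects[[b]]))
    if (!length(out_rows)) next
    pred <- .cpp_predict_tree(forest$trees[[b]],
                              x[out_rows, , drop = FALSE],
                              forest$medians[b, ])
    votes[out_rows] <- votes[out_rows] + pred
    elig[out_rows] <- elig[out_rows] + 1L
  }
  if (any(elig == 0L)) {
    stop(sprintf(
      "%d observation(s) have no out-of-bag trees; increase n_trees",
      sum(elig == 0L)))
  }
  score <- votes / elig
  truth <- if (identical(subjects, forest$subjects)) forest$y else NULL
  data.frame(subject_id = subjects,
             truth = truth %||% NA,
             score = score,
             n_eligible = elig,
             label = factor(ifelse(score > 0.5, forest$levels[2],
                                   forest$levels[1]), forest$levels),
             tie = score == 0.5)
}

#' Predict with a subject-bootstrapped forest
#'
#' All trees vote on new observations; missing features are imputed per tree
#' with the stored in-bag medians. Unknown feature names are rejected.
#'
#' @param object A `subject_rf`.
#' @param newdata Data frame or matrix with the training features.
#' @param type `"score"` (positive-vote fraction), `"class"`, or `"vote"`
#'   (full table as in [oob_votes()]).
#' @param ... Unused.
#' @return Numeric scores, factor labels, or a data frame, per `type`.
#' @export
predict.subject_rf <- function(object, newdata,
                               type = c("score", "class", "vote"), ...) {
  type <- match.arg(type)
  newdata <- as.data.frame(newdata)
  missing_cols <- setdiff(object$feature_names, colnames(newdata))
  if (length(missing_cols)) {
    stop("newdata lacks the model feature(s): ",
         paste(missing_cols, collapse = ", "))
  }
  x <- as.matrix(newdata[object$feature_names])
  storage.mode(x) <- "double"
  n <- nrow(x)
  if (n == 0L) {
    return(switch(type,
                  score = numeric(0),
                  class = factor(character(0), object$levels),
                  vote = data.frame(score = numeric(0), n_eligible = integer(0),
                                    label = factor(character(0), object$levels),
                                    tie = logical(0))))
  }
  votes <- numeric(n)
  for (b in seq_along(object$trees)) {
    votes <- votes + .cpp_predict_tree(object$trees[[b]], x,
                                       object$medians[b, ])
  }
  score <- votes / length(object$trees)
  label <- factor(ifelse(score > 0.5, object$levels[2], object$levels[1]),
                  object$levels)
  switch(type,
         score = score,
         class = label,
         vote = data.frame(score = score,
                           n_eligible = length(object$trees),
                           label = label, tie = score == 0.5))
}
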