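# Discrimination metrics: confusion summaries with Wilson intervals,
# ROC/AUC, and subject-level bootstrap confidence intervals for the AUC.

#' Accuracy, sensitivity and specificity of predicted labels
#'
#' Sensitivity is the fraction of positive-class (noxious) observations
#' predicted positive; specificity the fraction of control observations
#' predicted control. A metric whose denominator class is absent from the
#' truth is `NA` and flagged, never silently 0.
#'
#' @param predicted,truth Equal-length label vectors.
#' @param positive Positive-class label (default `"noxious"`).
#' @return List: `accuracy`, `sensitivity`, `specificity`, counts `tp`,
#'   `fn`, `tn`, `fp`, `n`, and `undefined` (names of undefined metrics).
#' @export
confusion_metrics <- function(predicted, truth, positive = "noxious") {
  predicted <- as.character(predicted)
  truth <- as.character(truth)
  if (length(predicted) != length(truth)) stop("length mismatch")
  if (length(truth) == 0) stop("empty input")
  pos <- truth == positive
  tp <- sum(pos & predicted == positive)
  fn <- sum(pos & predicted != positive)
  tn <- sum(!pos & predicted != positive)
  fp <- sum(!pos & predicted == positive)
  undefined <- character(0)
  sens <- if (any(pos)) tp / sum(pos) else {
    undefined <- c(undefined, "sensitivity"); NA_real_
  }
  spec <- if (any(!pos)) tn / sum(!pos) else {
    undefined <- c(undefined, "specificity"); NA_real_
  }
  list(accuracy = (tp + tn) / length(truth),
       sensitivity = sens, specificity = spec,
       tp = tp, fn = fn, tn = tn, fp = fp, n = length(truth),
       undefined = undefined)
}

#' Wilson score interval for a binomial proportion
#'
#' The score-test inversion interval, without continuity correction.
#'
#' @param k Successes, `0 <= k <= n`.
#' @param n Trials, `n >= 1`.
#' @param alpha Two-sided error rate (default 0.05 for a 95% interval).
#' @return Named numeric `(lower, upper)`.
#' @examples
#' wilson_interval(52, 64)  # c(0.700, 0.889) to 3 dp
#' @export
wilson_interval <- function(k, n, alpha = 0.05) {
  if (!(n >= 1) || k < 0 || k > n) stop("need 0 <= k <= n, n >= 1")
  z <- qnorm(1 - alpha / 2)
  phat <- k / n
  denom <- 1 + z^2 / n
  centre <- (phat + z^2 / (2 * n)) / denom
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

#' ROC curve and AUC
#'
#' The curve enumerates every distinct score as a threshold (predict
#' positive when score >= threshold), plus the trivial endpoints (0,0) and
#' (1,1); both coordinates are nondecreasing along it. The AUC is the
#' trapezoidal area, identical to the Mann-Whitney probability with ties
#' counted one half.
#'
#' @param scores Real-valued classifier scores (higher = more positive).
#' @param truth Binary labels; both classes must be present.
#' @param positive Positive-class label.
#' @return List: `curve` (data frame `threshold`, `fpr`, `tpr`) and `auc`.
#' @export
roc_and_auc <- function(scores, truth, positive = "noxious") {
  truth <- as.character(truth)
  stopifnot(length(scores) == length(truth))
  pos <- truth == positive
  if (!any(pos) || all(pos)) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  p <- pos[ord]
  # collapse tied scores: one threshold per distinct value
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(p)[last_of_tie]
  fp <- cumsum(!p)[last_of_tie]
  curve <- data.frame(threshold = c(Inf, s[last_of_tie]),
                      fpr = c(0, fp / sum(!pos)),
                      tpr = c(0, tp / sum(pos)))
  if (curve$fpr[nrow(curve)] < 1 || curve$tpr[nrow(curve)] < 1) {
    curve <- rbind(curve, data.frame(threshold = -Inf, fpr = 1, tpr = 1))
  }
  auc <- sum(diff(curve$fpr) * (head(curve$tpr, -1) + curve$tpr[-1]) / 2)
  list(curve = curve, auc = auc)
}

# rank-based AUC, identical to the trapezoid value; used where speed matters
auc_fast <- function(scores, pos) {
  r <- rank(scores)
  np <- sum(pos)
  nn <- length(pos) - np
  (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
}

#' Subject-level bootstrap confidence interval for the AUC
#'
#' Percentile bootstrap in which the resampling unit is the subject: a
#' subject's observations move together, respecting the paired design.
#' Resamples in which one class disappears are redrawn (the count is
#' reported); the procedure aborts if degenerate resamples persist past
#' `10 * n_boot` attempts.
#'
#' @param scores,truth As in [roc_and_auc()].
#' @param subject_ids Subject identifier per observation.
#' @param n_boot Bootstrap replicates (default 2000).
#' @param alpha Two-sided error rate.
#' @param seed Integer seed; results are deterministic given it.
#' @param positive Positive-class label.
#' @return Named numeric `(lower, upper)` with attribute `n_redrawn`.
#' @export
bootstrap_auc_ci <- function(scores, truth, subject_ids, n_boot = 2000L,
                             alpha = 0.05, seed = 1L, positive = "noxious") {
  truth <- as.character(truth)
  pos <- truth == positive
  subject_ids <- as.character(subject_ids)
  usubj <- unique(subject_ids)
  rows_of <- split(seq_along(scores), factor(subject_ids, levels = usubj))
  S <- length(usubj)
  with_preserved_rng({
    set.seed(as.integer(seed))
    aucs <- numeric(n_boot)
    redrawn <- 0L
    attempts <- 0L
    b <- 1L
    while (b <= n_boot) {
      attempts <- attempts + 1L
      if (attempts > 10L * n_boot) {
        stop("bootstrap degenerate: one class keeps disappearing from resamples")
      }
      take <- unlist(rows_of[sample.int(S, S, replace = TRUE)],
                     use.names = FALSE)
      pb <- pos[take]
      if (!any(pb) || all(pb)) {
        redrawn <- redrawn + 1L
        next
      }
      aucs[b] <- auc_fast(scores[take], pb)
      b <- b + 1L
    }
    ci <- quantile(aucs, c(alpha / 2, 1 - alpha / 2), names = FALSE)
    structure(c(lower = ci[1], upper = ci[2]), n_redrawn = redrawn)
  })
}

#' Full metric bundle for one classifier
#'
#' Point estimates with Wilson intervals for accuracy, sensitivity and
#' specificity (labels from thresholding the score at 0.5, ties to
#' control), the ROC curve, and the AUC with a subject-level bootstrap
#' percentile interval.
#'
#' @param scores Classifier scores in \[0, 1\].
#' @param truth Binary labels.
#' @param subjects Subject ids (needed for the AUC interval; when `NULL`
#'   each observation is its own subject).
#' @param threshold Label threshold (default 0.5).
#' @param alpha Two-sided error rate.
#' @param n_boot Bootstrap replicates for the AUC interval; 0 skips it.
#' @param seed Seed for the bootstrap.
#' @param positive Positive-class label.
#' @return Object of class `model_metrics`.
#' @export
model_metrics <- function(scores, truth, subjects = NULL, threshold = 0.5,
                          alpha = 0.05, n_boot = 2000L, seed = 1L,
                          positive = "noxious") {
  truth <- as.character(truth)
  neg_label <- setdiff(unique(truth), positive)
  neg_label <- if (length(neg_label)) neg_label[1] else "control"
  predicted <- ifelse(scores > threshold, positive, neg_label)
  cm <- confusion_metrics(predicted, truth, positive)
  roc <- roc_and_auc(scores, truth, positive)
  if (is.null(subjects)) subjects <- seq_along(scores)
  auc_ci <- if (n_boot > 0) {
    bootstrap_auc_ci(scores, truth, subjects, n_boot = n_boot,
                     alpha = alpha, seed = seed, positive = positive)
  } else c(lower = NA_real_, upper = NA_real_)
  structure(list(
    accuracy = cm$accuracy,
    accuracy_ci = wilson_interval(cm$tp + cm$tn, cm$n, alpha),
    sensitivity = cm$sensitivity,
    sensitivity_ci = if (is.na(cm$sensitivity)) c(lower = NA, upper = NA)
      else wilson_interval(cm$tp, cm$tp + cm$fn, alpha),
    specificity = cm$specificity,
    specificity_ci = if (is.na(cm$specificity)) c(lower = NA, upper = NA)
      else wilson_interval(cm$tn, cm$tn + cm$fp, alpha),
    auc = roc$auc, auc_ci = auc_ci, roc = roc$curve,
    n_observations = cm$n, counts = cm[c("tp", "fn", "tn", "fp")],
    undefined = cm$undefined, alpha = alpha
  ), class = "model_metrics")
}

#' @export
print.model_metrics <- function(x, ...) {
  fmt <- function(p, ci) {
    if (is.na(p)) return("undefined")
    if (anyNA(ci)) return(sprintf("%.3f", p))
    sprintf("%.3f (%.3f-%.3f)", p, ci[1], ci[2])
  }
  cat(sprintf("  accuracy    %s\n", fmt(x$accuracy, x$accuracy_ci)))
  cat(sprintf("  sensitivity %s\n", fmt(x$sensitivity, x$sensitivity_ci)))
  cat(sprintf("  specificity %s\n", fmt(x$specificity, x$specificity_ci)))
  cat(sprintf("  AUC         %s   (n = %d)\n",
              fmt(x$auc, x$auc_ci), x$n_observations))
  invisible(x)
}
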