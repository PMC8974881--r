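# print/summary/plot and JSON serialization for subject_rf objects.

#' @export
print.subject_rf <- function(x, ...) {
  cat("Subject-bootstrapped random forest\n")
  cat(sprintf("  %d trees, mtry %d, %d features, %d observations of %d subjects\n",
              x$n_trees, x$mtry, length(x$feature_names), nrow(x$x),
              length(unique(x$subjects))))
  if (!is.null(x$oob)) {
    acc <- mean(as.character(x$oob$label) == as.character(x$oob$truth))
    cat(sprintf("  OOB accuracy: %.3f (mean eligible-tree fraction %.3f)\n",
                acc, mean(x$oob$n_eligible) / x$n_trees))
  }
  invisible(x)
}

#' Summarise out-of-bag performance of a subject forest
#'
#' @param object A `subject_rf` fitted with `compute_oob = TRUE`.
#' @param alpha Confidence level complement for Wilson intervals.
#' @param ... Unused.
#' @return Object of class `summary.subject_rf`: the OOB [model_metrics()]
#'   plus the forest dimensions.
#' @export
summary.subject_rf <- function(object, alpha = 0.05, ...) {
  if (is.null(object$oob)) stop("forest was fitted without OOB votes")
  mm <- model_metrics(object$oob$score, object$oob$truth,
                      subjects = object$oob$subject_id, alpha = alpha,
                      positive = object$levels[2], n_boot = 0)
  structure(list(metrics = mm, n_trees = object$n_trees, mtry = object$mtry,
                 n_subjects = length(unique(object$subjects)),
                 n_obs = nrow(object$x)),
            class = "summary.subject_rf")
}

#' @export
print.summary.subject_rf <- function(x, ...) {
  cat(sprintf("Subject forest: %d trees, mtry %d, %d subjects / %d observations\n",
              x$n_trees, x$mtry, x$n_subjects, x$n_obs))
  print(x$metrics)
  invisible(x)
}

#' Plot the out-of-bag ROC curve of a subject forest
#'
#' @param x A `subject_rf`.
#' @param ... Passed to [plot()].
#' @return The ROC curve data frame, invisibly.
#' @export
plot.subject_rf <- function(x, ...) {
  if (is.null(x$oob)) stop("forest was fitted without OOB votes")
  roc <- roc_and_auc(x$oob$score, x$oob$truth, positive = x$levels[2])
  plot(roc$curve$fpr, roc$curve$tpr, type = "l",
       xlab = "False-positive rate", ylab = "True-positive rate",
       main = sprintf("OOB ROC (AUC = %.3f)", roc$auc), ...)
  abline(0, 1, lty = 3)
  invisible(roc$curve)
}

#' Serialize a subject forest to JSON and back
#'
#' Writes trees, per-tree in-bag subject multisets, per-tree imputation
#' medians and the fit configuration to a single JSON file; the round trip
#' reproduces an operationally identical forest (structural equality of
#' every tree, identical predictions). Training data and OOB votes travel
#' with the file so the object is self-contained.
#'
#' @param forest A `subject_rf`.
#' @param path JSON file path.
#' @return `write_subject_rf()`: `path`, invisibly. `read_subject_rf()`:
#'   the restored `subject_rf`.
#' @export
write_subject_rf <- function(forest, path) {
  stopifnot(inherits(forest, "subject_rf"))
  payload <- list(
    format = "painforest-subject-rf-v1",
    n_trees = forest$n_trees, mtry = forest$mtry, seed = forest$seed,
    levels = forest$levels, feature_names = forest$feature_names,
    trees = forest$trees,
    inbag_subjects = forest$inbag_subjects,
    medians = forest$medians,
    x = forest$x, y = as.character(forest$y), subjects = forest$subjects)
  writeLines(jsonlite::toJSON(payload, digits = I(17), auto_unbox = FALSE,
                              na = "null"),
             path)
  invisible(path)
}

#' @rdname write_subject_rf
#' @export
read_subject_rf <- function(path) {
  p <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                          simplifyDataFrame = FALSE,
                          simplifyMatrix = FALSE)
  if (!identical(p$format, "painforest-subject-rf-v1")) {
    stop("unrecognised model format in ", path)
  }
  p$feature_names <- as.character(p$feature_names)
  x <- do.call(rbind, lapply(p$x, as.numeric))
  colnames(x) <- p$feature_names
  medians <- do.call(rbind, lapply(p$medians, as.numeric))
  colnames(medians) <- p$feature_names
  trees <- lapply(p$trees, function(tr) {
    list(feature = as.integer(tr$feature), threshold = as.numeric(tr$threshold),
         left = as.integer(tr$left), right = as.integer(tr$right),
         n0 = as.numeric(tr$n0), n1 = as.numeric(tr$n1))
  })
  obj <- structure(list(
    trees = trees,
    inbag_subjects = lapply(p$inbag_subjects, as.character),
    medians = medians,
    feature_names = p$feature_names,
    levels = p$levels,
    mtry = as.integer(p$mtry),
    n_trees = as.integer(p$n_trees),
    seed = as.integer(p$seed),
    x = x, y = factor(p$y, p$levels), subjects = as.character(p$subjects),
    call = quote(read_subject_rf(path))
  ), class = "subject_rf")
  obj$oob <- oob_votes(obj)
  obj
}
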