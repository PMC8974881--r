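# End-to-end experiment drivers: within-modality measure comparison and the
# multimodal train/validate experiment.

#' Configuration of a full discrimination experiment
#'
#' @param cohort A [cohort_config()] (the cohort is simulated) or a
#'   directory path holding a written cohort (loaded with [read_cohort()]).
#' @param n_test Number of held-out test subjects. Test subjects are chosen
#'   among those with every modality available in both conditions (the
#'   held-out set must be artifact-complete so all models are comparable on
#'   it); remaining subjects form the training set.
#' @param min_modalities_train Multimodal training keeps subjects with at
#'   least this many modalities available (counted per subject as
#'   modalities present in all of the subject's observations).
#' @param full_measures Measure set of the full multimodal model: the best
#'   single measure per modality (facial nasolabial furrow, heart-rate
#'   maximum change over 15 s, saturation minimum change over 30 s, EEG
#'   template magnitude, and both legs' reflex RMS).
#' @param subset_measures The behavioural + physiological comparison subset.
#' @param n_trees,mtry Forest hyperparameters (see [subject_rf()]).
#' @param n_boot Bootstrap replicates for AUC intervals.
#' @param alpha Two-sided error rate for all intervals.
#' @param seed Experiment seed (controls the forest fits and bootstrap
#'   draws; the cohort keeps its own seed).
#' @return A validated list of class `experiment_config`.
#' @export
experiment_config <- function(cohort = cohort_config(n_subjects = 109L),
                              n_test = 32L,
                              min_modalities_train = 3L,
                              full_measures = c("NF", "hr_max_15",
                                                "sat_min_30", "EEGt",
                                                "RMSi", "RMSc"),
                              subset_measures = c("NF", "hr_max_15",
                                                  "sat_min_30"),
                              n_trees = 1000L, mtry = NULL,
                              n_boot = 2000L, alpha = 0.05, seed = 1L) {
  stopifnot(inherits(cohort, "cohort_config") ||
              (is.character(cohort) && length(cohort) == 1L))
  stopifnot(n_test >= 1L, n_trees >= 1L, n_boot >= 0L,
            alpha > 0, alpha < 1)
  bad <- setdiff(c(full_measures, subset_measures), feature_names())
  if (length(bad)) stop("unknown measure(s): ", paste(bad, collapse = ", "))
  structure(list(cohort = cohort, n_test = as.integer(n_test),
                 min_modalities_train = as.integer(min_modalities_train),
                 full_measures = full_measures,
                 subset_measures = subset_measures,
                 n_trees = as.integer(n_trees), mtry = mtry,
                 n_boot = as.integer(n_boot), alpha = alpha,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

load_cohort <- function(config) {
  if (inherits(config$cohort, "cohort_config")) {
    simulate_cohort(config$cohort)
  } else {
    read_cohort(config$cohort)
  }
}

# Split subjects into a complete test set and the training remainder.
# Test subjects must have every modality in both observations -- and, when
# `feature_complete`, every extracted measure defined (an EMG reflex whose
# endpoint the detector cannot identify counts as an artifact, exactly like
# a rejected recording). Candidates are taken in subject order, mirroring
# an observational assignment.
split_cohort <- function(cohort, n_test, feature_complete = FALSE) {
  man <- cohort$manifest
  complete_obs <- rowSums(!man[MODALITIES]) == 0
  by_subj <- tapply(complete_obs, man$subject_id, all)
  complete_subjects <- sort(as.integer(names(by_subj))[by_subj])
  if (feature_complete && length(complete_subjects) >= 1) {
    keep <- vapply(cohort$recordings, function(r)
      r$subject_id %in% complete_subjects, logical(1))
    cand <- structure(list(config = cohort$config,
                           recordings = cohort$recordings[keep],
                           manifest = man[man$subject_id %in%
                                            complete_subjects, ,
                                          drop = FALSE]),
                      class = "pain_cohort")
    # the reference only affects EEGa values, never their missingness, so a
    # provisional whole-cohort reference is fine for this screen
    feats <- extract_features(cand,
                              eega_reference = cohort_average_epoch(cohort))
    row_ok <- rowSums(is.na(feats[feature_names()])) == 0
    subj_ok <- tapply(row_ok, feats$subject_id, all)
    complete_subjects <- sort(as.integer(names(subj_ok))[subj_ok])
  }
  if (length(complete_subjects) < n_test) {
    stop(sprintf(
      "only %d subjects have artifact-free data in every modality and both conditions; cannot form a test set of %d",
      length(complete_subjects), n_test))
  }
  test_subjects <- complete_subjects[seq_len(n_test)]
  train_subjects <- setdiff(unique(man$subject_id), test_subjects)
  pick <- function(ids) {
    keep <- vapply(cohort$recordings,
                   function(r) r$subject_id %in% ids, logical(1))
    structure(list(config = cohort$config,
                   recordings = cohort$recordings[keep],
                   manifest = man[man$subject_id %in% ids, , drop = FALSE]),
              class = "pain_cohort")
  }
  list(train = pick(train_subjects), test = pick(test_subjects),
       train_subjects = train_subjects, test_subjects = test_subjects)
}

# fit one measure-set model and evaluate OOB
fit_measure_model <- function(features, measures, n_trees, mtry, seed,
                              alpha, n_boot) {
  rows <- which(rowSums(!is.na(features[, measures, drop = FALSE])) > 0)
  dat <- features[rows, , drop = FALSE]
  fit <- subject_rf(dat[measures], factor(dat$condition,
                                          c("control", "noxious")),
                    dat$subject_id, n_trees = n_trees, mtry = mtry,
                    seed = seed)
  oob <- fit$oob
  metrics <- model_metrics(oob$score, oob$truth, subjects = oob$subject_id,
                           alpha = alpha, n_boot = n_boot, seed = seed)
  list(fit = fit, rows = rows, oob = oob, metrics = metrics)
}

metrics_row <- function(name, m, n_obs = m$n_observations) {
  data.frame(model = name, n = n_obs,
             accuracy = m$accuracy,
             acc_lower = m$accuracy_ci[["lower"]],
             acc_upper = m$accuracy_ci[["upper"]],
             sensitivity = m$sensitivity,
             specificity = m$specificity,
             auc = m$auc,
             auc_lower = m$auc_ci[["lower"]],
             auc_upper = m$auc_ci[["upper"]],
             row.names = NULL)
}

#' Within-modality measure comparison
#'
#' For each modality, fits a subject forest per single measure plus (for
#' facial and EMG) the combined-measure model: facial `BB`/`ES`/`NF` and all
#' three; each EMG leg's RMS/duration/amplitude and all three; all 24
#' heart-rate and all 24 saturation measures; the two automated EEG
#' magnitudes. Every model is scored out-of-bag (accuracy/sensitivity/
#' specificity with Wilson intervals, AUC with a subject-bootstrap interval)
#' and compared with the modality's reference model (the combined model
#' where one exists, otherwise the best single measure by accuracy then
#' AUC) via the mid-P McNemar test on common observations and DeLong's test
#' on the paired OOB scores. A modality absent from the whole cohort is
#' skipped with a warning.
#'
#' @param config An [experiment_config()]. Only the training split is used.
#' @return Object of class `within_modality_result`: per-modality ranked
#'   tables, the selected best measure per modality, the features and the
#'   config.
#' @export
run_within_modality <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  cohort <- load_cohort(config)
  train <- tryCatch(split_cohort(cohort, config$n_test)$train,
                    error = function(e) {
                      warning("no complete held-out set is available (",
                              conditionMessage(e),
                              "); using the whole cohort for training")
                      cohort
                    })
  features <- extract_features(train)

  families <- list(
    facial = list(single = c("BB", "ES", "NF"),
                  combined = list(facial_all = c("BB", "ES", "NF"))),
    emg_ipsi = list(single = c("RMSi", "DURi", "AMPi"),
                    combined = list(emg_ipsi_all = c("RMSi", "DURi", "AMPi"))),
    emg_contra = list(single = c("RMSc", "DURc", "AMPc"),
                      combined = list(emg_contra_all = c("RMSc", "DURc",
                                                         "AMPc"))),
    hr = list(single = grep("^hr_", feature_names(), value = TRUE),
              combined = list()),
    spo2 = list(single = grep("^sat_", feature_names(), value = TRUE),
                combined = list()),
    eeg = list(single = c("EEGt", "EEGa"), combined = list())
  )

  tables <- list()
  best <- character(0)
  for (fam in names(families)) {
    spec <- families[[fam]]
    present <- vapply(spec$single, function(m) any(!is.na(features[[m]])),
                      logical(1))
    if (!any(present)) {
      warning(sprintf("modality %s absent from the entire cohort; skipped",
                      fam))
      next
    }
    model_sets <- c(as.list(setNames(spec$single, spec$single)),
                    spec$combined)
    fits <- lapply(seq_along(model_sets), function(i) {
      fit_measure_model(features, model_sets[[i]], config$n_trees,
                        config$mtry, config$seed + i, config$alpha,
                        config$n_boot)
    })
    names(fits) <- names(model_sets)

    # reference: the combined model if the family has one, else best single
    tab <- do.call(rbind, lapply(names(fits), function(nm) {
      metrics_row(nm, fits[[nm]]$metrics)
    }))
    if (length(spec$combined)) {
      ref <- names(spec$combined)[1]
    } else {
      ord <- order(-tab$accuracy, -tab$auc)
      ref <- tab$model[ord[1]]
    }
    cmp <- compare_to_reference(fits, ref)
    tab <- merge(tab, cmp, by = "model", sort = FALSE)
    tab <- tab[order(-tab$accuracy, -tab$auc), , drop = FALSE]
    rownames(tab) <- NULL
    attr(tab, "reference_model") <- ref
    tables[[fam]] <- tab

    singles <- tab[tab$model %in% spec$single, , drop = FALSE]
    best[fam] <- singles$model[order(-singles$accuracy, -singles$auc)][1]
  }

  structure(list(tables = tables, best = best, features = features,
                 config = config),
            class = "within_modality_result")
}

# mid-P McNemar and DeLong of every model against the reference model,
# evaluated on the observations common to both fits
compare_to_reference <- function(fits, ref) {
  ref_fit <- fits[[ref]]
  do.call(rbind, lapply(names(fits), function(nm) {
    if (nm == ref) {
      return(data.frame(model = nm, p_mcnemar_vs_ref = NA_real_,
                        p_delong_vs_ref = NA_real_))
    }
    f <- fits[[nm]]
    common <- intersect(f$rows, ref_fit$rows)
    ia <- match(common, f$rows)
    ib <- match(common, ref_fit$rows)
    truth <- as.character(f$oob$truth[ia])
    ca <- as.character(f$oob$label[ia]) == truth
    cb <- as.character(ref_fit$oob$label[ib]) == truth
    pm <- mcnemar_midp(ca, cb)
    pd <- tryCatch(
      delong_paired_test(f$oob$score[ia], ref_fit$oob$score[ib], truth)$p,
      error = function(e) NA_real_)
    data.frame(model = nm, p_mcnemar_vs_ref = pm, p_delong_vs_ref = pd)
  }))
}

#' Multimodal train/validate experiment
#'
#' Trains the full multimodal forest (best measure per modality) on the
#' training subjects with at least `min_modalities_train` modalities,
#' reports its out-of-bag metrics overall and stratified by gestational age
#' (term >= 37 weeks vs preterm < 37 weeks, compared with a Yates-corrected
#' chi-square), then validates on the held-out complete test set: the full
#' model, each single-measure model and the behavioural + physiological
#' subset are scored on the test observations, each compared against the
#' full model with the mid-P McNemar test and DeLong's test. The Spearman
#' correlation matrix of the headline measures on the training set is also
#' returned. Test subjects missing any modality are rejected at validation.
#'
#' @param config An [experiment_config()].
#' @return Object of class `multimodal_result`: `train_metrics`, `strata`
#'   (term/preterm table and chi-square), `test_table`, `spearman`, the
#'   fitted `models`, the feature tables and the config.
#' @export
run_multimodal <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  cohort <- load_cohort(config)
  split <- split_cohort(cohort, config$n_test, feature_complete = TRUE)
  train_feat <- extract_features(split$train)
  test_feat <- extract_features(
    split$test, eega_reference = attr(train_feat, "eega_reference"))
  if (anyNA(test_feat[feature_names()])) {
    bad <- unique(test_feat$subject_id[rowSums(
      is.na(test_feat[feature_names()])) > 0])
    stop("test subjects with missing modality data: ",
         paste(bad, collapse = ", "))
  }

  # multimodal training rule: subjects with >= 3 modalities in all their
  # observations
  man <- split$train$manifest
  n_mod <- tapply(rowSums(man[MODALITIES]), man$subject_id, min)
  keep_subjects <- as.integer(names(n_mod))[n_mod >= config$min_modalities_train]
  tf <- train_feat[train_feat$subject_id %in% keep_subjects, , drop = FALSE]

  full <- subject_rf(tf[config$full_measures],
                     factor(tf$condition, c("control", "noxious")),
                     tf$subject_id, n_trees = config$n_trees,
                     mtry = config$mtry, seed = config$seed)
  train_metrics <- model_metrics(full$oob$score, full$oob$truth,
                                 subjects = full$oob$subject_id,
                                 alpha = config$alpha,
                                 n_boot = config$n_boot, seed = config$seed)

  # term/preterm stratification of the OOB predictions
  ga <- tf$ga_weeks
  term <- ga >= 37
  correct <- as.character(full$oob$label) == as.character(full$oob$truth)
  strat_row <- function(sel, name) {
    m <- model_metrics(full$oob$score[sel], full$oob$truth[sel],
                       subjects = full$oob$subject_id[sel],
                       alpha = config$alpha, n_boot = 0)
    metrics_row(name, m)
  }
  strata_tab <- rbind(strat_row(!term, "preterm"), strat_row(term, "term"))
  strata_chisq <- chi_square_accuracy(sum(correct[term]), sum(term),
                                      sum(correct[!term]), sum(!term))

  # test-set models: full, singles, behavioural+physiological subset
  model_sets <- c(list(full = config$full_measures),
                  as.list(setNames(config$full_measures,
                                   config$full_measures)),
                  list(behav_physio = config$subset_measures))
  truth_test <- factor(test_feat$condition, c("control", "noxious"))
  test_scores <- list()
  i <- 0L
  for (nm in names(model_sets)) {
    i <- i + 1L
    fit <- if (nm == "full") full else {
      subject_rf(tf[model_sets[[nm]]],
                 factor(tf$condition, c("control", "noxious")),
                 tf$subject_id, n_trees = config$n_trees,
                 mtry = config$mtry, seed = config$seed + i)
    }
    test_scores[[nm]] <- predict(fit, test_feat, type = "score")
  }

  full_correct <- (test_scores$full > 0.5) ==
    (truth_test == "noxious")
  test_tab <- do.call(rbind, lapply(names(model_sets), function(nm) {
    m <- model_metrics(test_scores[[nm]], truth_test,
                       subjects = test_feat$subject_id,
                       alpha = config$alpha, n_boot = config$n_boot,
                       seed = config$seed)
    row <- metrics_row(nm, m)
    if (nm == "full") {
      row$p_mcnemar_vs_full <- NA_real_
      row$p_delong_vs_full <- NA_real_
    } else {
      corr <- (test_scores[[nm]] > 0.5) == (truth_test == "noxious")
      row$p_mcnemar_vs_full <- mcnemar_midp(corr, full_correct)
      row$p_delong_vs_full <- delong_paired_test(
        test_scores[[nm]], test_scores$full, truth_test)$p
    }
    row
  }))
  rownames(test_tab) <- NULL

  headline <- c("BB", "ES", "NF", "EEGt", "EEGa", "hr_max_15", "sat_min_30",
                "RMSi", "DURi", "AMPi", "RMSc", "DURc", "AMPc")
  spearman <- spearman_matrix(train_feat[headline], alpha = config$alpha)

  structure(list(train_metrics = train_metrics,
                 strata = list(table = strata_tab, chisq = strata_chisq),
                 test_table = test_tab,
                 test_scores = test_scores,
                 spearman = spearman,
                 model = full,
                 n_train_subjects = length(unique(tf$subject_id)),
                 n_test_subjects = length(unique(test_feat$subject_id)),
                 train_features = train_feat, test_features = test_feat,
                 config = config),
            class = "multimodal_result")
}

#' @export
print.within_modality_result <- function(x, ...) {
  cat("Within-modality comparison\n")
  for (fam in names(x$tables)) {
    cat(sprintf("  %s: best %s (accuracy %.3f, AUC %.3f), %d models\n",
                fam, x$best[fam],
                x$tables[[fam]]$accuracy[x$tables[[fam]]$model == x$best[fam]],
                x$tables[[fam]]$auc[x$tables[[fam]]$model == x$best[fam]],
                nrow(x$tables[[fam]])))
  }
  invisible(x)
}

#' @export
print.multimodal_result <- function(x, ...) {
  cat(sprintf("Multimodal experiment: %d training / %d test subjects\n",
              x$n_train_subjects, x$n_test_subjects))
  cat("Training (out-of-bag):\n")
  print(x$train_metrics)
  cat(sprintf("Term vs preterm accuracy: chi-square %.3f, p = %.3g\n",
              x$strata$chisq$statistic, x$strata$chisq$p))
  cat("Test set:\n")
  print(x$test_table[c("model", "n", "accuracy", "auc",
                       "p_mcnemar_vs_full", "p_delong_vs_full")])
  invisible(x)
}
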