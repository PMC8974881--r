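# Report generation: metrics JSON, comparison CSVs, ROC-point CSVs and a
# plain-text summary, each stamped with the config hash and seed.

result_payload <- function(results) {
  if (inherits(results, "painforest_report")) return(results)
  cfg <- results$config
  cfg_json <- as.character(jsonlite::toJSON(unclass_deep(cfg),
                                            auto_unbox = TRUE, digits = I(17)))
  stamp <- list(config_hash = config_hash(cfg_json), seed = cfg$seed)
  if (inherits(results, "within_modality_result")) {
    payload <- list(kind = "within_modality", stamp = stamp,
                    config = unclass_deep(cfg),
                    best = as.list(results$best),
                    tables = lapply(results$tables, function(t) {
                      c(list(reference_model = attr(t, "reference_model")),
                        list(rows = t))
                    }))
  } else if (inherits(results, "multimodal_result")) {
    tm <- results$train_metrics
    payload <- list(
      kind = "multimodal", stamp = stamp, config = unclass_deep(cfg),
      n_train_subjects = results$n_train_subjects,
      n_test_subjects = results$n_test_subjects,
      train = list(accuracy = tm$accuracy, accuracy_ci = tm$accuracy_ci,
                   sensitivity = tm$sensitivity,
                   specificity = tm$specificity,
                   auc = tm$auc, auc_ci = tm$auc_ci,
                   n = tm$n_observations),
      strata = list(table = results$strata$table,
                    chisq_statistic = results$strata$chisq$statistic,
                    chisq_p = results$strata$chisq$p),
      test = results$test_table,
      spearman = list(rho = results$spearman$rho,
                      p = results$spearman$p))
  } else {
    stop("report() expects a within_modality_result, multimodal_result, ",
         "or a payload from read_report()")
  }
  structure(payload, class = "painforest_report")
}

unclass_deep <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    x[] <- lapply(x, unclass_deep)
  }
  x
}

#' Write an experiment report to a directory
#'
#' Emits `report.json` (the complete payload), one CSV per comparison
#' table, ROC-point CSVs for the multimodal test models, and a plain-text
#' `summary.txt`. Every file embeds the configuration hash and seed; the
#' JSON payload is byte-identical across reruns with the same seed.
#'
#' @param results A `within_modality_result`, `multimodal_result`, or the
#'   payload returned by [read_report()].
#' @param directory Output directory (created if needed).
#' @param roc_curves Optional named list of ROC curve data frames to write
#'   as `<name>_roc.csv` (the multimodal driver's scores produce them
#'   automatically when `results` is a `multimodal_result`).
#' @return The payload, invisibly.
#' @export
report <- function(results, directory, roc_curves = NULL) {
  payload <- result_payload(results)
  ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stop("cannot create directory: ", directory)
  probe <- file.path(directory, ".write_probe")
  ok <- tryCatch({ writeLines("", probe); TRUE }, error = function(e) FALSE)
  if (!ok) stop("directory not writable: ", directory)
  unlink(probe)

  writeLines(jsonlite::toJSON(unclass(payload), auto_unbox = TRUE,
                              digits = I(17), na = "null", pretty = TRUE),
             file.path(directory, "report.json"))

  stamp_line <- sprintf("# config_hash=%s seed=%d",
                        payload$stamp$config_hash, payload$stamp$seed)
  put_csv <- function(df, name) {
    path <- file.path(directory, name)
    con <- file(path, "w")
    writeLines(stamp_line, con)
    write.csv(df, con, row.names = FALSE)
    close(con)
  }
  if (identical(payload$kind, "within_modality")) {
    for (fam in names(payload$tables)) {
      put_csv(as.data.frame(payload$tables[[fam]]$rows),
              sprintf("within_%s.csv", fam))
    }
  } else {
    put_csv(as.data.frame(payload$test), "multimodal_test.csv")
    put_csv(as.data.frame(payload$strata$table), "multimodal_strata.csv")
  }
  if (inherits(results, "multimodal_result")) {
    truth <- factor(results$test_features$condition,
                    c("control", "noxious"))
    for (nm in names(results$test_scores)) {
      rc <- roc_and_auc(results$test_scores[[nm]], truth)$curve
      put_csv(rc, sprintf("roc_%s.csv", nm))
    }
  } else if (!is.null(roc_curves)) {
    for (nm in names(roc_curves)) {
      put_csv(roc_curves[[nm]], sprintf("roc_%s.csv", nm))
    }
  }

  summary_lines <- c(stamp_line, summarise_payload(payload))
  writeLines(summary_lines, file.path(directory, "summary.txt"))
  invisible(payload)
}

summarise_payload <- function(payload) {
  if (identical(payload$kind, "within_modality")) {
    c("Within-modality measure comparison",
      vapply(names(payload$tables), function(fam) {
        rows <- as.data.frame(payload$tables[[fam]]$rows)
        sprintf("%s: %d models; best %s (accuracy %.3f, AUC %.3f)",
                fam, nrow(rows), rows$model[1], rows$accuracy[1],
                rows$auc[1])
      }, character(1)))
  } else {
    tt <- as.data.frame(payload$test)
    c("Multimodal train/validate experiment",
      sprintf("training subjects: %d, test subjects: %d",
              payload$n_train_subjects, payload$n_test_subjects),
      sprintf("training OOB accuracy %.3f, AUC %.3f",
              payload$train$accuracy, payload$train$auc),
      sprintf("term/preterm chi-square p = %.4g", payload$strata$chisq_p),
      vapply(seq_len(nrow(tt)), function(i) {
        sprintf("test %s: accuracy %.3f, AUC %.3f",
                tt$model[i], tt$accuracy[i], tt$auc[i])
      }, character(1)))
  }
}

#' @rdname report
#' @export
read_report <- function(directory) {
  path <- file.path(directory, "report.json")
  if (!file.exists(path)) stop("no report.json in ", directory)
  structure(jsonlite::fromJSON(path, simplifyVector = TRUE),
            class = "painforest_report")
}
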