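# Assembly of the per-observation feature vector from raw signals.

#' Names of the per-observation measures
#'
#' The full measure set: three facial-action durations (`BB`, `ES`, `NF`),
#' the 24-measure heart-rate grid, the 24-measure saturation grid, the two
#' automated EEG magnitudes (`EEGt` template projection, `EEGa` automated
#' peak-to-peak) and the six EMG reflex measures (`RMSi`, `DURi`, `AMPi`
#' and contralateral counterparts).
#'
#' @return Character vector of 59 measure names.
#' @export
feature_names <- function() {
  hr <- names(windowed_change_features(numeric(0), numeric(0), "max", "hr"))
  sat <- names(windowed_change_features(numeric(0), numeric(0), "min", "sat"))
  c("BB", "ES", "NF", hr, sat, "EEGt", "EEGa",
    "RMSi", "DURi", "AMPi", "RMSc", "DURc", "AMPc")
}

# modality owning each measure, for availability masking and the pipeline's
# model definitions
measure_modality <- function() {
  nm <- feature_names()
  mod <- character(length(nm))
  mod[nm %in% c("BB", "ES", "NF")] <- "facial"
  mod[startsWith(nm, "hr_")] <- "hr"
  mod[startsWith(nm, "sat_")] <- "spo2"
  mod[nm %in% c("EEGt", "EEGa")] <- "eeg"
  mod[nm %in% c("RMSi", "DURi", "AMPi")] <- "emg_ipsi"
  mod[nm %in% c("RMSc", "DURc", "AMPc")] <- "emg_contra"
  setNames(mod, nm)
}

# filtered, baseline-corrected EEG epoch of a recording (NULL if absent)
eeg_epoch_of <- function(rec) {
  if (is.null(rec$eeg)) return(NULL)
  filt <- eeg_filter(rec$eeg$x, rec$eeg$fs)
  epoch_and_baseline(filt, rec$eeg$fs, rec$eeg$t0, -0.5, 1.0,
                     baseline_window = c(-0.5, 0))
}

emg_epoch_of <- function(sig) {
  filt <- suppress_band_cap(emg_filter(sig$x, sig$fs))
  epoch_and_baseline(filt, sig$fs, sig$t0, -2, 14.5)
}

# EMG's nominal 500 Hz upper edge exceeds Nyquist at the default sampling
# rate; the capping warning is expected there, so log it rather than raise.
suppress_band_cap <- function(expr) {
  withCallingHandlers(expr, painforest_band_capped = function(w) {
    invokeRestart("muffleWarning")
  })
}

#' Extract the measure vector of one observation
#'
#' Applies the full per-modality chain (filter, epoch, align, measure) to a
#' single recording. An unavailable modality yields `NA` for all its
#' measures; an EMG burst with no identifiable endpoint yields `NA` for that
#' leg's duration and amplitude only. Modality-level processing failures are
#' converted to missingness with a recorded reason, never a pipeline abort.
#'
#' @param recording A `pain_recording`.
#' @param template A `pain_template` at the recording's EEG sampling rate.
#' @param eega_reference Optional `pain_epoch`: the cohort-average noxious
#'   EEG epoch used as the Woody reference for the automated peak-to-peak
#'   measure (`EEGa` is `NA` when absent). The template itself is the Woody
#'   reference for `EEGt`.
#' @return Named numeric vector over [feature_names()], with attributes
#'   `subject_id`, `condition` and `exclusions` (character log of per-
#'   modality failures).
#' @export
extract_feature_vector <- function(recording, template,
                                   eega_reference = NULL) {
  stopifnot(inherits(recording, "pain_recording"))
  out <- setNames(rep(NA_real_, length(feature_names())), feature_names())
  notes <- character(0)
  note <- function(m, e) {
    notes <<- c(notes, sprintf("%s: %s", m, conditionMessage(e)))
  }

  if (isTRUE(recording$available[["facial"]]) && !is.null(recording$facial)) {
    out[c("BB", "ES", "NF")] <- recording$facial[c("BB", "ES", "NF")]
  }

  if (isTRUE(recording$available[["hr"]]) && !is.null(recording$beat_times)) {
    tryCatch({
      hrs <- heart_rate_series(recording$beat_times)
      out[startsWith(names(out), "hr_")] <-
        windowed_change_features(hrs$t, hrs$bpm, "max", "hr")
    }, error = function(e) note("hr", e))
  }

  if (isTRUE(recording$available[["spo2"]]) && !is.null(recording$spo2)) {
    tryCatch({
      sp <- recording$spo2
      tt <- sp$t0 + (seq_along(sp$x) - 1) / sp$fs
      out[startsWith(names(out), "sat_")] <-
        windowed_change_features(tt, sp$x, "min", "sat")
    }, error = function(e) note("spo2", e))
  }

  if (isTRUE(recording$available[["eeg"]]) && !is.null(recording$eeg)) {
    tryCatch({
      ep <- eeg_epoch_of(recording)
      al_t <- woody_align(ep, template)
      out["EEGt"] <- template_magnitude(al_t$epoch, template)
      if (!is.null(eega_reference)) {
        al_a <- woody_align(ep, eega_reference)
        out["EEGa"] <- auto_peak_to_peak(al_a$epoch)
      }
    }, error = function(e) note("eeg", e))
  }

  for (leg in c("ipsi", "contra")) {
    m <- paste0("emg_", leg)
    suf <- substr(leg, 1, 1)
    if (isTRUE(recording$available[[m]]) && !is.null(recording[[m]])) {
      tryCatch({
        ep <- emg_epoch_of(recording[[m]])
        out[paste0("RMS", suf)] <- emg_rms(ep)
        bm <- emg_burst_metrics(ep)
        if (bm$no_endpoint) {
          notes <- c(notes, sprintf("%s: reflex endpoint not identifiable", m))
        } else {
          out[paste0("DUR", suf)] <- bm$duration_s
          out[paste0("AMP", suf)] <- bm$amplitude
        }
      }, error = function(e) note(m, e))
    }
  }

  attr(out, "subject_id") <- recording$subject_id
  attr(out, "condition") <- recording$condition
  attr(out, "exclusions") <- notes
  out
}

#' Extract the feature table of a cohort
#'
#' Runs [extract_feature_vector()] over every observation. The Woody
#' reference for the automated peak-to-peak measure is the average of the
#' available noxious EEG epochs of this cohort; when extracting a held-out
#' test cohort, pass the training cohort's reference (stored in the result's
#' `eega_reference` attribute) so that no test information enters the
#' reference.
#'
#' @param cohort A `pain_cohort`.
#' @param template Optional `pain_template` (built from the cohort's EEG
#'   sampling rate if omitted).
#' @param eega_reference Optional `pain_epoch` Woody reference; computed
#'   from this cohort's noxious epochs when `NULL`.
#' @return Data frame: `subject_id`, `condition`, `ga_weeks`, then the 59
#'   measures; missing encoded as `NA`. Attributes: `eega_reference`,
#'   `exclusions` (named character vector), `template_fs`.
#' @export
extract_features <- function(cohort, template = NULL, eega_reference = NULL) {
  stopifnot(inherits(cohort, "pain_cohort"))
  if (is.null(template)) template <- make_template(cohort$config$fs_eeg_hz)

  if (is.null(eega_reference)) {
    eega_reference <- cohort_average_epoch(cohort)
  }

  rows <- vector("list", length(cohort$recordings))
  excl <- character(0)
  for (i in seq_along(cohort$recordings)) {
    rec <- cohort$recordings[[i]]
    fv <- extract_feature_vector(rec, template, eega_reference)
    if (length(attr(fv, "exclusions"))) {
      excl[sprintf("sub%03d_%s", rec$subject_id, rec$condition)] <-
        paste(attr(fv, "exclusions"), collapse = "; ")
    }
    rows[[i]] <- data.frame(subject_id = rec$subject_id,
                            condition = rec$condition,
                            ga_weeks = rec$ga_weeks,
                            as.list(fv), row.names = NULL)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "eega_reference") <- eega_reference
  attr(out, "exclusions") <- excl
  attr(out, "template_fs") <- template$fs
  out
}

# average filtered noxious EEG epoch (Woody reference for EEGa); NULL when
# no noxious EEG is available
cohort_average_epoch <- function(cohort) {
  eps <- list()
  for (rec in cohort$recordings) {
    if (rec$condition == "noxious" && isTRUE(rec$available[["eeg"]]) &&
        !is.null(rec$eeg)) {
      eps[[length(eps) + 1L]] <- eeg_epoch_of(rec)
    }
  }
  if (length(eps) == 0) return(NULL)
  avg <- Reduce(`+`, lapply(eps, `[[`, "x")) / length(eps)
  structure(list(x = avg, fs = eps[[1]]$fs, t_start = eps[[1]]$t_start),
            class = "pain_epoch")
}

#' Write / read a feature table as CSV with a JSON sidecar
#'
#' One row per observation, columns `subject_id`, `condition`, `ga_weeks`
#' and the 59 measures; missing values are empty cells. The sidecar
#' `<path>.json` records the extraction configuration echo and per-row
#' exclusion reasons.
#'
#' @param features Data frame from [extract_features()].
#' @param path CSV file path.
#' @return `write_features()`: `path` invisibly. `read_features()`: the
#'   feature data frame (sidecar attributes restored when present).
#' @export
write_features <- function(features, path) {
  write.csv(features, path, row.names = FALSE, na = "")
  sidecar <- list(template_fs = attr(features, "template_fs"),
                  exclusions = as.list(attr(features, "exclusions")))
  writeLines(jsonlite::toJSON(sidecar, auto_unbox = TRUE, digits = I(17),
                              pretty = TRUE),
             paste0(path, ".json"))
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  sc <- paste0(path, ".json")
  if (file.exists(sc)) {
    side <- jsonlite::fromJSON(sc)
    attr(out, "template_fs") <- side$template_fs
    attr(out, "exclusions") <- unlist(side$exclusions)
  }
  out
}
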