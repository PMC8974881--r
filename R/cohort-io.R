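# Plain-text cohort serialization. Signals go to two-column CSVs
# (time_s,value), beat times to one-column CSVs, everything else to a JSON
# manifest. Numbers are printed with 17 significant digits so that
# read(write(cohort)) reproduces every sample bit-exactly.

fmt17 <- function(x) sprintf("%.17g", x)

write_signal_csv <- function(sig, path) {
  t <- sig$t0 + (seq_along(sig$x) - 1) / sig$fs
  writeLines(c("time_s,value", paste(fmt17(t), fmt17(sig$x), sep = ",")),
             path)
}

read_signal_csv <- function(path) {
  d <- read.csv(path, colClasses = c("numeric", "numeric"))
  if (!identical(names(d), c("time_s", "value"))) {
    stop("malformed signal file (expected columns time_s,value): ", path)
  }
  fs <- 1 / mean(diff(d$time_s))
  list(x = d$value, fs = round(fs, 9), t0 = d$time_s[1])
}

#' Write / read a synthetic cohort as plain-text files
#'
#' `write_cohort()` lays a cohort out as one directory: `manifest.json`
#' (subjects, conditions, facial durations, availability flags, relative
#' signal paths, generator-config echo) plus per-observation CSV signal
#' files. `read_cohort()` loads such a directory back, validating that every
#' referenced file exists, beat times are strictly increasing, saturation
#' values lie in \[0, 100\] and facial durations in \[0, 30\]; violations
#' name the offending record. The round trip is bit-exact.
#'
#' @param cohort A `pain_cohort` from [simulate_cohort()].
#' @param directory Target directory (created if needed).
#' @return `write_cohort()` returns `directory` invisibly; `read_cohort()`
#'   returns a `pain_cohort`.
#' @export
write_cohort <- function(cohort, directory) {
  stopifnot(inherits(cohort, "pain_cohort"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  subjects <- list()
  for (rec in cohort$recordings) {
    key <- sprintf("sub%03d_%s", rec$subject_id, rec$condition)
    files <- list()
    for (m in c("eeg", "emg_ipsi", "emg_contra", "spo2")) {
      if (!is.null(rec[[m]])) {
        fn <- paste0(key, "_", m, ".csv")
        write_signal_csv(rec[[m]], file.path(directory, fn))
        files[[m]] <- fn
      }
    }
    if (!is.null(rec$beat_times)) {
      fn <- paste0(key, "_beats.csv")
      writeLines(c("beat_time_s", fmt17(rec$beat_times)),
                 file.path(directory, fn))
      files[["beats"]] <- fn
    }
    subjects[[length(subjects) + 1L]] <- list(
      subject_id = rec$subject_id,
      condition = rec$condition,
      ga_weeks = rec$ga_weeks,
      responsiveness = rec$responsiveness,
      available = as.list(rec$available),
      facial = if (is.null(rec$facial)) NULL else as.list(rec$facial),
      files = files)
  }
  cfg_echo <- unclass(cohort$config)
  cfg_echo$missingness <- as.list(cfg_echo$missingness)
  manifest <- list(format = "painforest-cohort-v1",
                   config = cfg_echo,
                   observations = subjects)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = I(17),
                              null = "null", pretty = TRUE),
             file.path(directory, "manifest.json"))
  invisible(directory)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(directory) {
  mf <- file.path(directory, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json in ", directory)
  manifest <- jsonlite::fromJSON(mf, simplifyVector = FALSE)
  if (!identical(manifest$format, "painforest-cohort-v1")) {
    stop("unrecognised cohort format in ", mf)
  }
  cfg <- manifest$config
  cfg$missingness <- unlist(cfg$missingness)
  cfg <- structure(cfg, class = "cohort_config")
  validate_cohort_config(cfg)

  recordings <- list()
  rows <- list()
  for (obs in manifest$observations) {
    key <- sprintf("sub%03d_%s", obs$subject_id, obs$condition)
    rec <- list(subject_id = as.integer(obs$subject_id),
                condition = obs$condition,
                available = setNames(
                  unlist(obs$available)[MODALITIES], MODALITIES),
                ga_weeks = obs$ga_weeks,
                responsiveness = obs$responsiveness)
    for (m in names(obs$files)) {
      path <- file.path(directory, obs$files[[m]])
      if (!file.exists(path)) {
        stop(sprintf("record %s: referenced file is missing: %s",
                     key, obs$files[[m]]))
      }
      if (m == "beats") {
        beats <- read.csv(path, colClasses = "numeric")[[1]]
        if (any(diff(beats) <= 0)) {
          stop(sprintf("record %s: beat times are not strictly increasing",
                       key))
        }
        rec$beat_times <- beats
      } else {
        rec[[m]] <- read_signal_csv(path)
      }
    }
    if (!is.null(rec$spo2) && (any(rec$spo2$x < 0) || any(rec$spo2$x > 100))) {
      stop(sprintf("record %s: SpO2 values outside [0, 100]", key))
    }
    if (!is.null(obs$facial)) {
      rec$facial <- unlist(obs$facial)[c("BB", "ES", "NF")]
      if (any(rec$facial < 0) || any(rec$facial > 30)) {
        stop(sprintf("record %s: facial durations outside [0, 30] s", key))
      }
    }
    keep <- c("subject_id", "condition", "eeg", "emg_ipsi", "emg_contra",
              "beat_times", "spo2", "facial", "available", "ga_weeks",
              "responsiveness")
    rec <- structure(rec[intersect(keep, names(rec))],
                     class = "pain_recording")
    recordings[[length(recordings) + 1L]] <- rec
    rows[[length(rows) + 1L]] <- data.frame(
      subject_id = rec$subject_id, condition = rec$condition,
      ga_weeks = rec$ga_weeks, responsiveness = rec$responsiveness,
      as.list(rec$available), row.names = NULL)
  }
  manifest_df <- do.call(rbind, rows)
  rownames(manifest_df) <- NULL
  structure(list(config = cfg, recordings = recordings,
                 manifest = manifest_df),
            class = "pain_cohort")
}
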