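# Synthetic paired-recording generator. Every random draw comes from a
# deterministic substream keyed by (seed, subject, modality), so a subject's
# signals are reproducible regardless of cohort size or simulation order.

with_preserved_rng <- function(code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  force(code)
}

# smooth AR(1) process with marginal sd `sd` and correlation time `tau` (s)
ar1_noise <- function(n, dt, sd, tau) {
  if (sd == 0) return(numeric(n))
  phi <- exp(-dt / tau)
  x <- numeric(n)
  x[1] <- rnorm(1, 0, sd)
  innov <- rnorm(n - 1, 0, sd * sqrt(1 - phi^2))
  for (i in seq_len(n - 1)) x[i + 1] <- phi * x[i] + innov[i]
  x
}

# gamma-shaped transient: 0 before `onset`, peaks (value 1) at onset + tp
transient <- function(t, onset, tp) {
  u <- (t - onset) / tp
  ifelse(u > 0, u * exp(1 - u), 0)
}

#' Simulate one subject's paired noxious/control recordings
#'
#' Generates the raw multimodal signals for a single subject under both
#' stimulus conditions. The noxious recording contains (i) a template-shaped
#' EEG deflection at a jittered latency, (ii) an EMG reflex burst on both
#' legs starting within the first half-second (ipsilateral at least as large
#' as contralateral), (iii) a heart-rate rise peaking near 12 s, (iv) an
#' occasional delayed oxygen-saturation dip, and (v) prolonged facial-action
#' durations. The control recording realises the same baseline processes
#' with every effect contribution set to zero. All effect amplitudes are
#' scaled by a per-subject lognormal responsiveness factor shared between
#' the two conditions and across modalities.
#'
#' @param config A [cohort_config()].
#' @param subject_id Positive integer subject index.
#' @param template Optional `pain_template` at `config$fs_eeg_hz` (built on
#'   the fly if omitted; pass one when simulating many subjects).
#' @return List with elements `noxious` and `control`, each a
#'   `pain_recording`: subject_id, condition, `eeg`/`emg_ipsi`/`emg_contra`/
#'   `spo2` as lists `(x, fs, t0)` with time 0 at stimulus onset,
#'   `beat_times` (strictly increasing, spanning at least \[-20, 30\] s),
#'   `facial` durations (`BB`, `ES`, `NF`, seconds in \[0, 30\]),
#'   `available` flags, `ga_weeks`, and the latent `responsiveness`.
#' @export
simulate_subject <- function(config, subject_id, template = NULL) {
  validate_cohort_config(config)
  stopifnot(subject_id >= 1)
  if (is.null(template)) template <- make_template(config$fs_eeg_hz)
  stopifnot(inherits(template, "pain_template"),
            template$fs == config$fs_eeg_hz)

  with_preserved_rng({
    # subject-level latent state
    set.seed(substream_seed(config$seed, subject_id, "subject"))
    resp <- exp(rnorm(1, 0, config$responsiveness_sd) -
                  config$responsiveness_sd^2 / 2)
    ga_weeks <- runif(1, 34, 42.9)

    eeg <- sim_eeg(config, subject_id, resp, template)
    emg <- sim_emg(config, subject_id, resp)
    hr <- sim_beats(config, subject_id, resp)
    spo2 <- sim_spo2(config, subject_id, resp)
    facial <- sim_facial(config, subject_id, resp)

    mk <- function(cond) {
      structure(list(
        subject_id = as.integer(subject_id),
        condition = cond,
        eeg = eeg[[cond]],
        emg_ipsi = emg$ipsi[[cond]],
        emg_contra = emg$contra[[cond]],
        beat_times = hr[[cond]],
        spo2 = spo2[[cond]],
        facial = facial[[cond]],
        available = setNames(rep(TRUE, length(MODALITIES)), MODALITIES),
        ga_weeks = ga_weeks,
        responsiveness = resp
      ), class = "pain_recording")
    }
    list(noxious = mk("noxious"), control = mk("control"))
  })
}

sim_eeg <- function(cfg, id, resp, template) {
  fs <- cfg$fs_eeg_hz
  t0 <- -2
  n <- round(4 * fs)
  set.seed(substream_seed(cfg$seed, id, "eeg"))
  ctrl <- rnorm(n, 0, cfg$eeg_noise_sd)
  nox <- rnorm(n, 0, cfg$eeg_noise_sd)
  jitter_s <- runif(1, -cfg$latency_jitter_ms, cfg$latency_jitter_ms) / 1000
  shift <- round(jitter_s * fs)
  i0 <- round((template$t[1] - t0) * fs) + 1L + shift
  idx <- i0:(i0 + length(template$waveform) - 1L)
  nox[idx] <- nox[idx] + cfg$eeg_amp_uV * resp * template$waveform
  list(noxious = list(x = nox, fs = fs, t0 = t0),
       control = list(x = ctrl, fs = fs, t0 = t0))
}

sim_emg <- function(cfg, id, resp) {
  fs <- cfg$fs_emg_hz
  t0 <- -3
  n <- round(18 * fs)
  tt <- t0 + (seq_len(n) - 1) / fs
  # the reflex is one event: both legs share onset and duration
  set.seed(substream_seed(cfg$seed, id, "emg_timing"))
  onset <- runif(1, 0.05, 0.5)
  dur <- runif(1, 0.8, 2.5)
  env <- burst_envelope(tt, onset, dur)
  leg <- function(which, amp) {
    set.seed(substream_seed(cfg$seed, id, which))
    ctrl <- rnorm(n, 0, cfg$emg_noise_sd)
    nox <- rnorm(n, 0, cfg$emg_noise_sd)
    if (amp > 0) nox <- nox + rnorm(n, 0, amp) * env
    list(noxious = list(x = nox, fs = fs, t0 = t0),
         control = list(x = ctrl, fs = fs, t0 = t0))
  }
  list(ipsi = leg("emg_ipsi", cfg$emg_amp_uV * resp),
       contra = leg("emg_contra", cfg$emg_amp_uV * resp * cfg$emg_contra_ratio))
}

# raised-cosine-edged rectangular envelope (100 ms ramps)
burst_envelope <- function(t, onset, dur, ramp = 0.1) {
  env <- numeric(length(t))
  up <- t >= onset & t < onset + ramp
  flat <- t >= onset + ramp & t < onset + dur - ramp
  down <- t >= onset + dur - ramp & t < onset + dur
  env[up] <- 0.5 * (1 - cos(pi * (t[up] - onset) / ramp))
  env[flat] <- 1
  env[down] <- 0.5 * (1 - cos(pi * (onset + dur - t[down]) / ramp))
  env
}

# heartbeat times by time-rescaling an inhomogeneous rate 60/RR(t)
sim_beats <- function(cfg, id, resp) {
  dt <- 0.25
  tg <- seq(-25, 35, by = dt)
  set.seed(substream_seed(cfg$seed, id, "hr"))
  one <- function(rise_bpm) {
    noise <- ar1_noise(length(tg), dt, cfg$hr_noise_sd, tau = 5)
    hr <- cfg$hr_baseline_bpm + noise + rise_bpm * transient(tg, 0, 12)
    hr <- pmax(hr, 30)
    # cumulative expected beat count since tg[1], anchored at 0
    lam <- c(0, cumsum(hr[-1] / 60 * dt))
    u0 <- runif(1)
    ks <- seq(u0, max(lam), by = 1)
    approx(x = lam, y = tg, xout = ks)$y
  }
  nox <- one(cfg$hr_rise_bpm * resp)
  ctrl <- one(0)
  list(noxious = nox, control = ctrl)
}

sim_spo2 <- function(cfg, id, resp) {
  dt <- 1 / cfg$spo2_rate_hz
  tg <- seq(-20, 35, by = dt)
  set.seed(substream_seed(cfg$seed, id, "spo2"))
  one <- function(dip_pct) {
    noise <- ar1_noise(length(tg), dt, cfg$spo2_noise_sd, tau = 8)
    has_dip <- runif(1) < cfg$spo2_dip_prob
    x <- cfg$spo2_baseline_pct + noise -
      (if (has_dip) dip_pct * transient(tg, 5, 10) else 0)
    list(x = pmin(pmax(x, 0), 100), fs = cfg$spo2_rate_hz, t0 = tg[1])
  }
  nox <- one(cfg$spo2_dip_pct * resp)
  ctrl <- one(0)
  list(noxious = nox, control = ctrl)
}

sim_facial <- function(cfg, id, resp) {
  set.seed(substream_seed(cfg$seed, id, "facial"))
  draw <- function(mean_s) {
    if (mean_s <= 0) return(setNames(numeric(3), c("BB", "ES", "NF")))
    d <- rgamma(3, shape = 2, scale = mean_s / 2)
    setNames(pmin(d, 30), c("BB", "ES", "NF"))
  }
  nox <- draw(cfg$facial_baseline_s + cfg$facial_mean_s * resp)
  ctrl <- draw(cfg$facial_baseline_s)
  list(noxious = nox, control = ctrl)
}

#' Simulate a full paired cohort with per-modality missingness
#'
#' Runs [simulate_subject()] for every subject and then removes whole
#' modalities from individual observations independently with the configured
#' per-modality probabilities, emulating the per-modality artifact loss
#' patterns of real multimodal cohorts. The manifest records availability.
#'
#' @param config A [cohort_config()].
#' @return A `pain_cohort`: list with `config`, `recordings` (one
#'   `pain_recording` per observation, noxious and control interleaved per
#'   subject), and `manifest` (data frame: subject_id, condition, ga_weeks,
#'   responsiveness, one logical column per modality).
#' @export
simulate_cohort <- function(config) {
  validate_cohort_config(config)
  template <- make_template(config$fs_eeg_hz)
  recordings <- list()
  rows <- list()
  for (i in seq_len(config$n_subjects)) {
    pair <- simulate_subject(config, i, template)
    # whole-modality removal, independent per observation and modality
    with_preserved_rng({
      set.seed(substream_seed(config$seed, i, "missing"))
      for (cond in c("noxious", "control")) {
        drop <- runif(length(MODALITIES)) < config$missingness[MODALITIES]
        rec <- pair[[cond]]
        for (m in MODALITIES[drop]) {
          rec$available[[m]] <- FALSE
          rec[[modality_field(m)]] <- NULL
        }
        pair[[cond]] <- rec
      }
    })
    for (cond in c("noxious", "control")) {
      rec <- pair[[cond]]
      recordings[[length(recordings) + 1L]] <- rec
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = rec$subject_id, condition = rec$condition,
        ga_weeks = rec$ga_weeks, responsiveness = rec$responsiveness,
        as.list(rec$available), row.names = NULL)
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  structure(list(config = config, recordings = recordings,
                 manifest = manifest),
            class = "pain_cohort")
}

modality_field <- function(m) {
  switch(m, facial = "facial", hr = "beat_times", spo2 = "spo2",
         eeg = "eeg", emg_ipsi = "emg_ipsi", emg_contra = "emg_contra")
}

#' @export
print.pain_cohort <- function(x, ...) {
  cat(sprintf("Synthetic paired cohort: %d subjects, %d observations (seed %d)\n",
              x$config$n_subjects, nrow(x$manifest), x$config$seed))
  avail <- colMeans(x$manifest[MODALITIES])
  cat("  availability:", paste(sprintf("%s %.0f%%", names(avail),
                                       100 * avail), collapse = ", "), "\n")
  invisible(x)
}
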