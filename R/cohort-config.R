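#' Configuration for a synthetic paired-stimulus cohort
#'
#' Collects every parameter of the synthetic-data generator. Defaults emulate
#' a neonatal heel-lance study: each subject contributes one noxious and one
#' control observation; a per-subject latent responsiveness factor scales all
#' noxious effect sizes jointly, inducing the between-modality correlation
#' seen in real multimodal cohorts. Effect magnitudes default to values that
#' give single-measure discriminability in the range reported for this kind
#' of cohort (facial and EMG measures strongest, heart rate moderate, oxygen
#' saturation weakest through its occasional-dip mechanism).
#'
#' @param n_subjects Number of subjects (each yields a noxious/control pair).
#' @param seed Integer top-level seed. One shared seed spawns independent
#'   per-subject, per-modality substreams, so a subject's signals do not
#'   depend on cohort size.
#' @param fs_eeg_hz,fs_emg_hz EEG / EMG sampling rates (Hz).
#' @param spo2_rate_hz Oxygen-saturation sampling rate (Hz).
#' @param eeg_amp_uV Amplitude of the injected template-shaped EEG deflection
#'   (microvolts, before the responsiveness factor).
#' @param emg_amp_uV Within-burst EMG noise SD added on the ipsilateral leg
#'   (microvolts); the contralateral burst is scaled by `emg_contra_ratio`.
#' @param hr_rise_bpm Peak of the noxious heart-rate rise (bpm), reached
#'   around 12 s post-stimulus before decaying.
#' @param spo2_dip_pct Depth of the noxious oxygen-saturation dip (percentage
#'   points); dips occur with probability `spo2_dip_prob` and lag the
#'   stimulus by about 5 s, bottoming out near 15 s.
#' @param spo2_dip_prob Probability that a noxious trial shows a dip at all.
#' @param facial_mean_s Mean added facial-action duration (s) under the
#'   noxious condition; baseline grimacing of mean `facial_baseline_s` is
#'   present in both conditions. Durations are Gamma distributed (shape 2)
#'   truncated to the 30 s scoring window.
#' @param facial_baseline_s Baseline mean facial-action duration (s).
#' @param latency_jitter_ms Half-range of the uniform per-trial latency shift
#'   applied to the EEG deflection (ms).
#' @param eeg_noise_sd,emg_noise_sd EEG / EMG additive white-noise SD
#'   (microvolts).
#' @param hr_noise_sd Marginal SD of the smooth (AR(1)) heart-rate
#'   variability process (bpm).
#' @param spo2_noise_sd Marginal SD of the saturation noise process (pct pts).
#' @param hr_baseline_bpm,spo2_baseline_pct Baseline heart rate / saturation.
#' @param emg_contra_ratio Contralateral-to-ipsilateral burst amplitude
#'   ratio, in (0, 1\].
#' @param responsiveness_sd SD (log scale) of the per-subject lognormal
#'   responsiveness factor (mean 1).
#' @param missingness Named probabilities in \[0, 1\] of whole-modality
#'   removal per observation, for modalities `facial`, `hr`, `spo2`, `eeg`,
#'   `emg_ipsi`, `emg_contra`.
#' @return A validated list of class `cohort_config`.
#' @seealso [simulate_cohort()], [simulate_subject()]
#' @export
cohort_config <- function(n_subjects = 77L,
                          seed = 1L,
                          fs_eeg_hz = 500,
                          fs_emg_hz = 500,
                          spo2_rate_hz = 1,
                          eeg_amp_uV = 10,
                          emg_amp_uV = 1.2,
                          hr_rise_bpm = 6.5,
                          spo2_dip_pct = 2.5,
                          spo2_dip_prob = 0.35,
                          facial_mean_s = 2.5,
                          facial_baseline_s = 1,
                          latency_jitter_ms = 50,
                          eeg_noise_sd = 4,
                          emg_noise_sd = 2,
                          hr_noise_sd = 4,
                          spo2_noise_sd = 0.6,
                          hr_baseline_bpm = 140,
                          spo2_baseline_pct = 97,
                          emg_contra_ratio = 0.5,
                          responsiveness_sd = 0.7,
                          missingness = c(facial = 0.05, hr = 0.05,
                                          spo2 = 0.05, eeg = 0.05,
                                          emg_ipsi = 0.05, emg_contra = 0.05)) {
  cfg <- list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
              fs_eeg_hz = fs_eeg_hz, fs_emg_hz = fs_emg_hz,
              spo2_rate_hz = spo2_rate_hz,
              eeg_amp_uV = eeg_amp_uV, emg_amp_uV = emg_amp_uV,
              hr_rise_bpm = hr_rise_bpm, spo2_dip_pct = spo2_dip_pct,
              spo2_dip_prob = spo2_dip_prob,
              facial_mean_s = facial_mean_s,
              facial_baseline_s = facial_baseline_s,
              latency_jitter_ms = latency_jitter_ms,
              eeg_noise_sd = eeg_noise_sd, emg_noise_sd = emg_noise_sd,
              hr_noise_sd = hr_noise_sd, spo2_noise_sd = spo2_noise_sd,
              hr_baseline_bpm = hr_baseline_bpm,
              spo2_baseline_pct = spo2_baseline_pct,
              emg_contra_ratio = emg_contra_ratio,
              responsiveness_sd = responsiveness_sd,
              missingness = missingness)
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

MODALITIES <- c("facial", "hr", "spo2", "eeg", "emg_ipsi", "emg_contra")

validate_cohort_config <- function(cfg) {
  stopifnot(cfg$n_subjects >= 1L)
  rates <- c(cfg$fs_eeg_hz, cfg$fs_emg_hz, cfg$spo2_rate_hz)
  if (any(!is.finite(rates)) || any(rates <= 0)) {
    stop("all sampling rates must be > 0")
  }
  if (cfg$fs_eeg_hz < 200) stop("fs_eeg_hz must be >= 200 Hz to resolve the evoked template")
  effects <- c(cfg$eeg_amp_uV, cfg$emg_amp_uV, cfg$hr_rise_bpm,
               cfg$spo2_dip_pct, cfg$facial_mean_s, cfg$facial_baseline_s)
  if (any(effects < 0)) stop("effect sizes must be nonnegative")
  sds <- c(cfg$eeg_noise_sd, cfg$emg_noise_sd, cfg$hr_noise_sd,
           cfg$spo2_noise_sd, cfg$responsiveness_sd)
  if (any(sds < 0)) stop("noise SDs must be nonnegative")
  probs <- c(cfg$spo2_dip_prob, cfg$missingness)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (!all(MODALITIES %in% names(cfg$missingness))) {
    stop("missingness must name all modalities: ",
         paste(MODALITIES, collapse = ", "))
  }
  if (cfg$emg_contra_ratio <= 0 || cfg$emg_contra_ratio > 1) {
    stop("emg_contra_ratio must lie in (0, 1]")
  }
  if (cfg$hr_baseline_bpm <= 0 || cfg$spo2_baseline_pct <= 0 ||
      cfg$spo2_baseline_pct > 100) {
    stop("invalid baseline values")
  }
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("Synthetic cohort config: %d subjects, seed %d\n",
              x$n_subjects, x$seed))
  cat(sprintf("  effects: eeg %g uV, emg %g uV, hr %g bpm, spo2 %g%% (p=%g), facial %g s\n",
              x$eeg_amp_uV, x$emg_amp_uV, x$hr_rise_bpm, x$spo2_dip_pct,
              x$spo2_dip_prob, x$facial_mean_s))
  cat(sprintf("  noise: eeg %g, emg %g, hr %g, spo2 %g; responsiveness sd %g\n",
              x$eeg_noise_sd, x$emg_noise_sd, x$hr_noise_sd, x$spo2_noise_sd,
              x$responsiveness_sd))
  cat("  missingness:", paste(sprintf("%s=%g", names(x$missingness),
                                      x$missingness), collapse = " "), "\n")
  invisible(x)
}
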