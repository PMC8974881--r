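# EMG reflex quantification: windowed RMS and a threshold-crossing burst
# detector giving reflex duration and amplitude.

window_rms <- function(epoch, starts, width) {
  # cumulative-sum evaluation of RMS over many half-open windows
  cs <- c(0, cumsum(epoch$x^2))
  n <- length(epoch$x)
  i0 <- pmax(1L, round((starts - epoch$t_start) * epoch$fs) + 1L)
  i1 <- pmin(n, i0 + round(width * epoch$fs) - 1L)
  sqrt((cs[i1 + 1L] - cs[i0]) / (i1 - i0 + 1L))
}

#' Post-stimulus EMG root-mean-square
#'
#' RMS computed in 250 ms windows after the stimulus and averaged across the
#' first four windows, i.e. the first second post-stimulus.
#'
#' @param epoch Filtered EMG `pain_epoch` covering at least \[0, 1) s.
#' @return Scalar RMS (signal units).
#' @export
emg_rms <- function(epoch) {
  stopifnot(inherits(epoch, "pain_epoch"))
  mean(window_rms(epoch, starts = c(0, 0.25, 0.5, 0.75), width = 0.25))
}

#' Reflex burst duration and amplitude
#'
#' A documented threshold-crossing burst detector. The detection threshold is
#' mean + `thresh_sd` x SD of the RMS of 250 ms windows sliding at
#' `step_s` over the \[-2, 0) s baseline. Onset is the start of the first
#' post-stimulus window whose RMS exceeds the threshold, searched within the
#' first `max_onset_s` seconds (reflex withdrawal is a short-latency
#' response; an unbounded scan over the full 14.5 s epoch would cross a
#' 3-SD threshold by chance in roughly half of burst-free traces, while the
#' bounded scan keeps that rate below 10%). The offset is the start of the
#' first later window that begins a run of at least `offset_run`
#' consecutive sub-threshold windows, searched to the end of the epoch.
#' Duration is offset - onset and amplitude the maximum absolute sample in
#' \[onset, offset). A trace that never crosses threshold yields `(0, 0)`;
#' a burst still above threshold when the epoch ends is flagged
#' `no_endpoint` (such observations are excluded from duration/amplitude
#' downstream, mirroring how unresolvable reflex endpoints are treated in
#' practice). All detector constants are exposed as arguments.
#'
#' @param epoch Filtered EMG `pain_epoch` with at least 2 s of prestimulus
#'   baseline.
#' @param thresh_sd Baseline SD multiplier (default 3).
#' @param step_s Window step (s, default 0.05).
#' @param width_s RMS window width (s, default 0.25).
#' @param offset_run Consecutive sub-threshold windows ending the burst
#'   (default 4).
#' @param max_onset_s Latest window start considered for burst onset
#'   (default 1 s).
#' @return List: `duration_s`, `amplitude`, `no_endpoint`, `onset_s`,
#'   `threshold`.
#' @export
emg_burst_metrics <- function(epoch, thresh_sd = 3, step_s = 0.05,
                              width_s = 0.25, offset_run = 4L,
                              max_onset_s = 1) {
  stopifnot(inherits(epoch, "pain_epoch"))
  if (epoch$t_start > -2 + 1e-9) {
    stop(sprintf("burst detection needs a >= 2 s prestimulus baseline; epoch starts at %.3f s",
                 epoch$t_start))
  }
  tt <- epoch_times(epoch)
  t_end <- tt[length(tt)] + 1 / epoch$fs

  base_starts <- seq(-2, -width_s, by = step_s)
  base_rms <- window_rms(epoch, base_starts, width_s)
  threshold <- mean(base_rms) + thresh_sd * sd(base_rms)

  post_starts <- seq(0, t_end - width_s, by = step_s)
  post_rms <- window_rms(epoch, post_starts, width_s)
  above <- post_rms > threshold

  res <- list(duration_s = 0, amplitude = 0, no_endpoint = FALSE,
              onset_s = NA_real_, threshold = threshold)
  onset_candidates <- above & post_starts < max_onset_s
  if (!any(onset_candidates)) return(res)

  on_i <- which(onset_candidates)[1]
  res$onset_s <- post_starts[on_i]
  # first window after onset starting a run of >= offset_run sub-threshold
  off_i <- NA_integer_
  run <- 0L
  for (i in seq(on_i + 1L, length.out = max(0L, length(above) - on_i))) {
    if (!above[i]) {
      run <- run + 1L
      if (run == 1L) cand <- i
      if (run >= offset_run) { off_i <- cand; break }
    } else {
      run <- 0L
    }
  }
  if (is.na(off_i)) {
    res$no_endpoint <- TRUE
    return(res)
  }
  offset_s <- post_starts[off_i]
  res$duration_s <- offset_s - res$onset_s
  burst <- epoch$x[tt >= res$onset_s & tt < offset_s]
  res$amplitude <- max(abs(burst))
  res
}
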