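# Epoching, Woody latency alignment and the two automated EEG magnitude
# measures. All windows are half-open [a, b) in seconds relative to stimulus
# onset (t = 0).

#' Extract a stimulus-locked epoch with optional baseline correction
#'
#' Cuts the half-open window \[`t_start`, `t_end`) out of a sampled trace
#' and, if a baseline window is given, subtracts the mean over that window
#' (the EEG convention is a \[-0.5, 0) s prestimulus baseline; EMG epochs
#' are taken without baseline correction).
#'
#' @param x Numeric trace samples.
#' @param fs Sampling rate (Hz).
#' @param t0 Time of the first sample of `x` (s, stimulus at 0).
#' @param t_start,t_end Epoch bounds (s), half-open.
#' @param baseline_window Length-2 numeric or `NULL` for no correction.
#' @return A `pain_epoch`: list `(x, fs, t_start)`.
#' @export
epoch_and_baseline <- function(x, fs, t0, t_start, t_end,
                               baseline_window = NULL) {
  n_out <- round((t_end - t_start) * fs)
  i0 <- round((t_start - t0) * fs) + 1L
  i1 <- i0 + n_out - 1L
  if (i0 < 1L || i1 > length(x)) {
    cov0 <- t0
    cov1 <- t0 + length(x) / fs
    stop(sprintf(
      "trace covers [%.3f, %.3f) s but epoch needs [%.3f, %.3f) s; missing [%.3f, %.3f) s",
      cov0, cov1, t_start, t_end,
      if (i0 < 1L) t_start else cov1,
      if (i0 < 1L) cov0 else t_end))
  }
  ep <- x[i0:i1]
  tt <- t_start + (seq_len(n_out) - 1) / fs
  if (!is.null(baseline_window)) {
    sel <- tt >= baseline_window[1] & tt < baseline_window[2]
    if (!any(sel)) stop("baseline window contains no samples")
    ep <- ep - mean(ep[sel])
  }
  structure(list(x = ep, fs = fs, t_start = t_start), class = "pain_epoch")
}

epoch_times <- function(epoch) {
  epoch$t_start + (seq_along(epoch$x) - 1) / epoch$fs
}

# Values of an epoch on the reference's time grid (grids must share fs and
# phase, which they do throughout this package).
epoch_values_at <- function(epoch, times) {
  idx <- round((times - epoch$t_start) * epoch$fs) + 1L
  out <- rep(NA_real_, length(times))
  ok <- idx >= 1L & idx <= length(epoch$x)
  out[ok] <- epoch$x[idx[ok]]
  out
}

#' Woody alignment of a single trial to a reference
#'
#' Latency-corrects a single trial by integer-sample translation: the shift
#' in \[-`max_shift_ms`, +`max_shift_ms`\] maximising the normalised
#' cross-correlation between the shifted epoch and the reference over the
#' search window is applied. Shifts translate samples (edges become `NA`),
#' never wrap. Ties are broken toward the smallest absolute shift, then the
#' negative one, so the result is deterministic. A trial that is a delayed
#' copy of the reference by d ms yields shift -d (the trial is advanced).
#'
#' @param epoch A `pain_epoch`.
#' @param reference A `pain_template` or `pain_epoch` defined on the search
#'   window, at the same sampling rate.
#' @param search_window Length-2 window (s) over which correlation is
#'   evaluated; default \[0.4, 0.7) matches the evoked-potential convention.
#' @param max_shift_ms Maximum absolute shift (ms), default 100.
#' @return List: `shift_ms`, `shift_samples`, `epoch` (aligned `pain_epoch`
#'   with `NA` edge padding), `correlation`.
#' @export
woody_align <- function(epoch, reference, search_window = c(0.4, 0.7),
                        max_shift_ms = 100) {
  stopifnot(inherits(epoch, "pain_epoch"))
  fs <- epoch$fs
  ref_t <- if (inherits(reference, "pain_template")) reference$t else epoch_times(reference)
  ref_x <- if (inherits(reference, "pain_template")) reference$waveform else reference$x
  if (!isTRUE(all.equal(reference$fs, fs))) {
    stop("epoch and reference sampling rates differ")
  }
  sel <- ref_t >= search_window[1] & ref_t < search_window[2]
  if (!any(sel)) stop("reference does not cover the search window")
  wt <- ref_t[sel]
  rv <- ref_x[sel]

  smax <- round(max_shift_ms / 1000 * fs)
  shifts <- -smax:smax
  # evaluation order encodes the tie-break: |shift| ascending, negative first
  shifts <- shifts[order(abs(shifts), shifts)]
  et <- epoch_times(epoch)
  need_lo <- search_window[1] - smax / fs
  need_hi <- search_window[2] + smax / fs
  if (et[1] > need_lo + 1e-9 ||
      et[length(et)] + 1 / fs < need_hi - 1e-9) {
    stop(sprintf(
      "epoch [%.3f, %.3f) s cannot cover the search window after +/-%g ms shifts",
      et[1], et[length(et)] + 1 / fs, max_shift_ms))
  }

  best_c <- -Inf
  best_s <- 0L
  for (s in shifts) {
    # candidate aligned(t) = x(t - s), so correlate ref with x(wt - s)
    xv <- epoch_values_at(epoch, wt - s / fs)
    den <- sqrt(sum(xv^2) * sum(rv^2))
    cc <- if (den > 0) sum(xv * rv) / den else 0
    if (cc > best_c + 1e-12) {
      best_c <- cc
      best_s <- s
    }
  }

  # aligned(t) = x(t - shift)
  n <- length(epoch$x)
  aligned <- rep(NA_real_, n)
  src <- seq_len(n) - best_s
  ok <- src >= 1L & src <= n
  aligned[ok] <- epoch$x[src[ok]]
  list(shift_ms = best_s / fs * 1000,
       shift_samples = as.integer(best_s),
       correlation = best_c,
       epoch = structure(list(x = aligned, fs = fs,
                              t_start = epoch$t_start),
                         class = "pain_epoch"))
}

#' Template projection magnitude of an evoked response
#'
#' Least-squares scaling of the canonical template against a (previously
#' Woody-aligned) trial over the 400-700 ms window: the coefficient
#' beta = <x, T> / <T, T> with both restricted to the window. Sign is
#' preserved, so an inverted response yields a negative magnitude. The
#' operation is linear in the epoch.
#'
#' @param epoch Aligned `pain_epoch`.
#' @param template A `pain_template` at the epoch's sampling rate.
#' @param window Projection window (s), half-open.
#' @return Scalar magnitude (same units as the epoch).
#' @export
template_magnitude <- function(epoch, template, window = c(0.4, 0.7)) {
  stopifnot(inherits(epoch, "pain_epoch"), inherits(template, "pain_template"))
  sel <- template$t >= window[1] & template$t < window[2]
  tw <- template$waveform[sel]
  xv <- epoch_values_at(epoch, template$t[sel])
  ok <- !is.na(xv)
  if (!any(ok)) stop("epoch has no samples in the projection window")
  sum(xv[ok] * tw[ok]) / sum(tw[ok]^2)
}

#' Automated peak-to-peak amplitude of an evoked response
#'
#' The automated counterpart of observer peak picking: maximum over the
#' positive-peak window \[0.45, 0.65) s minus minimum over the
#' negative-peak window \[0.35, 0.45) s of a trial that has been
#' Woody-aligned to the cohort-average noxious response. The value can be
#' negative when the waveform is inverted.
#'
#' @param epoch Aligned `pain_epoch`.
#' @param neg_window,pos_window Half-open peak search windows (s).
#' @return Scalar amplitude.
#' @export
auto_peak_to_peak <- function(epoch, neg_window = c(0.35, 0.45),
                              pos_window = c(0.45, 0.65)) {
  stopifnot(inherits(epoch, "pain_epoch"))
  tt <- epoch_times(epoch)
  neg <- epoch$x[tt >= neg_window[1] & tt < neg_window[2]]
  pos <- epoch$x[tt >= pos_window[1] & tt < pos_window[2]]
  if (all(is.na(neg)) || all(is.na(pos))) {
    stop("epoch does not cover the peak search windows")
  }
  max(pos, na.rm = TRUE) - min(neg, na.rm = TRUE)
}
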