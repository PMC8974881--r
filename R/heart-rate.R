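# Beat-to-beat preprocessing and the windowed change-feature grids shared by
# heart rate and oxygen saturation.

#' Per-second heart rate from heartbeat times
#'
#' At each integer second t in \[-15, 30\], heart rate in bpm is 60 divided
#' by the mean of the RR intervals ending in the half-open window (t-5, t\].
#' Seconds in which no interval ends are `NA`.
#'
#' @param beat_times Strictly increasing heartbeat times (s, stimulus at 0),
#'   ideally covering \[-20, 30\] s.
#' @return Data frame with columns `t` (s) and `bpm`.
#' @export
heart_rate_series <- function(beat_times) {
  if (any(diff(beat_times) <= 0)) {
    stop("beat times must be strictly increasing")
  }
  rr <- diff(beat_times)
  rr_end <- beat_times[-1]
  tgrid <- -15:30
  bpm <- vapply(tgrid, function(t) {
    sel <- rr_end > t - 5 & rr_end <= t
    if (!any(sel)) return(NA_real_)
    60 / mean(rr[sel])
  }, numeric(1))
  data.frame(t = tgrid, bpm = bpm)
}

#' Windowed change features for a slow physiological series
#'
#' Computes the 4 x 6 grid of summary measures used for heart rate and
#' oxygen saturation: with baseline the mean over \[-15, 0) s and
#' prestimulus SD over the same window, each post-stimulus window
#' W in \{5, 10, 15, 20, 25, 30\} s yields mean change
#' (mean over \[0, W) minus baseline), extreme change (max for heart rate,
#' min for saturation, minus baseline) and the two normalised variants
#' (divided by the prestimulus SD). Normalised measures are `NA` when the
#' prestimulus SD is zero; if the baseline is entirely missing all 24
#' measures are `NA`. Missing samples are skipped.
#'
#' @param times Sample times (s).
#' @param values Series values (may contain `NA`).
#' @param direction `"max"` (heart rate) or `"min"` (saturation).
#' @param prefix Name prefix for the returned measures.
#' @param windows Post-stimulus window lengths (s).
#' @return Named numeric vector of length `4 * length(windows)`; names are
#'   `<prefix>_<mean|max|min|norm_mean|norm_max|norm_min>_<W>`.
#' @export
windowed_change_features <- function(times, values,
                                     direction = c("max", "min"),
                                     prefix = "hr",
                                     windows = c(5, 10, 15, 20, 25, 30)) {
  direction <- match.arg(direction)
  stopifnot(length(times) == length(values))
  ext_name <- direction
  nm <- as.vector(vapply(windows, function(W) {
    paste0(prefix, "_", c("mean", ext_name, "norm_mean",
                          paste0("norm_", ext_name)), "_", W)
  }, character(4)))
  out <- setNames(rep(NA_real_, length(nm)), nm)

  base <- values[times >= -15 & times < 0]
  base <- base[!is.na(base)]
  if (length(base) == 0) return(out)
  b_mean <- mean(base)
  b_sd <- sd(base)
  ext_fun <- if (direction == "max") max else min

  for (W in windows) {
    post <- values[times >= 0 & times < W]
    post <- post[!is.na(post)]
    if (length(post) == 0) next
    mc <- mean(post) - b_mean
    ec <- ext_fun(post) - b_mean
    out[paste0(prefix, "_mean_", W)] <- mc
    out[paste0(prefix, "_", ext_name, "_", W)] <- ec
    if (!is.na(b_sd) && b_sd > 0) {
      out[paste0(prefix, "_norm_mean_", W)] <- mc / b_sd
      out[paste0(prefix, "_norm_", ext_name, "_", W)] <- ec / b_sd
    }
  }
  out
}
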