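#' Zero-phase band-pass filter
#'
#' Butterworth band-pass applied channel-wise, forward and backward
#' (`signal::filtfilt`) so the filter adds no phase lag that would distort
#' lagged coupling between channels. The band is realized as a high-pass /
#' low-pass cascade, which stays numerically well conditioned when the lower
#' edge (0.3 Hz by default) is a tiny fraction of the sampling rate.
#'
#' @param rec An [eeg_recording()].
#' @param low_hz,high_hz Band edges in Hz; `0 < low_hz < high_hz < fs/2`.
#' @param order Butterworth order of each cascade half (default 4).
#' @return A filtered [eeg_recording()] of identical shape.
#' @export
bandpass_filter <- function(rec, low_hz = 0.3, high_hz = 75, order = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$fs / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq))
    stop("band edges must satisfy 0 < low_hz < high_hz < fs/2 = ", nyq)
  n <- ncol(rec$data)
  if (n < 3 * (order + 1))
    stop("signal too short for the filter warm-up")
  hp <- signal::butter(order, low_hz / nyq, type = "high")
  lp <- signal::butter(order, high_hz / nyq, type = "low")
  out <- rec$data
  for (i in seq_len(nrow(out))) {
    y <- signal::filtfilt(hp, out[i, ])
    out[i, ] <- signal::filtfilt(lp, y)
  }
  eeg_recording(out, fs = rec$fs, labels = rec$labels, stages = rec$stages)
}

#' Segment a recording into overlapping windows
#'
#' Windows of `window_s` seconds advance by `window_s * (1 - overlap_frac)`;
#' a trailing partial window is discarded. Each window is tagged with the
#' stage annotation covering its midpoint (`NA` when unannotated); windows
#' straddling a stage boundary are not split.
#'
#' @param rec An [eeg_recording()].
#' @param window_s Window length in seconds (default 12).
#' @param overlap_frac Fractional overlap in `[0, 1)` (default 0.5).
#' @return An object of class `window_set`: list with `windows` (list of
#'   channels x samples matrices), `starts_s`, `window_s`, `overlap_frac`,
#'   `stage_of_window`, `labels`, `fs`.
#' @export
segment_windows <- function(rec, window_s = 12, overlap_frac = 0.5) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (overlap_frac < 0 || overlap_frac >= 1)
    stop("`overlap_frac` must be in [0, 1)")
  wlen <- round(window_s * rec$fs)
  if (wlen < 2) stop("window must contain at least 2 samples")
  n <- ncol(rec$data)
  if (wlen > n)
    stop("window (", window_s, " s) longer than recording (", n / rec$fs, " s)")
  step <- max(1L, round(wlen * (1 - overlap_frac)))
  starts <- seq(1L, n - wlen + 1L, by = step)
  windows <- lapply(starts, function(s) rec$data[, s:(s + wlen - 1L),
                                                 drop = FALSE])
  starts_s <- (starts - 1L) / rec$fs
  mid_s <- starts_s + window_s / 2
  stage <- rep(NA_character_, length(starts))
  if (!is.null(rec$stages)) {
    for (k in seq_along(mid_s)) {
      hit <- which(rec$stages$start_s <= mid_s[k] & mid_s[k] < rec$stages$end_s)
      if (length(hit)) stage[k] <- rec$stages$stage[hit[1]]
    }
  }
  structure(list(windows = windows, starts_s = starts_s, window_s = window_s,
                 overlap_frac = overlap_frac, stage_of_window = stage,
                 labels = rec$labels, fs = rec$fs),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("<window_set> %d windows of %g s (overlap %g) x %d channels\n",
              length(x$windows), x$window_s, x$overlap_frac,
              length(x$labels)))
  if (!all(is.na(x$stage_of_window)))
    print(table(x$stage_of_window, useNA = "ifany"))
  invisible(x)
}
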