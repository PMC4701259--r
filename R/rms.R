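#' Sliding-window geometry
#'
#' Windows are specified in milliseconds and converted to samples at the
#' recording's rate, so the same 100 ms / 50 ms geometry holds at 400 Hz
#' (40-sample windows, 20-sample step) and at 2000 Hz (200 / 100 samples).
#'
#' @param window_ms window length (ms), default 100.
#' @param step_ms step between window starts (ms), default 50.
#' @return An object of class `window_config`.
#' @export
window_config <- function(window_ms = 100, step_ms = 50) {
  if (!(step_ms > 0 && step_ms <= window_ms))
    stop("need 0 < step_ms <= window_ms")
  structure(list(window_ms = window_ms, step_ms = step_ms),
            class = "window_config")
}

#' Root mean square of a signal window
#'
#' `sqrt(mean(x^2))`, the standard proxy for muscle contraction amplitude.
#'
#' @param window non-empty numeric vector.
#' @return The RMS value (non-negative).
#' @examples
#' rms(c(3, 4)) # sqrt(12.5)
#' @export
rms <- function(window) {
  if (length(window) == 0) stop("rms: window must be non-empty")
  if (any(!is.finite(window))) stop("rms: window contains non-finite values")
  sqrt(mean(window^2))
}

#' Enumerate sliding windows over a recording
#'
#' Half-open index ranges `[start, start + N)` (1-based starts in the
#' returned data.frame, `end` inclusive), advancing by the step; a trailing
#' incomplete window is dropped, so the count is
#' `floor((n_samples - N) / step) + 1`.
#'
#' @param n_samples number of samples available.
#' @param rate sampling rate (Hz).
#' @param config a [window_config()].
#' @return A data.frame with columns `start`, `end` (1-based inclusive
#'   sample indices); zero rows (with a warning) when the recording is
#'   shorter than one window.
#' @export
segment_windows <- function(n_samples, rate, config = window_config()) {
  stopifnot(inherits(config, "window_config"))
  N <- as.integer(round(config$window_ms / 1000 * rate))
  step <- as.integer(round(config$step_ms / 1000 * rate))
  if (N < 1 || step < 1)
    stop("window/step shorter than one sample at this rate")
  if (n_samples < N) {
    warning("recording shorter than one window; no windows")
    return(data.frame(start = integer(0), end = integer(0)))
  }
  n_win <- (n_samples - N) %/% step + 1
  start <- (seq_len(n_win) - 1L) * step + 1L
  data.frame(start = start, end = start + N - 1L)
}

#' Sliding-window RMS features from a recording
#'
#' One row per window, one RMS value per channel. The row's label is the
#' majority label within the window (ties broken toward the smaller class
#' index); its timestamp is the window-end time, which aligns the rows with
#' the 50 ms spiking-feature sampling instants.
#'
#' @param recording an [emg_recording()].
#' @param config a [window_config()].
#' @return A `feature_matrix` (see [make_feature_matrix()]).
#' @export
extract_rms_features <- function(recording, config = window_config()) {
  stopifnot(inherits(recording, "emg_recording"))
  win <- segment_windows(ncol(recording$signal), recording$sample_rate,
                         config)
  nch <- nrow(recording$signal)
  if (nrow(win) == 0) return(empty_feature_matrix(nch))
  feats <- matrix(0, nrow(win), nch)
  labels <- rep(NA_integer_, nrow(win))
  for (j in seq_len(nrow(win))) {
    idx <- win$start[j]:win$end[j]
    feats[j, ] <- sqrt(rowMeans(recording$signal[, idx, drop = FALSE]^2))
    if (!is.null(recording$labels)) {
      tab <- table(recording$labels[idx])
      labels[j] <- as.integer(names(tab)[which.max(tab)])
    }
  }
  t_ms <- win$end / recording$sample_rate * 1000
  make_feature_matrix(t_ms, feats, labels)
}
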