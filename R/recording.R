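#' Multichannel sEMG recording
#'
#' Container for a multichannel surface-EMG time series: a channels x
#' samples matrix in volts, the sampling rate, and optional per-sample
#' integer gesture labels.
#'
#' @param signal numeric matrix, channels x samples (volts).
#' @param sample_rate sampling rate (Hz); 400 (consumer bracelet class) and
#'   2000 (laboratory system class) are the two rates the pipeline targets,
#'   but any positive rate is accepted.
#' @param labels optional integer vector of per-sample gesture labels
#'   (length = number of samples).
#' @return An object of class `emg_recording`.
#' @export
emg_recording <- function(signal, sample_rate, labels = NULL) {
  signal <- as.matrix(signal)
  if (sample_rate <= 0) stop("sample_rate must be > 0")
  if (any(!is.finite(signal))) stop("signal contains non-finite samples")
  if (!is.null(labels) && length(labels) != ncol(signal))
    stop("labels length must equal the number of samples")
  structure(list(signal = signal, sample_rate = sample_rate,
                 labels = if (is.null(labels)) NULL else as.integer(labels)),
            class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  dur <- ncol(x$signal) / x$sample_rate
  cat(sprintf("<emg_recording> %d channels, %d samples @ %g Hz (%.2f s)%s\n",
              nrow(x$signal), ncol(x$signal), x$sample_rate, dur,
              if (is.null(x$labels)) "" else ", labelled"))
  invisible(x)
}

#' Recording duration in milliseconds
#' @param recording an [emg_recording()].
#' @return duration (ms).
#' @export
recording_duration_ms <- function(recording) {
  ncol(recording$signal) / recording$sample_rate * 1000
}

#' Write / read the sEMG CSV dialect
#'
#' Column layout `time_s,ch1..chN[,label]`; the sampling rate is inferred on
#' read from the time column spacing.
#'
#' @param recording an [emg_recording()].
#' @param file path to a CSV file.
#' @return `write_emg_csv` returns `file` invisibly; `read_emg_csv` returns
#'   an [emg_recording()].
#' @export
write_emg_csv <- function(recording, file) {
  n <- ncol(recording$signal)
  df <- data.frame(time_s = (seq_len(n) - 1) / recording$sample_rate)
  for (i in seq_len(nrow(recording$signal)))
    df[[paste0("ch", i)]] <- recording$signal[i, ]
  if (!is.null(recording$labels)) df$label <- recording$labels
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_emg_csv
#' @export
read_emg_csv <- function(file) {
  df <- utils::read.csv(file)
  ch_cols <- grep("^ch[0-9]+$", names(df), value = TRUE)
  if (length(ch_cols) == 0) stop("no channel columns (ch1..chN) in ", file)
  ch_cols <- ch_cols[order(as.integer(sub("ch", "", ch_cols)))]
  if (nrow(df) < 2) stop("recording must contain at least two samples")
  rate <- 1 / stats::median(diff(df$time_s))
  emg_recording(unname(t(as.matrix(df[ch_cols]))), round(rate, 6),
                labels = if ("label" %in% names(df)) df$label else NULL)
}
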