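#' Gesture activation profiles for the synthetic sEMG generator
#'
#' The generator emulates the acquisition protocol the pipeline was built
#' for: series of nine static hand gestures held 2-3 s each in random
#' order, with wrist relaxation between them, recorded on eight forearm
#' channels. Class 1 is rest (zero activation). Each of the eight active
#' gestures recruits a distinct sparse subset of three (ring-adjacent)
#' channels with per-channel envelope amplitudes drawn once, in the
#' 5e-5 to 1.2e-4 V RMS band -- the scale at which the stimulator gain
#' k = 2e6 puts sensory neurons firmly in their spiking range during
#' gestures and near silence at rest.
#'
#' @param n_gestures number of gesture classes including rest (default 9).
#' @param n_channels number of channels (default 8).
#' @param seed RNG seed for the amplitude draw.
#' @param common_mode_amp RMS amplitude (V) of the in-phase noise component
#'   shared identically by all channels (default 5e-6).
#' @param baseline_amp RMS amplitude (V) of per-channel baseline noise
#'   (default 2e-6).
#' @param duration_range gesture hold duration range (s), default `c(2, 3)`.
#' @return An object of class `gesture_profile` with the
#'   `n_gestures x n_channels` amplitude matrix and the noise/duration
#'   settings.
#' @export
make_gesture_profiles <- function(n_gestures = 9, n_channels = 8, seed = 1,
                                  common_mode_amp = 5e-6,
                                  baseline_amp = 2e-6,
                                  duration_range = c(2, 3)) {
  if (n_gestures < 1 || n_channels < 1)
    stop("n_gestures and n_channels must be >= 1")
  amp <- matrix(0, n_gestures, n_channels)
  with_seed(seed, {
    for (g in seq_len(n_gestures)[-1]) {
      # gesture g recruits 3 adjacent channels of the electrode ring,
      # shifted one channel per gesture: distinct subsets by construction
      ch <- ((g - 2 + 0:2) %% n_channels) + 1
      amp[g, ch] <- stats::runif(length(ch), 5e-5, 1.2e-4)
    }
  })
  structure(list(amplitude = amp, common_mode_amp = common_mode_amp,
                 baseline_amp = baseline_amp,
                 duration_range = duration_range),
            class = "gesture_profile")
}

#' Recording-series specification
#'
#' @param n_series number of gesture series (default 4).
#' @param sample_rate 400 or 2000 Hz (any positive rate accepted).
#' @param seed RNG seed; the gesture order, durations and noise of every
#'   series derive from it.
#' @param rest_s rest-gap duration between gestures (s), default 1.5.
#' @return An object of class `series_spec`.
#' @export
series_spec <- function(n_series = 4, sample_rate = 400, seed = 1,
                        rest_s = 1.5) {
  if (n_series < 1) stop("n_series must be >= 1")
  if (sample_rate <= 0) stop("sample_rate must be > 0")
  structure(list(n_series = n_series, sample_rate = sample_rate,
                 seed = seed, rest_s = rest_s),
            class = "series_spec")
}

# Band-limited (20-150 Hz) unit-RMS Gaussian noise: the standard surrogate
# for the interference pattern of surface EMG.
bandlimited_noise <- function(n, rate, low = 20, high = 150) {
  high <- min(high, 0.45 * rate)
  bf <- signal::butter(4, c(low, high) / (rate / 2), type = "pass")
  x <- signal::filtfilt(bf, stats::rnorm(n))
  x / sqrt(mean(x^2))
}

# Protocol timeline for one series, drawn in seconds so it is identical at
# any sampling rate: random gesture order, U(duration_range) holds, fixed
# rest gaps before/after every gesture.
series_timeline <- function(profile, rest_s) {
  n_g <- nrow(profile$amplitude)
  order <- sample(seq_len(n_g)[-1])
  dur <- stats::runif(length(order), profile$duration_range[1],
                      profile$duration_range[2])
  events <- data.frame(gesture = integer(0), start = numeric(0),
                       end = numeric(0))
  t <- rest_s
  for (i in seq_along(order)) {
    events <- rbind(events, data.frame(gesture = order[i], start = t,
                                       end = t + dur[i]))
    t <- t + dur[i] + rest_s
  }
  list(events = events, total_s = t)
}

# Raised-cosine on/off envelope with `ramp_s` transitions inside the span.
gesture_envelope <- function(tt, start, end, ramp_s = 0.1) {
  env <- numeric(length(tt))
  inside <- tt >= start & tt < end
  env[inside] <- 1
  up <- inside & tt < start + ramp_s
  env[up] <- 0.5 * (1 - cos(pi * (tt[up] - start) / ramp_s))
  down <- inside & tt >= end - ramp_s
  env[down] <- 0.5 * (1 - cos(pi * (end - tt[down]) / ramp_s))
  env
}

#' Generate one synthetic multichannel sEMG recording
#'
#' Per channel the signal is gesture-envelope-modulated band-limited
#' (20-150 Hz) Gaussian noise, independent across channels, plus an
#' in-phase common-mode noise term added identically to every channel,
#' plus per-channel baseline noise. Envelopes use 100 ms raised-cosine
#' ramps. Per-sample labels mark the gesture spans (class 1 = rest
#' elsewhere). Gesture order, durations and all noise derive from
#' `spec$seed` offset by `series`; the protocol timeline is drawn in
#' seconds, so the same seed produces the same gesture schedule at 400 and
#' 2000 Hz.
#'
#' @param profile a [make_gesture_profiles()] object.
#' @param spec a [series_spec()].
#' @param series which series to render (1-based index; offsets the seed).
#' @return A labelled [emg_recording()].
#' @export
generate_recording <- function(profile, spec, series = 1) {
  stopifnot(inherits(profile, "gesture_profile"),
            inherits(spec, "series_spec"))
  rate <- spec$sample_rate
  nch <- ncol(profile$amplitude)
  series_seed <- (as.numeric(spec$seed) * 1000 + series) %% 2147483647
  with_seed(series_seed, {
    tl <- series_timeline(profile, spec$rest_s)
    n <- as.integer(round(tl$total_s * rate))
    tt <- (seq_len(n) - 1) / rate
    labels <- rep(1L, n)
    sig <- matrix(0, nch, n)
    cm <- profile$common_mode_amp * bandlimited_noise(n, rate)
    for (i in seq_len(nch)) {
      env2 <- numeric(n) # summed squared gesture envelope amplitude
      for (e in seq_len(nrow(tl$events))) {
        g <- tl$events$gesture[e]
        if (profile$amplitude[g, i] > 0) {
          env <- gesture_envelope(tt, tl$events$start[e], tl$events$end[e])
          env2 <- env2 + (profile$amplitude[g, i] * env)^2
        }
      }
      sig[i, ] <- sqrt(env2) * bandlimited_noise(n, rate) + cm +
        profile$baseline_amp * bandlimited_noise(n, rate)
    }
    for (e in seq_len(nrow(tl$events))) {
      span <- tt >= tl$events$start[e] & tt < tl$events$end[e]
      labels[span] <- tl$events$gesture[e]
    }
    emg_recording(sig, rate, labels)
  })
}

#' Generate a train/test dataset of gesture series
#'
#' Renders `spec$n_series` independent series and assigns disjoint series
#' to the training and test split (default 3 train / 1 test), concatenating
#' each split into one labelled recording.
#'
#' @param spec a [series_spec()].
#' @param profile a [make_gesture_profiles()] object; defaults to
#'   `make_gesture_profiles(seed = spec$seed)`.
#' @param train_series,test_series how many series go to each split.
#' @return A list with labelled [emg_recording()]s `train` and `test` and
#'   the `manifest` (seed, rate, split) for exact regeneration.
#' @export
generate_dataset <- function(spec, profile = NULL, train_series = 3,
                             test_series = 1) {
  stopifnot(inherits(spec, "series_spec"))
  if (train_series + test_series > spec$n_series)
    stop("train_series + test_series exceeds the number of series")
  if (is.null(profile)) profile <- make_gesture_profiles(seed = spec$seed)
  recs <- lapply(seq_len(spec$n_series), function(s)
    generate_recording(profile, spec, series = s))
  concat <- function(rs) {
    emg_recording(do.call(cbind, lapply(rs, `[[`, "signal")),
                  spec$sample_rate,
                  unlist(lapply(rs, `[[`, "labels")))
  }
  list(train = concat(recs[seq_len(train_series)]),
       test = concat(recs[train_series + seq_len(test_series)]),
       manifest = list(seed = spec$seed, sample_rate = spec$sample_rate,
                       n_series = spec$n_series,
                       train_series = seq_len(train_series),
                       test_series = train_series + seq_len(test_series)))
}

#' Write a generation manifest
#'
#' JSON manifest (seed, profile, spec) sufficient to regenerate a dataset
#' exactly.
#'
#' @param manifest the `manifest` element of [generate_dataset()].
#' @param file output path.
#' @return Invisibly, `file`.
#' @export
write_manifest <- function(manifest, file) {
  jsonlite::write_json(manifest, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file)
}
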