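#' Lateral-coupling parameters of the sensory layer
#'
#' Each electrode channel drives one sensory spiking neuron with the
#' rectified, scaled signal `k * |EMG(t)|`, and every sensory neuron
#' receives the weighted synaptic outputs of all the others:
#' `I = sum_i w * g_i * y_i(t) + k * |EMG(t)|`, with `g_i` negative when the
#' connections are inhibitory. `g` is stored as a magnitude and the
#' `inhibitory` flag applies the sign.
#'
#' @param w connection weight (dimensionless), default 0.5.
#' @param g output-current scaling magnitude (model current units),
#'   default 60.
#' @param inhibitory logical; if `TRUE` (default) the applied coefficient is
#'   `-g`.
#' @param k stimulator gain mapping volts of rectified sEMG to model
#'   current, default `2e6`.
#' @return An object of class `coupling_params`.
#' @export
coupling_params <- function(w = 0.5, g = 60, inhibitory = TRUE, k = 2e6) {
  if (w < 0) stop("w must be >= 0")
  if (g < 0) stop("g must be >= 0 (the sign comes from 'inhibitory')")
  if (k <= 0) stop("k must be > 0")
  structure(list(w = w, g = g, inhibitory = isTRUE(inhibitory), k = k),
            class = "coupling_params")
}

#' Stimulator plus synaptic drive current for one sensory neuron
#'
#' @param emg_sample instantaneous sEMG value (volts); rectified internally.
#' @param y_others synaptic outputs `y` of the other sensory neurons
#'   (numeric vector, possibly empty).
#' @param params a [coupling_params()].
#' @return The total input current (model units).
#' @examples
#' drive_current(5e-5, numeric(0), coupling_params()) # 100
#' @export
drive_current <- function(emg_sample, y_others, params) {
  stopifnot(inherits(params, "coupling_params"))
  if (!is.finite(emg_sample)) stop("emg_sample is not finite")
  g_signed <- if (params$inhibitory) -params$g else params$g
  sum(params$w * g_signed * y_others) + params$k * abs(emg_sample)
}

#' Construct a sensory layer
#'
#' One Izhikevich neuron plus one Tsodyks-Markram synapse per sEMG channel,
#' all-to-all laterally coupled (by default inhibitory). Neurons start at
#' their resting state and synapses at the empty state `(1, 0, 0, 0)`.
#'
#' @param n_channels number of channels (default 8).
#' @param neuron a [neuron_params()] (default RS preset).
#' @param synapse a [synapse_params()] (default feature-extractor preset).
#' @param coupling a [coupling_params()].
#' @return An object of class `sensory_layer` holding per-channel states.
#' @export
sensory_layer <- function(n_channels = 8, neuron = neuron_params(),
                          synapse = synapse_params(),
                          coupling = coupling_params()) {
  if (n_channels < 1) stop("n_channels must be >= 1")
  rest <- resting_state(neuron)
  structure(list(
    n_channels = n_channels, neuron = neuron, synapse = synapse,
    coupling = coupling,
    neurons = replicate(n_channels, rest, simplify = FALSE),
    synapses = replicate(n_channels, synapse_state(), simplify = FALSE)
  ), class = "sensory_layer")
}

#' Advance the whole sensory layer by one integration step
#'
#' The drive of every channel is computed from the *previous* step's
#' synaptic outputs (synchronous update, so the result is independent of
#' channel ordering); each neuron is then stepped, and its spike, if any,
#' feeds its own synapse's event map.
#'
#' @param layer a [sensory_layer()].
#' @param emg_samples one instantaneous sEMG value (volts) per channel.
#' @param dt integration step (ms).
#' @return The advanced `sensory_layer`, with attribute `spiked` (logical
#'   per channel).
#' @export
step_layer <- function(layer, emg_samples, dt) {
  stopifnot(inherits(layer, "sensory_layer"))
  if (length(emg_samples) != layer$n_channels)
    stop("emg_samples length (", length(emg_samples),
         ") does not match channel count (", layer$n_channels, ")")
  y_prev <- vapply(layer$synapses, `[[`, numeric(1), "y")
  spiked <- logical(layer$n_channels)
  for (i in seq_len(layer$n_channels)) {
    I <- drive_current(emg_samples[i], y_prev[-i], layer$coupling)
    st <- step_neuron(layer$neurons[[i]], layer$neuron, I, dt)
    layer$neurons[[i]] <- st$state
    spiked[i] <- st$spiked
    layer$synapses[[i]] <- step_synapse(layer$synapses[[i]], layer$synapse,
                                        dt, spike = st$spiked)
  }
  attr(layer, "spiked") <- spiked
  layer
}

#' Run the sensory layer over a full recording
#'
#' Zero-order-holds each sEMG sample over the neuron integration steps,
#' integrates all channels, and samples the instantaneous synaptic outputs
#' `y` every `feature_period` ms. In `"isolated"` mode the lateral coupling
#' is dropped (each neuron sees only its own channel); `"inhibitory"` mode
#' applies the mutual inhibition.
#'
#' @param recording an [emg_recording()].
#' @param mode `"inhibitory"` or `"isolated"`.
#' @param feature_period feature sampling period (ms), default 50.
#' @param dt neuron integration step (ms), default 0.5. The sampling
#'   interval `1000 / sample_rate` must be an integer multiple of `dt`.
#' @param neuron,synapse,coupling parameter objects (see
#'   [sensory_layer()]).
#' @return A list with `features` (rows = feature instants, cols =
#'   channels), `spike_counts` (per channel), and `t_ms` (feature instants,
#'   multiples of `feature_period`).
#' @export
simulate_sensory_layer <- function(recording,
                                   mode = c("inhibitory", "isolated"),
                                   feature_period = 50, dt = 0.5,
                                   neuron = neuron_params(),
                                   synapse = synapse_params(),
                                   coupling = coupling_params()) {
  stopifnot(inherits(recording, "emg_recording"))
  mode <- match.arg(mode)
  interval_ms <- 1000 / recording$sample_rate
  hold <- interval_ms / dt
  if (abs(hold - round(hold)) > 1e-9)
    stop("1000/sample_rate must be an integer multiple of dt")
  hold <- as.integer(round(hold))
  stride <- feature_period / dt
  if (abs(stride - round(stride)) > 1e-9)
    stop("feature_period must be an integer multiple of dt")
  stride <- as.integer(round(stride))
  g_signed <- if (coupling$inhibitory) -coupling$g else coupling$g
  cc <- if (mode == "isolated") 0 else coupling$w * g_signed
  res <- layer_simulate_cpp(recording$signal, hold, dt,
                            neuron$a, neuron$b, neuron$c, neuron$d,
                            neuron$v_peak,
                            synapse$U, synapse$tau_rec, synapse$tau_I,
                            synapse$tau_facil,
                            coupling$k, cc, stride)
  n_feat <- nrow(res$features)
  list(features = res$features, spike_counts = res$spike_counts,
       t_ms = seq_len(n_feat) * feature_period)
}

#' Extract spiking-network features from a recording
#'
#' The feature vector at each 50 ms instant is the instantaneous synaptic
#' output `y` of every channel's sensory neuron (not a window average). Each
#' row carries the gesture label active at that instant.
#'
#' @inheritParams simulate_sensory_layer
#' @return A `feature_matrix` data.frame: `t_ms`, `f1..fN`, `label`
#'   (NA when the recording is unlabelled). Row count is
#'   `floor(duration / feature_period)`.
#' @export
extract_spiking_features <- function(recording,
                                     feature_period = 50,
                                     mode = c("inhibitory", "isolated"),
                                     dt = 0.5,
                                     neuron = neuron_params(),
                                     synapse = synapse_params(),
                                     coupling = coupling_params()) {
  mode <- match.arg(mode)
  if (recording_duration_ms(recording) < feature_period) {
    warning("recording shorter than one feature period; empty feature matrix")
    return(empty_feature_matrix(nrow(recording$signal)))
  }
  sim <- simulate_sensory_layer(recording, mode, feature_period, dt,
                                neuron, synapse, coupling)
  labels <- if (is.null(recording$labels)) {
    rep(NA_integer_, length(sim$t_ms))
  } else {
    idx <- pmin(round(sim$t_ms / 1000 * recording$sample_rate),
                ncol(recording$signal))
    recording$labels[idx]
  }
  make_feature_matrix(sim$t_ms, sim$features, labels)
}
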