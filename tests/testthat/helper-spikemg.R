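# Shared fixtures and independent oracles.

rs_params <- function() neuron_params() # regular-spiking preset

fig_synapse <- function() synapse_params(U = 0.5, tau_rec = 100,
                                         tau_I = 10, tau_facil = 1000)

# Independent oracle for the inter-event TM dynamics: numeric matrix
# exponential of the linear system in (x, y, z, u_f). Used to check the
# stepped implementation without sharing its analytic decay formulas.
tm_drift_matrix <- function(params) {
  rbind(c(0, 0, 1 / params$tau_rec, 0),
        c(0, -1 / params$tau_I, 0, 0),
        c(0, 1 / params$tau_I, -1 / params$tau_rec, 0),
        c(0, 0, 0, -1 / params$tau_facil))
}

tm_expm_propagate <- function(state_vec, params, t) {
  as.numeric(Matrix::expm(tm_drift_matrix(params) * t) %*% state_vec)
}

# Event-by-event closed-form oracle: propagate between spikes with expm,
# apply the event map at each spike. Returns pre-event states and the
# per-spike release amplitudes.
tm_event_oracle <- function(spike_times, params, state0 = c(1, 0, 0, 0)) {
  s <- state0
  t_prev <- 0
  jumps <- numeric(length(spike_times))
  pre_uf <- numeric(length(spike_times))
  for (i in seq_along(spike_times)) {
    s <- tm_expm_propagate(s, params, spike_times[i] - t_prev)
    pre_uf[i] <- s[4]
    uf <- s[4] + params$U * (1 - s[4])
    rel <- uf * s[1]
    jumps[i] <- rel
    s <- c(s[1] - rel, s[2] + rel, s[3], uf)
    t_prev <- spike_times[i]
  }
  list(jumps = jumps, pre_uf = pre_uf, state = s)
}

# Small band-limited test recording: channels in `active` carry amplitude
# `amp` Gaussian noise, everything shares a common-mode term of amplitude
# `cm`; deterministic under `seed`.
make_test_recording <- function(duration_s = 2, rate = 400, n_channels = 8,
                                active = integer(0), amp = 8e-5,
                                cm = 0, seed = 42, labels = NULL) {
  n <- as.integer(duration_s * rate)
  withr::with_seed(seed, {
    sig <- matrix(0, n_channels, n)
    shared <- cm * stats::rnorm(n)
    for (i in seq_len(n_channels)) {
      sig[i, ] <- shared + if (i %in% active) amp * stats::rnorm(n) else 0
    }
    emg_recording(sig, rate, labels)
  })
}

# A light synthetic dataset for structural pipeline tests (NOT the study
# conditions used by the acceptance suite).
light_dataset <- function(seed = 7, rate = 400) {
  profile <- make_gesture_profiles(seed = seed)
  profile$duration_range <- c(0.8, 1.0)
  spec <- series_spec(n_series = 2, sample_rate = rate, seed = seed,
                      rest_s = 0.6)
  generate_dataset(spec, profile, train_series = 1, test_series = 1)
}

# Heavy end-to-end results shared by the acceptance blocks, computed once
# per test run under the standard study conditions (9 gestures x 4 series,
# 3/1 split, seed 1).
.acceptance_cache <- new.env(parent = emptyenv())

acceptance_e2e <- function() {
  if (is.null(.acceptance_cache$res)) {
    ds400 <- generate_dataset(series_spec(sample_rate = 400, seed = 1))
    cmp400 <- compare_extractors(pipeline_config("spiking_inhibitory",
                                                 sample_rate = 400,
                                                 seed = 1), ds400)
    ds2000 <- generate_dataset(series_spec(sample_rate = 2000, seed = 1))
    cfg2000 <- pipeline_config("spiking_inhibitory", sample_rate = 2000,
                               seed = 1)
    sp2000 <- run_training_pipeline(cfg2000, ds2000)
    .acceptance_cache$res <- list(cmp400 = cmp400, sp2000 = sp2000)
  }
  .acceptance_cache$res
}
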