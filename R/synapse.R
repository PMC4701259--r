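#' Tsodyks-Markram synapse parameters
#'
#' Short-term plasticity parameters: a unit synaptic resource is partitioned
#' into recovered (`x`), active (`y`) and inactivated (`z`) fractions, with a
#' utilization variable `u_f` producing frequency-dependent facilitation and
#' depression. Defaults are the feature-extractor preset used by the sensory
#' layer (U = 0.05, tau_rec = 1 ms, tau_I = 200 ms, tau_facil = 1 ms), under
#' which the synapse degenerates to a leaky spike integrator with a 200 ms
#' decay: each spike releases ~U of the (instantly recovered) resource into
#' `y`, which then decays slowly. That slow `y` is the classifier feature.
#'
#' @param U baseline utilization fraction, in (0, 1].
#' @param tau_rec recovery time constant (ms): inactivated -> recovered.
#' @param tau_I inactivation time constant (ms): active -> inactivated.
#' @param tau_facil facilitation decay time constant (ms).
#' @return An object of class `synapse_params`.
#' @export
synapse_params <- function(U = 0.05, tau_rec = 1, tau_I = 200,
                           tau_facil = 1) {
  if (!(U > 0 && U <= 1)) stop("U must lie in (0, 1]")
  if (tau_rec <= 0 || tau_I <= 0 || tau_facil <= 0)
    stop("all synaptic time constants must be > 0")
  structure(list(U = U, tau_rec = tau_rec, tau_I = tau_I,
                 tau_facil = tau_facil),
            class = "synapse_params")
}

#' Synapse state
#'
#' Resource fractions `x` (recovered), `y` (active), `z` (inactivated) and
#' facilitation variable `u_f`. The three resource pools are conserved:
#' `x + y + z = 1`.
#'
#' @param x,y,z resource fractions in \[0, 1\], summing to 1.
#' @param u_f utilization/facilitation variable in \[0, 1\].
#' @return An object of class `synapse_state`.
#' @export
synapse_state <- function(x = 1, y = 0, z = 0, u_f = 0) {
  vals <- c(x = x, y = y, z = z, u_f = u_f)
  if (any(!is.finite(vals))) stop("synapse state rejected: non-finite value")
  if (any(vals < -1e-9) || any(vals > 1 + 1e-9))
    stop("synapse state rejected: components must lie in [0, 1]")
  if (abs(x + y + z - 1) > 1e-6)
    stop("synapse state rejected: x + y + z must equal 1 (within 1e-6)")
  structure(list(x = x, y = y, z = z, u_f = u_f), class = "synapse_state")
}

#' Advance the synapse by one step
#'
#' If `spike` is set, the event map is applied first -- the utilization jump
#' `u_f <- u_f + U (1 - u_f)` followed by the resource transfer of
#' `u_f * x` from the recovered to the active pool. The continuous dynamics
#' (`dx/dt = z/tau_rec`, `dy/dt = -y/tau_I`, `dz/dt = y/tau_I - z/tau_rec`,
#' `du_f/dt = -u_f/tau_facil`) are linear between events, so they are then
#' advanced by `dt` with their exact propagator (the standard event-driven
#' treatment of this model): `y` and `u_f` decay exponentially, `z` follows
#' the two-exponential convolution of the `y` inflow, and `x` absorbs the
#' balance, which conserves `x + y + z` by construction.
#'
#' @param state a [synapse_state()].
#' @param params a [synapse_params()].
#' @param dt time step (ms).
#' @param spike logical; did the presynaptic neuron fire on this step?
#' @return The advanced [synapse_state()].
#' @export
step_synapse <- function(state, params, dt, spike = FALSE) {
  stopifnot(inherits(state, "synapse_state"),
            inherits(params, "synapse_params"))
  if (dt <= 0) stop("dt must be > 0")
  x <- state$x; y <- state$y; z <- state$z; u_f <- state$u_f
  if (isTRUE(spike)) {
    u_f <- u_f + params$U * (1 - u_f)
    rel <- u_f * x
    x <- x - rel
    y <- y + rel
  }
  ey <- exp(-dt / params$tau_I)
  er <- exp(-dt / params$tau_rec)
  kd <- 1 / params$tau_rec - 1 / params$tau_I
  cyz <- if (abs(kd) < 1e-12) {
    # tau_I == tau_rec limit: inflow term t/tau * exp(-t/tau)
    (dt / params$tau_I) * er
  } else {
    (1 / params$tau_I) * (ey - er) / kd
  }
  y1 <- y * ey
  z1 <- z * er + y * cyz
  x1 <- x + (y + z - y1 - z1)
  synapse_state(x1, y1, z1, u_f * exp(-dt / params$tau_facil))
}

#' Simulate the synapse under a presynaptic spike train
#'
#' Integrates the Tsodyks-Markram dynamics over `[0, T]` with spikes at the
#' given times (each snapped to the nearest integration step). The active
#' fraction `y(t)` is the synaptic output signal; the per-spike response
#' amplitude is the jump in `y` at each event, which decreases with
#' high-frequency drive (depression) and whose utilization `u_f` builds up
#' under sustained low-frequency drive when `tau_facil` is long
#' (facilitation).
#'
#' @param spike_times spike times (ms), strictly increasing, within
#'   `[0, T]`.
#' @param params a [synapse_params()].
#' @param dt integration step (ms), default 0.1.
#' @param T total duration (ms).
#' @param init initial [synapse_state()]; default `(1, 0, 0, 0)`.
#' @return A data.frame with columns `time_ms`, `x`, `y`, `z`, `u_f`,
#'   sampled every `dt`, plus attributes `spike_steps` (the step indices the
#'   events were applied on) and `y_jumps` (the per-spike release
#'   amplitudes `u_f * x` actually transferred).
#' @export
simulate_synapse <- function(spike_times, params, dt = 0.1, T,
                             init = synapse_state()) {
  stopifnot(inherits(params, "synapse_params"))
  if (length(spike_times) > 1 && any(diff(spike_times) <= 0))
    stop("spike_times must be strictly increasing")
  if (length(spike_times) > 0 &&
      (min(spike_times) < 0 || max(spike_times) > T))
    stop("spike_times must lie within [0, T]")
  n_steps <- as.integer(round(T / dt))
  steps <- as.integer(pmax(1, round(spike_times / dt)))
  res <- tm_simulate_cpp(steps, n_steps, dt, params$U, params$tau_rec,
                         params$tau_I, params$tau_facil,
                         init$x, init$y, init$z, init$u_f)
  out <- data.frame(time_ms = seq_len(n_steps) * dt,
                    x = res$x, y = res$y, z = res$z, u_f = res$u_f)
  # reconstruct per-event jumps by replaying the event maps on the stored
  # pre-step states
  jumps <- numeric(length(steps))
  if (length(steps) > 0) {
    for (i in seq_along(steps)) {
      s <- steps[i]
      if (s == 1) {
        xs <- init$x; us <- init$u_f
      } else {
        xs <- res$x[s - 1]; us <- res$u_f[s - 1]
      }
      us2 <- us + params$U * (1 - us)
      jumps[i] <- us2 * xs
    }
  }
  attr(out, "spike_steps") <- steps
  attr(out, "y_jumps") <- jumps
  out
}

#' Export a synaptic output trace to CSV
#'
#' @param sim result of [simulate_synapse()].
#' @param file output path; two columns `time_ms,y`.
#' @return Invisibly, `file`.
#' @export
write_synapse_csv <- function(sim, file) {
  utils::write.csv(data.frame(time_ms = sim$time_ms, y = sim$y), file,
                   row.names = FALSE)
  invisible(file)
}
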