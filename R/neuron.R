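#' Izhikevich neuron parameters
#'
#' Parameter set for the two-variable quadratic integrate-and-fire model
#' with after-spike reset. The defaults are the "regular spiking" (RS)
#' cortical preset, the firing regime used throughout the sensory layer.
#'
#' @param a recovery time-scale (1/ms).
#' @param b recovery sensitivity (dimensionless).
#' @param c after-spike reset potential (mV).
#' @param d after-spike recovery increment.
#' @param v_peak spike cut-off threshold (mV). Fixed at 30 mV in the model
#'   definition; exposed for completeness.
#' @return An object of class `neuron_params`.
#' @examples
#' p <- neuron_params() # RS preset: a=0.02, b=0.2, c=-65, d=8
#' resting_state(p)
#' @export
neuron_params <- function(a = 0.02, b = 0.2, c = -65, d = 8, v_peak = 30) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c), is.numeric(d))
  if (!is.finite(a) || a <= 0) stop("'a' must be finite and > 0")
  if (v_peak <= c) stop("'v_peak' must exceed the reset potential 'c'")
  structure(list(a = a, b = b, c = c, d = d, v_peak = v_peak),
            class = "neuron_params")
}

#' Neuron state
#'
#' Membrane potential `V` (mV) and recovery variable `u` of one Izhikevich
#' unit.
#'
#' @param V membrane potential (mV).
#' @param u recovery variable.
#' @return An object of class `neuron_state`.
#' @export
neuron_state <- function(V, u) {
  if (!is.finite(V)) stop("neuron state rejected: V is not finite")
  if (!is.finite(u)) stop("neuron state rejected: u is not finite")
  structure(list(V = V, u = u), class = "neuron_state")
}

#' Resting state of the neuron
#'
#' Stable fixed point of the subthreshold dynamics at zero input, i.e. the
#' intersection of the nullclines `0.04 V^2 + 5 V + 140 - u = 0` and
#' `u = b V`. Solving the quadratic `0.04 V^2 + (5 - b) V + 140 = 0` gives
#' two candidate potentials; the stable one (negative trace, positive
#' determinant of the Jacobian) is returned and used as the canonical
#' initial condition for all simulations.
#'
#' @param params a [neuron_params()] object.
#' @return A [neuron_state()] at the stable fixed point. For the RS preset
#'   this is `V = -70`, `u = -14`.
#' @export
resting_state <- function(params) {
  stopifnot(inherits(params, "neuron_params"))
  A <- 0.04; B <- 5 - params$b; C <- 140
  disc <- B^2 - 4 * A * C
  if (disc < 0) stop("no resting state: nullclines do not intersect at I = 0")
  roots <- c((-B - sqrt(disc)) / (2 * A), (-B + sqrt(disc)) / (2 * A))
  for (V in roots) {
    # Jacobian of (dV/dt, du/dt) at (V, bV)
    tr <- (0.08 * V + 5) - params$a
    det <- -params$a * (0.08 * V + 5) + params$a * params$b
    if (tr < 0 && det > 0) return(neuron_state(V, params$b * V))
  }
  stop("no resting state: no stable fixed point for this parameter set")
}

#' Advance the neuron by one Euler step
#'
#' Explicit Euler update of `dV/dt = 0.04 V^2 + 5 V + 140 - u + I` and
#' `du/dt = a (b V - u)`, followed by the after-spike rule: if the updated
#' `V` has reached `v_peak` (30 mV), the step is flagged as a spike and the
#' state is reset to `V = c`, `u = u + d`.
#'
#' @param state a [neuron_state()].
#' @param params a [neuron_params()].
#' @param I applied current (model drive units, dimensionless).
#' @param dt time step (ms); must be positive and at most 1 ms for the
#'   explicit scheme to stay in its stable regime.
#' @return A list with elements `state` (the advanced [neuron_state()]) and
#'   `spiked` (logical).
#' @export
step_neuron <- function(state, params, I, dt) {
  stopifnot(inherits(state, "neuron_state"), inherits(params, "neuron_params"))
  if (!is.finite(I)) stop("step_neuron rejected: input current I is not finite")
  if (!is.finite(state$V)) stop("step_neuron rejected: V is not finite")
  if (!is.finite(state$u)) stop("step_neuron rejected: u is not finite")
  if (dt <= 0 || dt > 1) stop("dt must satisfy 0 < dt <= 1 ms")
  V1 <- state$V + dt * (0.04 * state$V^2 + 5 * state$V + 140 - state$u + I)
  u1 <- state$u + dt * params$a * (params$b * state$V - state$u)
  if (V1 >= params$v_peak) {
    list(state = neuron_state(params$c, u1 + params$d), spiked = TRUE)
  } else {
    list(state = neuron_state(V1, u1), spiked = FALSE)
  }
}

#' Simulate the neuron along a current trace
#'
#' Integrates the neuron with explicit Euler under a piecewise-constant
#' (zero-order-held) input current. Each input sample is held for
#' `sample_interval / dt` integration steps. At spike steps the recorded
#' trace stores the clipped peak `v_peak` rather than the Euler overshoot,
#' so plotted spikes reach 30 mV reproducibly regardless of dt.
#'
#' @param I_trace numeric vector of input current samples.
#' @param params a [neuron_params()].
#' @param dt integration step (ms), default 0.5.
#' @param sample_interval spacing of `I_trace` samples (ms); must be a
#'   positive integer multiple of `dt`. Defaults to `dt` (one sample per
#'   step).
#' @param init initial [neuron_state()]; defaults to [resting_state()].
#' @return A list with `time_ms`, `V` (the membrane trace sampled every
#'   `dt`), and `spike_times` (ms, strictly increasing).
#' @export
simulate_neuron <- function(I_trace, params, dt = 0.5,
                            sample_interval = dt, init = NULL) {
  stopifnot(inherits(params, "neuron_params"))
  if (length(I_trace) == 0) {
    return(list(time_ms = numeric(0), V = numeric(0),
                spike_times = numeric(0)))
  }
  if (any(!is.finite(I_trace)))
    stop("simulate_neuron rejected: I_trace contains non-finite values")
  hold <- sample_interval / dt
  if (abs(hold - round(hold)) > 1e-9)
    stop("sample_interval must be an integer multiple of dt")
  hold <- as.integer(round(hold))
  if (is.null(init)) init <- resting_state(params)
  I_held <- rep(I_trace, each = hold)
  res <- iz_simulate_cpp(I_held, dt, params$a, params$b, params$c, params$d,
                         params$v_peak, init$V, init$u)
  list(time_ms = seq_along(I_held) * dt, V = res$V,
       spike_times = res$spike_times)
}

#' Export a membrane trace or spike times to CSV
#'
#' @param sim result of [simulate_neuron()].
#' @param trace_file path for the two-column trace CSV (`time_ms,V_mV`), or
#'   `NULL` to skip.
#' @param spikes_file path for the one-column spike-time CSV, or `NULL`.
#' @return Invisibly, the paths written.
#' @export
write_neuron_csv <- function(sim, trace_file = NULL, spikes_file = NULL) {
  if (!is.null(trace_file)) {
    utils::write.csv(data.frame(time_ms = sim$time_ms, V_mV = sim$V),
                     trace_file, row.names = FALSE)
  }
  if (!is.null(spikes_file)) {
    utils::write.csv(data.frame(spike_time_ms = sim$spike_times),
                     spikes_file, row.names = FALSE)
  }
  invisible(c(trace_file, spikes_file))
}
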