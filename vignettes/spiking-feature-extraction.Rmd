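---
title: "Spiking-network feature extraction for sEMG gesture recognition: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spiking-network feature extraction for sEMG gesture recognition: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikemg)
```

# The problem

Multichannel surface electromyography (sEMG) recorded around the forearm
carries enough information to recognise static hand gestures and drive
human–machine interfaces. The classical streaming recipe segments each
channel into overlapping windows, summarises every window with its root
mean square (RMS) — a proxy for contraction amplitude — and feeds the
per-channel RMS vector to a classifier. `spikemg` implements that baseline
and an alternative, biologically grounded feature extractor: a layer of
spiking *sensory neurons*, one per electrode, coupled by mutual lateral
inhibition, whose short-term-plasticity synaptic output is sampled at a low
rate and classified by the same small sigmoid network. The package's claim
of interest is comparative: the spiking features classify gestures about as
well as RMS, while suppressing in-phase (common-mode) activity that carries
no pattern information.

# The sensory neuron

Each channel drives one Izhikevich neuron,

$$\frac{dV}{dt} = 0.04V^2 + 5V + 140 - u + I,\qquad
  \frac{du}{dt} = a(bV - u),$$

with the after-spike rule: when $V \ge 30$ mV, a spike is registered and
$V \leftarrow c$, $u \leftarrow u + d$. Throughout the package the
*regular spiking* preset $a = 0.02$, $b = 0.2$, $c = -65$, $d = 8$ is the
default — tonic firing with spike-frequency adaptation, the generic
cortical regime. `resting_state()` returns the stable nullcline
intersection ($V^* = -70$, $u^* = -14$ for this preset), the canonical
initial condition.

Numerical choices:

* **Explicit Euler, default `dt = 0.5` ms.** This is the scheme the model
  was designed for; its quadratic spike upstroke makes higher-order
  schemes pointless next to the discontinuous reset. `dt` is exposed
  everywhere.
* **Spike detection after the update.** The threshold test runs on the
  updated $V$; the spike is stamped at the step's end time, then the reset
  applies. Recorded traces store the clipped peak (30 mV) rather than the
  Euler overshoot so plots are `dt`-independent.
* **Convergence.** Euler spike times drift linearly in `dt` (about
  25·`dt` ms over a one-second tonic run at $I = 10$), so step-refinement
  checks are run in the dense-step regime (0.02 ms halved to 0.01 ms,
  where all spike times agree to better than 1 ms); at the working
  `dt = 0.5` ms the spike count and the adaptation structure are already
  exact, which is what the feature extractor consumes.

# The synaptic output

The feature itself is not the spike train but the active-resource fraction
$y(t)$ of a Tsodyks–Markram synapse driven by it. A unit resource is split
into recovered $x$, active $y$ and inactivated $z$ pools,

$$\dot x = z/\tau_{rec}, \quad
  \dot y = -y/\tau_I, \quad
  \dot z = y/\tau_I - z/\tau_{rec}, \quad
  \dot u_f = -u_f/\tau_{facil},$$

and each presynaptic spike applies the event map
$u_f \leftarrow u_f + U(1 - u_f)$ followed by the transfer of $u_f\,x$
from $x$ to $y$ (facilitation update first, then release — the standard
event convention). This reproduces both canonical regimes: depression at
high rates ($x$ cannot recover between spikes) and facilitation at low
rates when $\tau_{facil}$ is long.

Between events the system is linear, so the continuous part is advanced
with its **exact per-step propagator** ($y$ and $u_f$ decay exponentially,
$z$ receives the convolved $y$ inflow, and $x$ absorbs the balance). This
conserves $x + y + z = 1$ to machine precision by construction and matches
the matrix-exponential solution of the inter-spike dynamics to rounding
error — the property the test suite checks against an independent
`Matrix::expm` oracle.

With the feature-extractor preset ($U = 0.05$, $\tau_{rec} = 1$ ms,
$\tau_I = 200$ ms, $\tau_{facil} = 1$ ms) the synapse deliberately
degenerates into a leaky spike integrator: $x$ recovers within about a
millisecond and $u_f$ resets between spikes, so every spike adds roughly
$U(1 - y)$ to a $y$ that decays with a 200 ms constant. $y(t)$ is then a
smooth, bounded firing-rate code — exactly what a 50 ms classifier wants.

# The laterally inhibited layer

Each sensory neuron's input current is

$$I = \sum_i w\,g_i\,y_i(t) + k\,\lvert \mathrm{EMG}(t)\rvert,$$

rectified channel signal scaled by the stimulator gain $k$ plus the
weighted synaptic outputs of every *other* channel. All connections are
inhibitory ($g_i < 0$); the package stores the magnitude $g$ with an
`inhibitory` flag. Defaults: $w = 0.5$, $g = 60$, $k = 2\times 10^6$
(volts to model current). Two modes exist: *isolated* (no coupling, each
neuron sees only its own channel) and *inhibitory*.

Implementation decisions:

* sEMG samples are zero-order-held across integration steps, so the
  400 Hz (2.5 ms/sample) and 2000 Hz (0.5 ms/sample) pipelines share one
  code path.
* $I_{syn}$ uses the *previous* step's $y$ values (synchronous update), so
  results cannot depend on channel ordering.
* A neuron's own spike feeds its own synapse; the same $y$ is both the
  inhibitory signal sent to neighbours and the classifier feature.
* The feature is the instantaneous $y$ at each 50 ms instant, not a window
  average.

With these defaults a gesture-scale input ($\sim 5\times10^{-5}$ V RMS,
hence drive $\sim 100$) produces vigorous spiking and $y \approx 0.3$–$0.8$,
while rest-scale noise ($\sim 5\times10^{-6}$ V) leaves neurons near
threshold. In inhibitory mode that residual background activity is
actively suppressed — the layer's contrast-enhancement role — and
common-mode input inflates the features far less than in isolated mode,
because in-phase activity inhibits itself symmetrically.

# The RMS baseline

`extract_rms_features()` applies the classical geometry: 100 ms windows
advanced every 50 ms, specified in milliseconds and converted to samples
(40/20 samples at 400 Hz, 200/100 at 2000 Hz), RMS per channel per window,
trailing incomplete windows dropped. Window labels are the majority label
inside the window, ties toward the smaller class index; timestamps are
window-end times so both extractors emit rows on the same 50 ms grid and
one classifier serves both.

# The classifier

A deliberately small fully connected sigmoid network: 8 inputs, one hidden
layer of 9, one output unit per gesture class (9), trained by
backpropagation on mean squared error against one-hot targets, learning
rate 0.01, at most 4000 epochs. After each epoch the held-out error is
computed; training stops once it has not improved for 50 epochs
(`patience`), and the best-epoch snapshot is returned. The class readout
is the arg-max output unit, ties toward the lowest index.

Two training regimes are provided. The default is **online** (per-sample
updates in data order): with a fixed learning rate of 0.01 this is the
regime in which the 1000–4000-epoch budget actually converges, and it is
the convention of the small homegrown backprop implementations this
architecture descends from. The **batch** alternative (one mean-gradient
step per epoch) is retained as a configuration switch and for exact
gradient analysis; at the same learning rate it advances roughly
`n_samples` times slower per epoch, which is why it is not the default.
The compiled online loop is cross-checked in the tests against an R
per-sample reference to machine precision, and the analytic gradients
against central finite differences.

Feature columns are min–max normalised to $[0,1]$ on *training-set*
ranges before training; the fitted ranges travel with the serialized model
so streaming classification applies the identical affine map. This is
required for fairness of the extractor comparison: raw RMS features live
at $10^{-4}$ V scale while synaptic outputs live at $10^{-1}$, and a
fixed-learning-rate sigmoid network is not scale-invariant.

# The synthetic protocol

Real recordings from the two wireless acquisition systems the pipeline
targets are not shipped, so `make_gesture_profiles()` /
`generate_dataset()` emulate the acquisition protocol: four series of nine
static gestures (class 1 = rest), each held 2–3 s in random order with
1.5 s relaxation gaps, eight channels, at 400 or 2000 Hz, split 3/1 into
train/test series.

The signal model per channel is amplitude-modulated Gaussian noise
band-passed to 20–150 Hz (the standard interference-pattern surrogate for
sEMG), with:

* a per-gesture activation matrix — each active gesture recruits three
  adjacent channels of the electrode ring with envelope amplitudes drawn
  once from $5\times10^{-5}$–$1.2\times10^{-4}$ V RMS, the scale at which
  $k = 2\times10^6$ puts neurons firmly in the spiking range (the voltage
  scale of the original recordings is not documented, so the generator is
  calibrated to make the published gain meaningful);
* an in-phase common-mode noise term ($5\times10^{-6}$ V RMS) added
  identically to every channel, included specifically so the benefit of
  lateral inhibition is testable;
* independent per-channel baseline noise ($2\times10^{-6}$ V RMS);
* 100 ms raised-cosine envelope ramps at gesture boundaries.

The protocol timeline is drawn in seconds before rendering, so one seed
produces the same gesture schedule at both sampling rates; only the noise
realisations differ. What the generator does **not** model: motor-unit
action potentials and recruitment, electrode lift and powerline artifacts,
inter-subject variability, and gesture-to-gesture co-articulation. Tests
passing on this generator therefore demonstrate that the pipeline's
machinery is correct and that its comparative claims hold under a clean,
separable signal model — not that the absolute accuracies transfer to any
particular human subject.

# Worked comparison

```{r, eval = FALSE}
ds <- generate_dataset(series_spec(sample_rate = 400, seed = 1))
cmp <- compare_extractors(pipeline_config("spiking_inhibitory", seed = 1), ds)
cmp$accuracies
#>      rms  spiking
#> 99.54407 97.72382
cmp$delta
#> [1] -1.820249
```

The paired design always trains and evaluates both extractors on the same
train/test recordings; `delta` is spiking minus RMS in percentage points.
`scripts/acceptance.R` repeats this comparison at both sampling rates from
a single seed.

# Problem sizes and runtime

The standard study conditions (four series, nine gestures, eight channels)
produce roughly 130 s of signal and ~2600 feature rows per dataset. One
full paired comparison — generation, two feature extractions, two
trainings to the 4000-epoch cap — takes on the order of ten seconds on a
single core, dominated by the compiled sensory-layer integration (0.5 ms
steps) and the online training loop. Unit tests run on much smaller
recordings; the end-to-end acceptance checks use the standard conditions
unchanged.

# Known limitations

* The neuron integrator is first-order; spike *times* at the working step
  carry an O(`dt`) phase drift (spike counts and rates are stable). Use a
  smaller `dt` where precise timing matters.
* Online training is order-dependent by construction; reproducibility is
  guaranteed for a fixed dataset and seed, not under row permutation.
* The min–max scaling is fitted on training features only; a test
  recording with radically larger amplitudes will extrapolate outside
  $[0,1]$ (the sigmoid saturates gracefully, but calibration drift is not
  modelled).
* With nine gestures the output layer size equals the hidden layer size
  by coincidence of the published architecture; both are configurable.
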