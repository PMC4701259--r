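# Sensory layer: drive current, lateral inhibition, decoupling identity and
# feature extraction.

test_that("drive current combines rectified input and inhibitory feedback", {
  cp <- coupling_params() # w = 0.5, g = 60 inhibitory, k = 2e6
  expect_identical(drive_current(0, numeric(0), cp), 0)
  expect_equal(drive_current(5e-5, numeric(0), cp), 100)
  expect_equal(drive_current(-5e-5, numeric(0), cp),
               drive_current(5e-5, numeric(0), cp))
  # each neighbour's y subtracts w*g*y from the drive
  expect_equal(drive_current(5e-5, c(0.2, 0.1), cp),
               100 - 0.5 * 60 * 0.3)
  cp_exc <- coupling_params(inhibitory = FALSE)
  expect_equal(drive_current(5e-5, c(0.2), cp_exc), 100 + 0.5 * 60 * 0.2)
})

test_that("stepping the layer validates channel count and stays silent at rest", {
  layer <- sensory_layer(n_channels = 4)
  expect_error(step_layer(layer, rep(0, 3), dt = 0.5), "channel count")
  for (i in 1:200) layer <- step_layer(layer, rep(0, 4), dt = 0.5)
  expect_true(all(vapply(layer$synapses, `[[`, numeric(1), "y") == 0))
  expect_false(any(attr(layer, "spiked")))
})

test_that("the R stepper and the compiled layer path agree", {
  rec <- make_test_recording(duration_s = 0.25, rate = 2000, n_channels = 3,
                             active = 1:3, amp = 6e-5, cm = 1e-5)
  sim <- simulate_sensory_layer(rec, "inhibitory", feature_period = 50,
                                dt = 0.5)
  layer <- sensory_layer(n_channels = 3)
  y_at <- matrix(NA_real_, 5, 3)
  for (s in seq_len(ncol(rec$signal))) {
    layer <- step_layer(layer, rec$signal[, s], dt = 0.5)
    t_ms <- s * 0.5
    if (t_ms %% 50 == 0)
      y_at[t_ms / 50, ] <- vapply(layer$synapses, `[[`, numeric(1), "y")
  }
  expect_equal(unname(sim$features), unname(y_at), tolerance = 1e-12)
})

test_that("zero coupling reproduces isolated single-channel runs bit-exactly", {
  rec <- make_test_recording(duration_s = 1, rate = 400, n_channels = 8,
                             active = c(2, 5), amp = 8e-5, cm = 5e-6)
  iso <- simulate_sensory_layer(rec, "isolated")
  w0 <- simulate_sensory_layer(rec, "inhibitory",
                               coupling = coupling_params(w = 0))
  expect_identical(w0$features, iso$features)
  expect_identical(w0$spike_counts, iso$spike_counts)
  # per-channel independent runs reproduce each isolated column
  for (ch in c(1, 2, 5)) {
    solo <- simulate_sensory_layer(
      emg_recording(rec$signal[ch, , drop = FALSE], rec$sample_rate),
      "isolated")
    expect_identical(solo$features[, 1], iso$features[, ch])
  }
})

test_that("mutual inhibition suppresses common-mode driven spiking", {
  # identical strong in-phase signal on all 8 channels for 5 s
  n <- 5 * 400
  shared <- withr::with_seed(11, 2.5e-5 * stats::rnorm(n))
  rec <- emg_recording(matrix(rep(shared, each = 8), nrow = 8), 400)
  iso <- simulate_sensory_layer(rec, "isolated")
  inh <- simulate_sensory_layer(rec, "inhibitory")
  expect_true(all(inh$spike_counts < iso$spike_counts))
  expect_gt(min(iso$spike_counts), 0)
})

test_that("in-phase input inflates isolated features more than inhibitory ones", {
  base <- make_test_recording(duration_s = 2, rate = 400, active = 3,
                              amp = 8e-5, cm = 0, seed = 5)
  shared <- withr::with_seed(6, 1.5e-5 * stats::rnorm(ncol(base$signal)))
  with_cm <- emg_recording(base$signal +
                             matrix(rep(shared, each = 8), nrow = 8), 400)
  gain <- function(mode) {
    mean(simulate_sensory_layer(with_cm, mode)$features) -
      mean(simulate_sensory_layer(base, mode)$features)
  }
  expect_gt(gain("isolated"), gain("inhibitory"))
})

test_that("feature extraction samples y on the 50 ms grid with labels", {
  labels <- rep(c(1L, 4L), each = 200)
  rec <- make_test_recording(duration_s = 1, rate = 400, active = 3,
                             amp = 8e-5, labels = labels)
  fm <- extract_spiking_features(rec, mode = "inhibitory")
  expect_s3_class(fm, "feature_matrix")
  expect_identical(nrow(fm), 20L) # floor(1000 / 50)
  expect_equal(fm$t_ms, seq(50, 1000, by = 50))
  expect_identical(fm$label, rep(c(1L, 4L), each = 10))
  # selective drive: the active channel dominates every other channel
  fv <- feature_values(fm)
  expect_true(all(mean(fv[, 3]) > colMeans(fv[, -3])))
  # all-zero recording gives all-zero features
  zero <- emg_recording(matrix(0, 8, 400), 400, labels)
  expect_true(all(feature_values(extract_spiking_features(zero)) == 0))
})

test_that("features are deterministic and invariant to signal negation", {
  rec <- make_test_recording(duration_s = 1, rate = 400, active = c(1, 6),
                             amp = 7e-5, cm = 4e-6)
  f1 <- extract_spiking_features(rec, mode = "inhibitory")
  f2 <- extract_spiking_features(rec, mode = "inhibitory")
  expect_identical(f1, f2)
  neg <- emg_recording(-rec$signal, rec$sample_rate)
  f3 <- extract_spiking_features(neg, mode = "inhibitory")
  expect_identical(feature_values(f3), feature_values(f1))
})

test_that("recordings shorter than one feature period yield an empty matrix", {
  rec <- make_test_recording(duration_s = 0.02, rate = 400)
  expect_warning(fm <- extract_spiking_features(rec), "shorter")
  expect_identical(nrow(fm), 0L)
})
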