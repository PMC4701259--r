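# Synthetic sEMG generator: gesture profiles, protocol structure, amplitude
# calibration and rate independence.

test_that("gesture profiles are reproducible, sparse and distinct", {
  p1 <- make_gesture_profiles(seed = 3)
  p2 <- make_gesture_profiles(seed = 3)
  p3 <- make_gesture_profiles(seed = 4)
  expect_identical(p1$amplitude, p2$amplitude)
  expect_false(identical(p1$amplitude, p3$amplitude))
  expect_true(all(p1$amplitude[1, ] == 0)) # rest class
  # every active gesture recruits exactly three channels in the assigned band
  active <- p1$amplitude[-1, ]
  expect_true(all(rowSums(active > 0) == 3))
  on <- active[active > 0]
  expect_true(all(on >= 5e-5 & on <= 1.2e-4))
  # pairwise distinct activation patterns
  d <- as.matrix(dist(p1$amplitude))
  expect_gt(min(d[upper.tri(d)]), 1e-6)
})

test_that("recordings follow the series protocol with aligned labels", {
  profile <- make_gesture_profiles(seed = 2)
  spec <- series_spec(sample_rate = 400, seed = 2)
  rec <- generate_recording(profile, spec, series = 1)
  expect_s3_class(rec, "emg_recording")
  expect_identical(sort(unique(rec$labels)), 1:9)
  expect_identical(length(rec$labels), ncol(rec$signal))
  # eight gestures of 2-3 s each plus nine 1.5 s rest gaps
  runs <- rle(rec$labels)
  g_runs <- runs$lengths[runs$values != 1] / 400
  expect_identical(length(g_runs), 8L)
  expect_true(all(g_runs >= 1.99 & g_runs <= 3.01))
  expect_true(all(runs$values[c(1, length(runs$values))] == 1))
  # reproducible; different series index gives a different ordering
  rec_b <- generate_recording(profile, spec, series = 1)
  expect_identical(rec$signal, rec_b$signal)
  rec2 <- generate_recording(profile, spec, series = 2)
  g_order <- function(r) rle(r$labels)$values
  expect_false(identical(g_order(rec), g_order(rec2)))
})

test_that("active-channel RMS matches the composed amplitude budget", {
  profile <- make_gesture_profiles(seed = 6)
  spec <- series_spec(sample_rate = 400, seed = 6)
  rec <- generate_recording(profile, spec, series = 1)
  for (g in c(3, 7)) {
    span <- which(rec$labels == g)
    span <- span[seq(round(length(span) * 0.2), round(length(span) * 0.8))]
    for (ch in which(profile$amplitude[g, ] > 0)) {
      expected <- sqrt(profile$amplitude[g, ch]^2 +
                         profile$common_mode_amp^2 + profile$baseline_amp^2)
      expect_equal(rms(rec$signal[ch, span]), expected, tolerance = 0.1)
    }
  }
  # rest spans are zero-mean noise: |mean| under 3 standard errors
  rest <- which(rec$labels == 1)
  for (ch in 1:8) {
    x <- rec$signal[ch, rest]
    expect_lt(abs(mean(x)), 3 * sd(x) / sqrt(length(x)))
  }
})

test_that("zero-amplitude profiles still carry labels over pure noise", {
  profile <- make_gesture_profiles(seed = 9)
  profile$amplitude[] <- 0
  rec <- generate_recording(profile, series_spec(seed = 9), series = 1)
  expect_identical(sort(unique(rec$labels)), 1:9)
  expect_lt(max(abs(rec$signal)),
            20 * (profile$common_mode_amp + profile$baseline_amp))
})

test_that("the same seed renders the same protocol at 400 and 2000 Hz", {
  profile <- make_gesture_profiles(seed = 5)
  r400 <- generate_recording(profile, series_spec(sample_rate = 400,
                                                  seed = 5), 1)
  r2000 <- generate_recording(profile, series_spec(sample_rate = 2000,
                                                   seed = 5), 1)
  # identical schedule in seconds
  runs4 <- rle(r400$labels)
  runs20 <- rle(r2000$labels)
  expect_identical(runs4$values, runs20$values)
  expect_equal(runs4$lengths / 400, runs20$lengths / 2000, tolerance = 0.01)
  # per-gesture RMS profiles agree within 5% on recruited channels
  for (g in 2:9) {
    for (ch in which(profile$amplitude[g, ] > 0)) {
      rms4 <- rms(r400$signal[ch, r400$labels == g])
      rms20 <- rms(r2000$signal[ch, r2000$labels == g])
      expect_equal(rms4, rms20, tolerance = 0.05)
    }
  }
})

test_that("the common-mode component is shared and the split is disjoint", {
  spec <- series_spec(sample_rate = 400, seed = 3)
  ds <- generate_dataset(spec)
  expect_identical(sort(unique(ds$train$labels)), 1:9)
  expect_identical(sort(unique(ds$test$labels)), 1:9)
  # 3/1 split of four series: test is about a third of train
  expect_equal(ncol(ds$train$signal) / ncol(ds$test$signal), 3,
               tolerance = 0.2)
  expect_error(generate_dataset(spec, train_series = 4, test_series = 1),
               "exceeds")
  # different seeds give different gesture orderings
  ds2 <- generate_dataset(series_spec(sample_rate = 400, seed = 4))
  expect_false(identical(rle(ds$train$labels)$values,
                         rle(ds2$train$labels)$values))
  f <- withr::local_tempfile(fileext = ".json")
  write_manifest(ds$manifest, f)
  expect_equal(jsonlite::read_json(f)$seed, 3)
})
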