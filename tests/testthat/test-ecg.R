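test_that("baseline removal attenuates drift and preserves the passband", {
  fs <- 100
  t <- seq(0, 60, by = 1 / fs)
  slow <- sin(2 * pi * 0.1 * t)
  out <- remove_baseline(uniform_signal(slow, fs), cutoff_hz = 0.5)
  mid <- seq(10 * fs, 50 * fs)  # avoid filter edge transients
  expect_lt(max(abs(out$values[mid])), 0.1)

  zero <- remove_baseline(uniform_signal(rep(0, 1000), fs), 0.5)
  expect_equal(zero$values, rep(0, 1000))

  fast <- sin(2 * pi * 20 * t)
  outf <- remove_baseline(uniform_signal(fast, fs), 0.5)
  expect_equal(max(abs(outf$values[mid])), 1, tolerance = 0.05)

  expect_error(remove_baseline(uniform_signal(fast, fs), 60), "Nyquist")
})

test_that("R peaks are recovered exactly from clean synthetic ECG", {
  beats <- cumsum(rep(0.18, 100))
  ecg <- generate_synthetic_ecg(beats, fs = 1000)
  ann <- detect_r_peaks(ecg)
  expect_equal(length(ann$peak_times), 100)
  expect_true(all(abs(ann$peak_times - beats) <= 1 / 1000 + 1e-9))
  expect_true(all(diff(ann$peak_times) >= 0.05))
})

test_that("spurious spikes inside the refractory window are rejected", {
  beats <- cumsum(rep(0.18, 50))
  ecg <- generate_synthetic_ecg(beats, fs = 1000)
  v <- ecg$values
  # two small spikes 20 ms after true peaks
  for (b in beats[c(10, 30)]) v[round((b + 0.02) * 1000) + 1] <- 0.6
  ann <- detect_r_peaks(uniform_signal(v, 1000), refractory_s = 0.05)
  expect_equal(length(ann$peak_times), 50)
  expect_true(all(abs(ann$peak_times - beats) <= 2 / 1000))
})

test_that("a flat trace yields an empty annotation with a warning", {
  expect_warning(ann <- detect_r_peaks(uniform_signal(rep(0, 5000), 1000)),
                 "no peaks")
  expect_length(ann$peak_times, 0)
})

test_that("beat recovery survives noise and baseline drift end to end", {
  set.seed(11)
  beats <- cumsum(170 + stats::rnorm(300, sd = 5)) / 1000
  ecg <- generate_synthetic_ecg(beats, drift_amp = 5, drift_freq_hz = 0.3,
                                noise_sd = 0.1, fs = 1000)
  ann <- detect_r_peaks(remove_baseline(ecg))
  # >= 99% of true beats recovered, no false beats
  matched <- vapply(beats, function(b) any(abs(ann$peak_times - b) < 0.01), NA)
  expect_gte(mean(matched), 0.99)
  expect_lte(length(ann$peak_times), length(beats))
})

test_that("rr_from_annotations computes, bounds, and excludes intervals", {
  ann <- structure(list(peak_times = c(0, 0.2, 0.4),
                        quality_flags = rep("ok", 3)), class = "beat_annotations")
  rr <- rr_from_annotations(ann, bounds_ms = c(80, 400))
  expect_equal(rr$rr, c(200, 200))
  expect_equal(attr(rr, "n_excluded"), 0)

  # a 900 ms dropout among 150-200 ms beats is excluded, not interpolated
  pk <- c(cumsum(rep(0.18, 20)), cumsum(rep(0.18, 20)) + 0.18 * 20 + 0.9)
  ann2 <- structure(list(peak_times = pk, quality_flags = rep("ok", length(pk))),
                    class = "beat_annotations")
  rr2 <- rr_from_annotations(ann2, bounds_ms = c(80, 400))
  expect_equal(attr(rr2, "n_excluded"), 1)
  expect_true(all(rr2$rr >= 80 & rr2$rr <= 400))
  # retained values are untouched originals
  expect_true(all(abs(rr2$rr - 180) < 1e-9))
  expect_error(rr_from_annotations(structure(list(peak_times = 0.1,
                                                  quality_flags = "ok"),
                                             class = "beat_annotations")),
               "at least 2")
})

test_that("epoch segmentation follows wall-clock windows and midpoint labels", {
  rr <- rr_series(rr = rep(200, 3001), beat_times = seq(0, 600, by = 0.2))
  eps <- segment_epochs(rr, 150)
  expect_length(eps, 4)
  expect_true(all(vapply(eps, function(e) diff(range(e$beat_times)) <= 150, NA)))

  labels <- data.frame(label = c("Bsln", "V1"), start = c(0, 300), end = c(300, 600))
  eps2 <- segment_epochs(rr, 150, labels)
  expect_equal(vapply(eps2, function(e) e$label, ""), c("Bsln", "Bsln", "V1", "V1"))

  short <- rr_series(rr = rep(200, 700))  # 140 s record
  expect_warning(out <- segment_epochs(short, 150), "shorter")
  expect_length(out, 0)
})
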