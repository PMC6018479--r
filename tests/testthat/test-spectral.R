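test_that("Lomb-Scargle locates tones under even and uneven sampling", {
  t <- seq(0, 99.8, by = 0.2)
  y <- sin(2 * pi * 1.0 * t)
  grid <- seq(0.3, 2, by = 0.0025)
  pg <- lomb_scargle(t, y, grid)
  expect_s3_class(pg, "periodogram")
  expect_lt(abs(pg$freqs[which.max(pg$power)] - 1.0), 0.0025 + 1e-12)

  set.seed(8)
  keep <- sort(sample(length(t), round(0.7 * length(t))))
  pg2 <- lomb_scargle(t[keep], y[keep], grid)
  expect_lt(abs(pg2$freqs[which.max(pg2$power)] - 1.0), 0.0025 + 1e-12)

  expect_error(lomb_scargle(t, y, c(0, 1)), "> 0")
  expect_error(lomb_scargle(t[1:3], y[1:3], grid), "at least 4")
})

test_that("Lomb-Scargle matches direct formula evaluation at random frequencies", {
  set.seed(12)
  t <- sort(stats::runif(120, 0, 60))
  y <- sin(2 * pi * 0.7 * t) + 0.5 * stats::rnorm(120)
  fs <- stats::runif(20, 0.1, 2.4)
  pg <- lomb_scargle(t, y, fs)
  direct <- vapply(fs, function(f) oracle_lomb(t, y, f), 0)
  expect_equal(pg$power, direct, tolerance = 1e-9)
})

test_that("relative spectrum excludes VLF and normalizes to one", {
  pg <- structure(list(freqs = c(0.1, 0.5, 1.0, 1.5),
                       power = c(100, 2, 6, 0)), class = "periodogram")
  rs <- relative_spectrum(pg, c(0.3, 2))
  expect_equal(sum(rs$relpower), 1, tolerance = 1e-12)
  expect_false(0.1 %in% rs$freqs)        # VLF component dropped
  expect_equal(rs$relpower[1:2], c(0.25, 0.75))
  pg0 <- structure(list(freqs = c(0.5, 1), power = c(0, 0)), class = "periodogram")
  expect_error(relative_spectrum(pg0), "degenerate")
})

test_that("maxPER reflects spectral concentration", {
  expect_equal(max_per(make_relspec(seq(0.31, 1.99, length.out = 50), rep(1, 50))),
               1 / 50)
  expect_equal(max_per(make_relspec(c(0.5, 1, 1.5), c(0, 1, 0))), 1.0)
})

test_that("tRSE has its closed-form values and invariances", {
  # all power in one bin
  expect_equal(trse(make_relspec(c(1.0, 1.01), c(0.5, 0.5)), 20), 1.0)
  # uniform across bins: one component at each of 20 bin centres
  centres <- 0.3 + (seq_len(20) - 0.5) * (1.7 / 20)
  expect_equal(trse(make_relspec(centres, rep(1, 20)), 20), 0.0, tolerance = 1e-12)
  # two equal bins among 20: 1 - ln 2 / ln 20
  expect_equal(trse(make_relspec(centres[c(3, 11)], c(1, 1)), 20),
               1 - log(2) / log(20), tolerance = 1e-12)   # 0.76863
  # scale invariance of the underlying periodogram
  pg <- structure(list(freqs = centres, power = stats::runif(20)), class = "periodogram")
  pg2 <- structure(list(freqs = centres, power = 7.3 * pg$power), class = "periodogram")
  expect_equal(trse(relative_spectrum(pg), 20), trse(relative_spectrum(pg2), 20),
               tolerance = 1e-12)
})

test_that("tRSE stays in [0, 1] over random spectra and bin merges", {
  set.seed(19)
  for (i in 1:25) {
    nf <- sample(30:300, 1)
    rs <- make_relspec(sort(stats::runif(nf, 0.3, 2)), stats::rexp(nf))
    v20 <- trse(rs, 20)
    v10 <- trse(rs, 10)
    expect_true(v20 >= 0 && v20 <= 1)
    expect_true(v10 >= 0 && v10 <= 1)
  }
})

test_that("sliding spectrogram tracks a chirp and respects boundaries", {
  fs <- 5
  t <- seq(0, 200, by = 1 / fs)
  finst <- 0.5 + t / 200                      # 0.5 -> 1.5 Hz sweep
  y <- sin(2 * pi * cumsum(finst) / fs)
  grid <- seq(0.3, 2, by = 0.005)
  sp <- sliding_spectrogram(t, y, window_s = 40, step_s = 20, freq_grid = grid)
  peaks <- vapply(sp, function(w) w$periodogram$freqs[which.max(w$periodogram$power)], 0)
  expect_true(all(diff(peaks) > 0))

  y2 <- sin(2 * pi * 1.0 * t)
  sp2 <- sliding_spectrogram(t, y2, 40, 20, grid)
  peaks2 <- vapply(sp2, function(w) w$periodogram$freqs[which.max(w$periodogram$power)], 0)
  expect_lt(diff(range(peaks2)), 0.011)

  expect_warning(out <- sliding_spectrogram(t[1:50], y[1:50], window_s = 100,
                                            step_s = 10, freq_grid = grid),
                 "shorter")
  expect_length(out, 0)
})
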