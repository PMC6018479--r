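test_that("piecewise detrending fits lines where lines are the truth", {
  x <- 3 + 0.5 * (1:400)
  ds <- detrend_piecewise(x)
  expect_length(ds$segment_bounds, 1)
  expect_lt(max(abs(ds$values)), 1e-8)

  # joined ramps +1 / -1 ms per beat, break at beat 500
  set.seed(14)
  tent <- c(1:500, 500 - 1:500) + stats::rnorm(1000, sd = 5)
  ds2 <- detrend_piecewise(tent)
  cp <- ds2$segment_bounds[1]
  expect_lt(abs(cp - 500), 10)
  expect_lt(stats::sd(ds2$values), 0.05 * stats::sd(tent))

  # white noise around a constant: detrending removes (almost) nothing
  wn <- stats::rnorm(800)
  ds3 <- detrend_piecewise(wn)
  expect_gt(stats::var(ds3$values), 0.98 * stats::var(wn))
  expect_warning(detrend_piecewise(stats::rnorm(40), min_segment = 30), "single-segment")
})

test_that("autocorrelation follows its defining formula exactly", {
  alt <- rep(c(1, -1), 50)
  a <- rr_autocorrelation(alt, max_lag = 20)
  expect_equal(a$values, (-1)^(0:20), tolerance = 1e-12)
  expect_equal(a$values[1], 1.0)

  set.seed(26)
  v <- stats::rnorm(300)
  a2 <- rr_autocorrelation(v, max_lag = 50)
  expect_equal(a2$values, oracle_acf(v, 50), tolerance = 1e-12)

  # iid: sampling-theory bound on spurious correlation
  v3 <- stats::rnorm(2000)
  a3 <- rr_autocorrelation(v3, max_lag = 50)
  frac <- mean(abs(a3$values[-1]) < 4 / sqrt(2000))
  expect_gte(frac, 0.95)
  expect_error(rr_autocorrelation(rep(1, 100)), "degenerate")
})

test_that("maxACF and meanACF summarize the lag range correctly", {
  alt <- rep(c(1, -1), 60)
  a <- rr_autocorrelation(alt, max_lag = 55)
  expect_equal(max_acf(a), 1.0, tolerance = 1e-12)
  expect_equal(mean_acf(a), 1.0, tolerance = 1e-12)

  set.seed(7)
  noise <- rr_autocorrelation(stats::rnorm(2000), max_lag = 60)
  expect_lt(max_acf(noise), 0.1)
  expect_lt(mean_acf(noise), 0.05)

  per <- rr_autocorrelation(sin(2 * pi * (1:600) / 10), max_lag = 60)
  expect_gte(max_acf(per), 0.95)  # peaks at d = 30, 40, 50

  # mean <= max, sign-flip invariance
  set.seed(2)
  for (i in 1:10) {
    a4 <- rr_autocorrelation(stats::rnorm(400) + sin(2 * pi * (1:400) / 7), max_lag = 60)
    expect_lte(mean_acf(a4), max_acf(a4))
  }
  v <- sin(2 * pi * (1:500) / 9) + stats::rnorm(500, sd = 0.1)
  expect_equal(max_acf(rr_autocorrelation(v, 60)), max_acf(rr_autocorrelation(-v, 60)),
               tolerance = 1e-12)
  expect_error(max_acf(noise, c(25, 100)), "outside")
})

test_that("embedding selection finds sensible delay and dimension", {
  acf_sin <- structure(list(lags = 0:200, values = cos(2 * pi * (0:200) / 20)),
                       class = "acf_series")
  ch <- select_embedding(acf_sin)
  expect_gte(ch$tau, 4); expect_lte(ch$tau, 6)   # ~ quarter period
  expect_lte(ch$m, 3)                            # limit cycle embeds low-dim
  expect_equal(ch$r, 0.4 * sqrt(mean((acf_sin$values - mean(acf_sin$values))^2)),
               tolerance = 1e-12)
  expect_error(select_embedding(structure(list(lags = 0:50, values = rep(1, 51)),
                                          class = "acf_series")), "degenerate")
})

test_that("SE.ACF separates regular from irregular autocorrelograms", {
  # ACF of a pure periodic series at a physiological beat period
  acf_per <- rr_autocorrelation(sin(2 * pi * (1:600) / 8), max_lag = 200)
  expect_lt(se_acf(acf_per), 0.05)

  set.seed(99)
  acf_noise <- structure(list(lags = 0:200, values = stats::rnorm(201, sd = 0.2)),
                         class = "acf_series")
  expect_gt(se_acf(acf_noise), 0.5)

  # equals the delay-embedded brute-force oracle
  ch <- select_embedding(acf_noise)
  expect_equal(se_acf(acf_noise, ch),
               oracle_sampen(acf_noise$values, ch$m, ch$r, ch$tau),
               tolerance = 1e-12)
})

test_that("detrending rescues periodicity detection under drift", {
  n <- 600
  drift <- ifelse(seq_len(n) <= 300, 0.8 * seq_len(n), 0.8 * 300 - 0.6 * (seq_len(n) - 300))
  set.seed(4)
  x <- 170 + drift + 8 * sin(2 * pi * seq_len(n) / 10) + stats::rnorm(n, sd = 1)
  a_raw <- rr_autocorrelation(x - mean(x), max_lag = 60)
  a_det <- rr_autocorrelation(detrend_piecewise(x), max_lag = 60)
  expect_gte(max_acf(a_det, c(25, 50)), 0.8)
  expect_gt(max_acf(a_det, c(25, 50)), max_acf(a_raw, c(25, 50)))
})
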