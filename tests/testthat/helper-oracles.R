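# Independent brute-force oracles, kept deliberately naive (double loops,
# direct formula evaluation) so they share no code path with the package.

oracle_sampen <- function(x, m, r, tau = 1) {
  n <- length(x)
  nv <- n - m * tau
  count_m <- 0L; count_m1 <- 0L
  for (i in seq_len(nv - 1L)) {
    for (j in seq.int(i + 1L, nv)) {
      dm <- 0
      for (k in 0:(m - 1L)) dm <- max(dm, abs(x[i + k * tau] - x[j + k * tau]))
      if (dm <= r) {
        count_m <- count_m + 1L
        if (max(dm, abs(x[i + m * tau] - x[j + m * tau])) <= r) count_m1 <- count_m1 + 1L
      }
    }
  }
  if (count_m == 0L || count_m1 == 0L) return(NA_real_)
  -log(count_m1 / count_m)
}

oracle_acf <- function(v, max_lag) {
  n <- length(v)
  mu <- mean(v)
  sig <- sqrt(mean((v - mu)^2))
  xh <- (v - mu) / sig
  vapply(0:max_lag, function(d) {
    s <- 0
    for (nn in seq_len(n - d)) s <- s + xh[nn] * xh[nn + d]
    s / (n - d)
  }, 0)
}

# direct scalar evaluation of the classical normalized Lomb-Scargle formula
oracle_lomb <- function(times, values, f) {
  y <- values - mean(values)
  w <- 2 * pi * f
  tau <- atan2(sum(sin(2 * w * times)), sum(cos(2 * w * times))) / (2 * w)
  ct <- cos(w * (times - tau)); st <- sin(w * (times - tau))
  (sum(y * ct)^2 / sum(ct^2) + sum(y * st)^2 / sum(st^2)) / (2 * mean(y^2))
}

# build a relative_spectrum object directly (for closed-form entropy checks)
make_relspec <- function(freqs, relpower, band = c(0.3, 2)) {
  structure(list(freqs = freqs, relpower = relpower / sum(relpower), band = band),
            class = "relative_spectrum")
}

# power-matched CMV-like / BVV-like fixture pair under one seed
matched_fixtures <- function(seed, n_beats = 600) {
  set.seed(seed)
  cmv <- generate_rr_cmv(n_beats = n_beats, mod_depth_ms = 10, jitter_ms = 2)
  bvv <- generate_rr_bvv(n_beats = n_beats, mod_sd_ms = 10 / sqrt(2), jitter_ms = 2)
  list(cmv = cmv, bvv = bvv)
}
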