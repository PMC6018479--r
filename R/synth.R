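#' Van der Pol simulation configuration
#'
#' The oscillator `x'' = (1 - x^2) x' - (omega + C z(t)) x` with standard
#' Gaussian noise `z(t)` modulating the stiffness.  With `omega = 40` the
#' small-oscillation frequency is `sqrt(40)/(2*pi) ~ 1.007 Hz`, inside the
#' 0.5--1.5 Hz band of interest; increasing `C` widens the bandwidth.
#'
#' @param omega stiffness parameter (default 40).
#' @param c noise amplitude `C` (default 0).
#' @param t_end end time in s (default 99.8).
#' @param dt integration/sampling step in s (default 0.2, i.e. 5 Hz).
#' @param x0,v0 initial state (default `(2, 0)`, on the noise-free limit
#'   cycle, so no burn-in is discarded).
#' @param seed optional integer seed for the noise stream.
#' @return A list of class `"vdp_config"`.
#' @export
vdp_config <- function(omega = 40, c = 0, t_end = 99.8, dt = 0.2,
                       x0 = 2, v0 = 0, seed = NULL) {
  if (dt <= 0 || t_end < dt) stop("vdp_config: need dt > 0 and t_end >= dt")
  structure(list(omega = omega, c = c, t_end = t_end, dt = dt,
                 x0 = x0, v0 = v0, seed = seed),
            class = "vdp_config")
}

#' Simulate the stochastically forced Van der Pol oscillator
#'
#' Integrates `x' = v`, `v' = (1 - x^2) v - (omega + C z) x` with classical
#' 4th-order Runge-Kutta.  The noise `z ~ N(0, 1)` is drawn once per time
#' step of length `dt` and held constant across all stage evaluations
#' within that step (a stochastically forced ODE is only well defined under
#' RK4 with piecewise-constant forcing).  Each `dt` interval is integrated
#' with RK4 sub-steps: at large `C` the instantaneous stiffness
#' `omega + C z` can be strongly negative, transiently inflating `|x|`
#' until the nonlinear damping `(1 - x^2) v` -- which is stiff -- pulls it
#' back, and a single 0.2 s RK4 step is unstable through such excursions
#' while the true trajectory stays bounded.  The sub-step count is retried
#' upward (8, 32, 128, 512) until the interval integrates finitely; a step
#' that still overflows (`|x| > 1e6`) is an integration-failure error.
#' The output is the `x` state sampled on the `dt` grid; defaults give 500
#' samples spanning 0--99.8 s at 5 Hz.
#'
#' @param cfg a [vdp_config()].
#' @return A [uniform_signal()] at rate `1/dt`.
#' @export
simulate_vdp <- function(cfg = vdp_config()) {
  stopifnot(inherits(cfg, "vdp_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- floor(cfg$t_end / cfg$dt + 1e-9) + 1L
  dt <- cfg$dt; om <- cfg$omega; C <- cfg$c
  x <- numeric(n)
  xx <- cfg$x0; vv <- cfg$v0
  x[1L] <- xx
  z <- stats::rnorm(n - 1L)
  for (k in seq_len(n - 1L)) {
    w <- om + C * z[k]
    done <- FALSE
    for (nsub in c(8L, 32L, 128L, 512L)) {
      h <- dt / nsub
      x1 <- xx; v1 <- vv
      ok <- TRUE
      for (s in seq_len(nsub)) {
        k1x <- v1;                      k1v <- (1 - x1^2) * v1 - w * x1
        x2 <- x1 + h / 2 * k1x; v2 <- v1 + h / 2 * k1v
        k2x <- v2;                      k2v <- (1 - x2^2) * v2 - w * x2
        x3 <- x1 + h / 2 * k2x; v3 <- v1 + h / 2 * k2v
        k3x <- v3;                      k3v <- (1 - x3^2) * v3 - w * x3
        x4 <- x1 + h * k3x;     v4 <- v1 + h * k3v
        k4x <- v4;                      k4v <- (1 - x4^2) * v4 - w * x4
        x1 <- x1 + h / 6 * (k1x + 2 * k2x + 2 * k3x + k4x)
        v1 <- v1 + h / 6 * (k1v + 2 * k2v + 2 * k3v + k4v)
        if (!is.finite(x1) || !is.finite(v1) || abs(x1) > 1e6) { ok <- FALSE; break }
      }
      if (ok) { xx <- x1; vv <- v1; done <- TRUE; break }
    }
    if (!done) {
      stop(sprintf("simulate_vdp: integration failure at step %d (t = %.1f s)", k, k * dt))
    }
    x[k + 1L] <- xx
  }
  uniform_signal(x, sampling_rate = 1 / dt, start_time = 0)
}

#' Generate the noise-level ensemble of Van der Pol signals
#'
#' Default protocol: 21 noise levels `C` in steps of 2.5 (0 to 50), with
#' 20 independent realizations each (different noise streams), every
#' realization integrated over 0--99.8 s at step 0.2 s.  Per-cell child
#' seeds are drawn from the master seed with `sample.int`, so the whole
#' ensemble is reproducible bitwise from `master_seed` and any cell can be
#' regenerated in isolation from the seed table.
#'
#' @param cfg_base a [vdp_config()] template (its `c` and `seed` are
#'   overridden per cell).
#' @param c_values noise amplitudes (rows).
#' @param n_realizations realizations per noise level (columns).
#' @param master_seed integer seed for the child-seed table.
#' @return A list of class `"signal_ensemble"` with `c_values`,
#'   `n_realizations`, `seeds` (matrix), and `signals` (list of lists:
#'   `signals[[i]][[k]]`).
#' @export
generate_ensemble <- function(cfg_base = vdp_config(),
                              c_values = seq(0, 50, by = 2.5),
                              n_realizations = 20,
                              master_seed = 1L) {
  r <- length(c_values)
  set.seed(master_seed)
  seeds <- matrix(sample.int(.Machine$integer.max - 1L, r * n_realizations),
                  nrow = r, ncol = n_realizations)
  signals <- vector("list", r)
  for (i in seq_len(r)) {
    signals[[i]] <- vector("list", n_realizations)
    for (k in seq_len(n_realizations)) {
      cfg <- cfg_base
      cfg$c <- c_values[i]
      cfg$seed <- seeds[i, k]
      signals[[i]][[k]] <- tryCatch(simulate_vdp(cfg), error = function(e) {
        stop(sprintf("generate_ensemble: cell (C = %g, k = %d): %s",
                     c_values[i], k, conditionMessage(e)))
      })
    }
  }
  structure(list(c_values = c_values, n_realizations = n_realizations,
                 seeds = seeds, signals = signals, master_seed = master_seed),
            class = "signal_ensemble")
}

#' @export
print.signal_ensemble <- function(x, ...) {
  cat(sprintf("Signal ensemble: %d noise levels (C in [%g, %g]) x %d realizations\n",
              length(x$c_values), min(x$c_values), max(x$c_values),
              x$n_realizations))
  invisible(x)
}

check_rr_positive <- function(rr) {
  if (any(rr <= 0)) stop("generated RR intervals must be positive; reduce modulation depth/jitter")
  rr
}

#' Synthetic RR series with fixed-rate (CMV-like) sinusoidal modulation
#'
#' Emulates heart rate entrained to a fixed-rate ventilator: a single
#' sinusoidal modulation of RR at `mod_freq_hz` plus optional white jitter.
#' Beat times accumulate self-consistently (`t[n+1] = t[n] + rr[n+1]/1000`).
#'
#' @param n_beats number of beats.
#' @param mean_rr_ms mean RR in ms (default 170, rat-like).
#' @param mod_freq_hz modulation frequency in Hz (default 1).
#' @param mod_depth_ms sinusoid amplitude in ms (default 10).
#' @param jitter_ms white Gaussian jitter SD in ms (default 0).
#' @return An [rr_series()].
#' @export
generate_rr_cmv <- function(n_beats = 600, mean_rr_ms = 170, mod_freq_hz = 1,
                            mod_depth_ms = 10, jitter_ms = 0) {
  if (mod_depth_ms < 0 || jitter_ms < 0) stop("generate_rr_cmv: depths must be >= 0")
  rr <- numeric(n_beats)
  t <- 0
  times <- numeric(n_beats)
  eps <- stats::rnorm(n_beats, sd = jitter_ms)
  for (nn in seq_len(n_beats)) {
    rr[nn] <- mean_rr_ms + mod_depth_ms * sin(2 * pi * mod_freq_hz * t) + eps[nn]
    t <- t + rr[nn] / 1000
    times[nn] <- t
  }
  rr_series(rr = check_rr_positive(rr), beat_times = times, label = "CMV-like")
}

#' Synthetic RR series with broadband (BVV-like) modulation
#'
#' Emulates heart rate coupled to a variable ventilator: RR is modulated by
#' a band-limited Gaussian process over `band_hz`, synthesized as a sum of
#' `n_components` random-phase sinusoids with frequencies uniform in the
#' band and total variance `mod_sd_ms^2`.
#'
#' @inheritParams generate_rr_cmv
#' @param band_hz modulation band in Hz (default `c(0.5, 1.5)`); must lie
#'   below the beat Nyquist `1/(2 * mean_rr_s)`.
#' @param mod_sd_ms RMS modulation amplitude in ms (default `10/sqrt(2)`,
#'   power-matched to the default CMV sinusoid of amplitude 10).
#' @param n_components number of sinusoidal components (default 64).
#' @return An [rr_series()].
#' @export
generate_rr_bvv <- function(n_beats = 600, mean_rr_ms = 170,
                            band_hz = c(0.5, 1.5), mod_sd_ms = 10 / sqrt(2),
                            jitter_ms = 0, n_components = 64) {
  if (mod_sd_ms < 0 || jitter_ms < 0) stop("generate_rr_bvv: depths must be >= 0")
  if (band_hz[2] >= 1 / (2 * mean_rr_ms / 1000)) {
    stop("generate_rr_bvv: band exceeds the beat Nyquist frequency")
  }
  fk <- stats::runif(n_components, band_hz[1], band_hz[2])
  ph <- stats::runif(n_components, 0, 2 * pi)
  amp <- mod_sd_ms * sqrt(2 / n_components)
  modulate <- function(t) amp * sum(cos(2 * pi * fk * t + ph))
  rr <- numeric(n_beats)
  times <- numeric(n_beats)
  t <- 0
  eps <- stats::rnorm(n_beats, sd = jitter_ms)
  for (nn in seq_len(n_beats)) {
    rr[nn] <- mean_rr_ms + modulate(t) + eps[nn]
    t <- t + rr[nn] / 1000
    times[nn] <- t
  }
  rr_series(rr = check_rr_positive(rr), beat_times = times, label = "BVV-like")
}

#' Synthetic single-lead ECG with known beat times
#'
#' Sum of Gaussian QRS bumps centred at `beat_times`, plus sinusoidal
#' baseline drift and white noise.  With zero noise the beat times are
#' recoverable as local maxima, providing ground truth for the R-peak
#' detector.
#'
#' @param beat_times beat times in seconds (may be empty: drift-only trace).
#' @param duration_s trace length in s (default: 0.2 s past the last beat).
#' @param r_amp R-wave amplitude (default 1).
#' @param qrs_width_ms QRS full width at half maximum in ms (default 10);
#'   must be well below the minimum RR (error if >= min RR / 2).
#' @param drift_amp,drift_freq_hz baseline drift sinusoid (default 0 / 0.2 Hz).
#' @param noise_sd additive white noise SD (default 0).
#' @param fs sampling rate in Hz (>= 500).
#' @return A [uniform_signal()].
#' @export
generate_synthetic_ecg <- function(beat_times, duration_s = NULL, r_amp = 1,
                                   qrs_width_ms = 10, drift_amp = 0,
                                   drift_freq_hz = 0.2, noise_sd = 0,
                                   fs = 1000) {
  if (fs < 500) stop("generate_synthetic_ecg: fs must be >= 500 Hz")
  beat_times <- as.numeric(beat_times)
  if (length(beat_times) >= 2L) {
    min_rr <- min(diff(beat_times))
    if (qrs_width_ms / 1000 >= min_rr / 2) {
      stop("generate_synthetic_ecg: QRS width too large, bumps would overlap")
    }
  }
  if (is.null(duration_s)) {
    duration_s <- if (length(beat_times)) max(beat_times) + 0.2 else 1
  }
  t <- seq(0, duration_s, by = 1 / fs)
  v <- drift_amp * sin(2 * pi * drift_freq_hz * t)
  sig_t <- qrs_width_ms / 1000 / (2 * sqrt(2 * log(2)))  # FWHM -> SD
  for (bt in beat_times) {
    sel <- abs(t - bt) < 6 * sig_t
    v[sel] <- v[sel] + r_amp * exp(-(t[sel] - bt)^2 / (2 * sig_t^2))
  }
  if (noise_sd > 0) v <- v + stats::rnorm(length(v), sd = noise_sd)
  uniform_signal(v, fs, 0)
}
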