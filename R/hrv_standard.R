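rr_values <- function(rr) if (inherits(rr, "rr_series")) rr$rr else as.numeric(rr)

#' SDNN: standard deviation of the RR intervals
#'
#' Sample standard deviation (n - 1 denominator) of the RR series, in ms.
#'
#' @param rr an [rr_series()] or numeric vector of RR intervals (ms).
#' @return SDNN in ms.
#' @export
sdnn <- function(rr) {
  x <- rr_values(rr)
  if (length(x) < 2L) stop("sdnn: need at least 2 intervals")
  stats::sd(x)
}

#' RMSSD: root mean square of successive RR differences
#' @inheritParams sdnn
#' @return RMSSD in ms.
#' @export
rmssd <- function(rr) {
  x <- rr_values(rr)
  if (length(x) < 2L) stop("rmssd: need at least 2 intervals")
  sqrt(mean(diff(x)^2))
}

#' HRV triangular index
#'
#' Total number of RR intervals divided by the count in the modal bin of a
#' fixed-origin histogram.  The default bin width, 7.8125 ms (1/128 s), is
#' the conventional HRV standard; it was derived for human RR ranges and is
#' kept configurable for rodent data.
#'
#' @inheritParams sdnn
#' @param bin_width_ms histogram bin width in ms.
#' @return Unitless index >= 1.
#' @export
triangular_index <- function(rr, bin_width_ms = 7.8125) {
  x <- rr_values(rr)
  if (length(x) < 1L) stop("triangular_index: need at least 1 interval")
  if (bin_width_ms <= 0) stop("triangular_index: bin_width_ms must be > 0")
  counts <- table(floor(x / bin_width_ms))
  length(x) / max(counts)
}

#' Relative power in a frequency band
#'
#' Trapezoidal integration of a periodogram over `band`, divided by the
#' integral over `total_band`.  Band edges falling between grid points are
#' handled by linear interpolation, so disjoint bands tiling `total_band`
#' sum to exactly 1.
#'
#' @param pg a `"periodogram"` (see [lomb_scargle()]).
#' @param band numeric `c(low, high)` in Hz.
#' @param total_band numeric `c(low, high)` in Hz; must contain `band`.
#' @return Fraction in `[0, 1]`.
#' @export
band_relative_power <- function(pg, band, total_band) {
  stopifnot(inherits(pg, "periodogram"))
  rng <- range(pg$freqs)
  if (band[1] < total_band[1] || band[2] > total_band[2]) {
    stop("band_relative_power: band must lie within total_band")
  }
  # a grid built with seq() may stop short of the band edge by one step
  step <- max(diff(pg$freqs))
  if (total_band[1] < rng[1] - step || total_band[2] > rng[2] + step) {
    stop("band_relative_power: periodogram does not cover total_band")
  }
  num <- trapz_band(pg$freqs, pg$power, band)
  den <- trapz_band(pg$freqs, pg$power, total_band)
  if (den <= 0) stop("band_relative_power: zero total power")
  num / den
}

# trapezoid integral over [b1, b2] with linear interpolation at the edges
trapz_band <- function(f, p, band) {
  lo <- max(band[1], f[1]); hi <- min(band[2], f[length(f)])
  if (hi <= lo) return(0)
  inside <- f > lo & f < hi
  fk <- c(lo, f[inside], hi)
  pk <- c(stats::approx(f, p, lo)$y, p[inside], stats::approx(f, p, hi)$y)
  sum(diff(fk) * (pk[-1L] + pk[-length(pk)]) / 2)
}

#' Poincare plot descriptors SD1, SD2, SDRatio
#'
#' SD1 is the dispersion perpendicular to the line of identity, computed as
#' the uncentred RMS of `diff(rr)/sqrt(2)` so that `SD1 = RMSSD/sqrt(2)`
#' holds exactly; SD2 is the sample SD (n - 1) of `(rr[n] + rr[n+1])/sqrt(2)`
#' along the line of identity.
#'
#' @inheritParams sdnn
#' @return A list with `sd1`, `sd2` (ms) and `sd_ratio` (= sd1/sd2, `NA`
#'   with a `"reason"` attribute when sd2 is 0).
#' @export
poincare <- function(rr) {
  x <- rr_values(rr)
  if (length(x) < 3L) stop("poincare: need at least 3 intervals")
  d <- diff(x)
  sd1 <- sqrt(mean(d^2) / 2)
  sd2 <- stats::sd((x[-length(x)] + x[-1L]) / sqrt(2))
  ratio <- if (sd2 == 0) structure(NA_real_, reason = "sd2 is zero") else sd1 / sd2
  list(sd1 = sd1, sd2 = sd2, sd_ratio = ratio)
}

#' Detrended fluctuation analysis
#'
#' Integrates the mean-centred RR series, splits the profile into
#' non-overlapping boxes of size `s`, removes a linear fit per box, and
#' regresses `log F(s)` on `log s`.  `alpha1` is the slope over the
#' short-term scales (default 4--16 beats), `alpha2` over the long-term
#' scales (default 16--64 beats).
#'
#' @inheritParams sdnn
#' @param short_scales,long_scales integer box sizes.
#' @return A list with `alpha1`, `alpha2`, and the `scales`/`fluctuation`
#'   profile.
#' @export
dfa <- function(rr, short_scales = c(4, 5, 6, 8, 10, 12, 14, 16),
                long_scales = c(16, 20, 24, 32, 40, 48, 56, 64)) {
  x <- rr_values(rr)
  smax <- max(long_scales)
  if (length(x) < 2 * smax) stop("dfa: series too short for the requested scales")
  y <- cumsum(x - mean(x))
  scales <- sort(unique(c(short_scales, long_scales)))
  fl <- vapply(scales, function(s) dfa_fluct(y, s), 0)
  fit_slope <- function(sc) {
    sel <- scales %in% sc
    stats::coef(stats::lm(log(fl[sel]) ~ log(scales[sel])))[[2L]]
  }
  list(alpha1 = fit_slope(short_scales), alpha2 = fit_slope(long_scales),
       scales = scales, fluctuation = fl)
}

dfa_fluct <- function(y, s) {
  nb <- floor(length(y) / s)
  t <- seq_len(s)
  sst <- sum((t - mean(t))^2)
  res2 <- 0
  for (b in seq_len(nb)) {
    seg <- y[((b - 1) * s + 1):(b * s)]
    beta <- sum((t - mean(t)) * (seg - mean(seg))) / sst
    r <- seg - (mean(seg) + beta * (t - mean(t)))
    res2 <- res2 + sum(r^2)
  }
  sqrt(res2 / (nb * s))
}

#' Sample entropy with delay embedding
#'
#' SampEn = -ln(A/B), where B counts pairs of delay-embedded templates of
#' length `m` within Chebyshev distance `r` (self-matches excluded) and A
#' counts the same for length `m + 1`.  Both counts use the same
#' `n - m*tau` template vectors so A <= B.
#'
#' @param series numeric vector.
#' @param m pattern length (>= 1).
#' @param r tolerance, same units as `series` (> 0).
#' @param tau embedding delay in samples (>= 1).
#' @return Non-negative entropy; `NA` with a `"reason"` attribute when no
#'   template pairs match (undefined, never infinite).
#' @export
sample_entropy <- function(series, m = 2, r, tau = 1) {
  x <- as.numeric(series)
  n <- length(x)
  if (!is.numeric(r) || r <= 0) stop("sample_entropy: r must be > 0")
  if (m < 1 || tau < 1) stop("sample_entropy: m and tau must be >= 1")
  nv <- n - m * tau
  if (nv < 2L) stop("sample_entropy: series too short for m, tau")
  emb <- vapply(0:m, function(k) x[seq_len(nv) + k * tau], numeric(nv))
  dmax <- matrix(0, nv, nv)
  for (k in seq_len(m)) dmax <- pmax(dmax, abs(outer(emb[, k], emb[, k], "-")))
  within <- dmax <= r
  B <- (sum(within) - nv) / 2
  dmax1 <- pmax(dmax, abs(outer(emb[, m + 1L], emb[, m + 1L], "-")))
  A <- (sum(dmax1 <= r) - nv) / 2
  if (B == 0) return(structure(NA_real_, reason = "no length-m template matches"))
  if (A == 0) return(structure(NA_real_, reason = "no length-(m+1) template matches"))
  -log(A / B)
}

#' Conventional HRV battery for one epoch
#'
#' Time domain (SDNN, RMSSD, triangular index), Lomb-Scargle LF/HF relative
#' power and their ratio, Poincare SD1/SD2/SDRatio, DFA alpha1/alpha2, and
#' SampEn (m = 2, r = 0.2 x SDNN by default).  The LF/HF denominator is the
#' integrated power over the union of the two bands.
#'
#' @param rr an [rr_series()].
#' @param config a [run_config()].
#' @return A named list of indices; entries that cannot be computed are `NA`
#'   with the reason collected in `attr(, "notes")`.
#' @export
hrv_indices <- function(rr, config = run_config()) {
  stopifnot(inherits(rr, "rr_series"))
  notes <- character()
  out <- list(SDNN = NA_real_, RMSSD = NA_real_, TriIdx = NA_real_,
              LF = NA_real_, HF = NA_real_, LHR = NA_real_,
              SD1 = NA_real_, SD2 = NA_real_, SDRatio = NA_real_,
              alpha1 = NA_real_, alpha2 = NA_real_, SampEn = NA_real_)
  grab <- function(name, expr) {
    v <- tryCatch(expr, error = function(e) {
      notes <<- c(notes, sprintf("%s: %s", name, conditionMessage(e)))
      NA_real_
    })
    v
  }
  out$SDNN <- grab("SDNN", sdnn(rr))
  out$RMSSD <- grab("RMSSD", rmssd(rr))
  out$TriIdx <- grab("TriIdx", triangular_index(rr))
  total_band <- c(config$lf_band[1], config$hf_band[2])
  pg <- tryCatch({
    dur <- diff(range(rr$beat_times))
    grid <- seq(total_band[1], total_band[2], by = 1 / (config$oversample * dur))
    lomb_scargle(rr$beat_times, rr$rr, grid)
  }, error = function(e) { notes <<- c(notes, paste("LF/HF:", conditionMessage(e))); NULL })
  if (!is.null(pg)) {
    out$LF <- grab("LF", band_relative_power(pg, config$lf_band, total_band))
    out$HF <- grab("HF", band_relative_power(pg, config$hf_band, total_band))
    if (is.finite(out$LF) && is.finite(out$HF) && out$HF > 0) out$LHR <- out$LF / out$HF
  }
  pc <- tryCatch(poincare(rr), error = function(e) {
    notes <<- c(notes, paste("Poincare:", conditionMessage(e))); NULL })
  if (!is.null(pc)) {
    out$SD1 <- pc$sd1; out$SD2 <- pc$sd2
    out$SDRatio <- as.numeric(pc$sd_ratio)
    if (is.na(out$SDRatio)) notes <- c(notes, "SDRatio: sd2 is zero")
  }
  df <- tryCatch(dfa(rr), error = function(e) {
    notes <<- c(notes, paste("DFA:", conditionMessage(e))); NULL })
  if (!is.null(df)) { out$alpha1 <- df$alpha1; out$alpha2 <- df$alpha2 }
  out$SampEn <- grab("SampEn", {
    r <- config$sampen_r_factor * sdnn(rr)
    if (r <= 0) stop("zero SDNN, tolerance undefined")
    v <- sample_entropy(rr$rr, m = config$sampen_m, r = r, tau = 1)
    if (is.na(v)) stop(attr(v, "reason")) else v
  })
  attr(out, "notes") <- notes
  out
}
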