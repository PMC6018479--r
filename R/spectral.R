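#' Lomb-Scargle periodogram
#'
#' Classical normalized Lomb-Scargle periodogram of mean-centred values on an
#' arbitrary frequency grid.  Valid for unevenly sampled data such as RR
#' intervals indexed by their own beat times; for uniformly sampled input the
#' peak locations agree with a discrete-Fourier periodogram.
#'
#' @param times sample times in seconds, strictly increasing (not
#'   necessarily uniform), length >= 4.
#' @param values numeric vector, same length as `times`.
#' @param freq_grid strictly positive frequencies in Hz.
#' @return A list of class `"periodogram"` with `freqs` and `power`
#'   (non-negative, normalized by the population variance of `values`).
#' @export
lomb_scargle <- function(times, values, freq_grid) {
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values)) stop("lomb_scargle: length mismatch")
  if (length(times) < 4L) stop("lomb_scargle: need at least 4 samples")
  if (any(diff(times) <= 0)) stop("lomb_scargle: times must be strictly increasing")
  if (any(freq_grid <= 0)) stop("lomb_scargle: frequencies must be > 0")
  y <- values - mean(values)
  var_y <- mean(y^2)
  if (var_y == 0) {
    return(structure(list(freqs = freq_grid, power = rep(0, length(freq_grid))),
                     class = "periodogram"))
  }
  omega <- 2 * pi * freq_grid
  wt <- outer(omega, times)                       # nf x n
  tau <- atan2(rowSums(sin(2 * wt)), rowSums(cos(2 * wt))) / (2 * omega)
  arg <- wt - omega * tau                         # recycles tau down rows
  ca <- cos(arg); sa <- sin(arg)
  yc <- as.vector(ca %*% y); ys <- as.vector(sa %*% y)
  cc <- rowSums(ca * ca); ss <- rowSums(sa * sa)
  pw <- ifelse(cc > 0, yc^2 / cc, 0) + ifelse(ss > 0, ys^2 / ss, 0)
  structure(list(freqs = freq_grid, power = pw / (2 * var_y)),
            class = "periodogram")
}

#' @export
print.periodogram <- function(x, ...) {
  cat(sprintf("Periodogram: %d frequencies in [%.4g, %.4g] Hz, peak at %.4g Hz\n",
              length(x$freqs), min(x$freqs), max(x$freqs),
              x$freqs[which.max(x$power)]))
  invisible(x)
}

# default analysis grid for a record of the given duration
default_freq_grid <- function(duration, band, oversample = 4) {
  seq(band[1], band[2], by = 1 / (oversample * duration))
}

#' Band-limited relative power spectrum
#'
#' Drops frequencies outside `band` (excluding very-low-frequency drift
#' below the band floor) and normalizes the remaining powers to sum to 1, so
#' the result is a probability distribution over in-band frequency.  With
#' `normalization = "full_spectrum"` the denominator is instead the total
#' over the whole input grid (sensitivity analysis; the relative powers then
#' sum to the in-band fraction).
#'
#' @param pg a `"periodogram"`.
#' @param band `c(low, high)` in Hz (default 0.3--2.0).
#' @param normalization `"in_band"` (default) or `"full_spectrum"`.
#' @return A list of class `"relative_spectrum"` with `freqs`, `relpower`,
#'   `band`.
#' @export
relative_spectrum <- function(pg, band = c(0.3, 2.0),
                              normalization = c("in_band", "full_spectrum")) {
  stopifnot(inherits(pg, "periodogram"))
  normalization <- match.arg(normalization)
  sel <- pg$freqs >= band[1] & pg$freqs <= band[2]
  if (!any(sel)) stop("relative_spectrum: periodogram does not cover the band")
  p <- pg$power[sel]
  tot <- if (normalization == "in_band") sum(p) else sum(pg$power)
  if (tot <= 0) stop("relative_spectrum: zero in-band power (degenerate spectrum)")
  structure(list(freqs = pg$freqs[sel], relpower = p / tot, band = band),
            class = "relative_spectrum")
}

#' maxPER: peak of the relative power spectrum
#'
#' A periodic series concentrates relative power in a narrow band with a
#' high peak; a broadband series disperses it, lowering the maximum.
#'
#' @param rs a `"relative_spectrum"`.
#' @return Fraction in `(0, 1]`.
#' @export
max_per <- function(rs) {
  stopifnot(inherits(rs, "relative_spectrum"))
  max(rs$relpower)
}

#' tRSE: transformed Relative Shannon Entropy of the spectrum
#'
#' The band is split into `n_bins` equal-width bins; `P(i)` is the summed
#' relative power in bin `i`, and
#' `tRSE = 1 + sum(P(i) * log(P(i))) / log(M)` with `0 * log(0) := 0`.
#' A value near 1 indicates a narrowband (periodic) series; a uniform
#' distribution of power gives 0.
#'
#' @param rs a `"relative_spectrum"`.
#' @param n_bins number of bins `M` (default 20).
#' @return Value in `[0, 1]`.
#' @export
trse <- function(rs, n_bins = 20) {
  stopifnot(inherits(rs, "relative_spectrum"))
  if (n_bins < 2) stop("trse: n_bins must be >= 2")
  edges <- seq(rs$band[1], rs$band[2], length.out = n_bins + 1)
  idx <- findInterval(rs$freqs, edges, rightmost.closed = TRUE)
  idx[idx < 1L] <- 1L; idx[idx > n_bins] <- n_bins
  P <- vapply(seq_len(n_bins), function(b) sum(rs$relpower[idx == b]), 0)
  P <- P / sum(P)  # guard against full-spectrum normalization input
  h <- sum(ifelse(P > 0, P * log(P), 0))
  val <- 1 + h / log(n_bins)
  min(max(val, 0), 1)
}

#' Sliding-window Lomb-Scargle spectrogram
#'
#' Computes one periodogram per overlapping window, for time-frequency maps
#' of ventilator-coupled heart rate.
#'
#' @param times,values the series (seconds / values), uneven sampling
#'   allowed.
#' @param window_s window length in seconds (<= record duration).
#' @param step_s spacing between window centres in seconds.
#' @param freq_grid frequencies in Hz.
#' @return A list of class `"spectrogram"`: elements are lists with
#'   `center_time` and `periodogram`.  Windows with fewer than 4 samples are
#'   skipped with a warning.
#' @export
sliding_spectrogram <- function(times, values, window_s, step_s, freq_grid) {
  times <- as.numeric(times); values <- as.numeric(values)
  dur <- times[length(times)] - times[1L]
  if (window_s > dur) {
    warning("sliding_spectrogram: record shorter than one window")
    return(structure(list(), class = "spectrogram"))
  }
  starts <- seq(times[1L], times[length(times)] - window_s, by = step_s)
  out <- list()
  skipped <- 0L
  for (s in starts) {
    sel <- times >= s & times <= s + window_s
    if (sum(sel) < 4L) { skipped <- skipped + 1L; next }
    out[[length(out) + 1L]] <- list(
      center_time = s + window_s / 2,
      periodogram = lomb_scargle(times[sel], values[sel], freq_grid))
  }
  if (skipped > 0L) warning(sprintf("sliding_spectrogram: %d window(s) with < 4 samples skipped", skipped))
  structure(out, class = "spectrogram")
}

#' Write a spectrogram as long-format TSV
#' @param sp a `"spectrogram"`.
#' @param path output path; columns `time`, `freq`, `power`.
#' @return Invisibly, `path`.
#' @export
write_spectrogram <- function(sp, path) {
  stopifnot(inherits(sp, "spectrogram"))
  rows <- do.call(rbind, lapply(sp, function(w) {
    data.frame(time = w$center_time, freq = w$periodogram$freqs,
               power = w$periodogram$power)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
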