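#' RR-interval time series
#'
#' The central analysis object: a sequence of RR intervals (ms), each stamped
#' with the time of the beat that ends it (seconds since record start).
#'
#' When `beat_times` is omitted it is reconstructed as the cumulative sum of
#' `rr / 1000`, i.e. the first beat sits at `rr[1]/1000` s.  For `n >= 2`,
#' `rr[n]` must equal `(beat_times[n] - beat_times[n-1]) * 1000` within 0.5 ms
#' unless position `n` is listed in `gaps` (positions following an excluded
#' artifact interval, see [rr_from_annotations()]).
#'
#' @param rr numeric vector of RR intervals in milliseconds, all positive.
#' @param beat_times optional numeric vector of beat times in seconds,
#'   strictly increasing, same length as `rr`.
#' @param label free-text period tag (e.g. `"Bsln"`, `"V1"`, `"Rcvry"`).
#' @param gaps integer indices (>= 2) exempt from the time/RR consistency
#'   check because the preceding interval was excluded.
#' @return An object of class `"rr_series"` with fields `beat_times`, `rr`,
#'   `label`, `gaps`.
#' @export
#' @examples
#' x <- rr_series(rr = c(200, 210, 200))
#' x$beat_times  # 0.2, 0.41, 0.61
rr_series <- function(rr, beat_times = NULL, label = "", gaps = integer()) {
  rr <- as.numeric(rr)
  if (length(rr) < 1L) stop("rr_series: need at least one RR interval")
  bad <- which(!is.finite(rr) | rr <= 0)
  if (length(bad)) {
    stop(sprintf("rr_series: non-positive or non-finite RR at index %d (value %s)",
                 bad[1L], format(rr[bad[1L]])))
  }
  if (is.null(beat_times)) {
    beat_times <- cumsum(rr) / 1000
  } else {
    beat_times <- as.numeric(beat_times)
    if (length(beat_times) != length(rr)) {
      stop("rr_series: beat_times and rr must have the same length")
    }
    nonmono <- which(diff(beat_times) <= 0)
    if (length(nonmono)) {
      stop(sprintf("rr_series: beat_times not strictly increasing at index %d",
                   nonmono[1L] + 1L))
    }
    if (length(rr) >= 2L) {
      implied <- diff(beat_times) * 1000
      check <- setdiff(seq.int(2L, length(rr)), as.integer(gaps))
      off <- check[abs(rr[check] - implied[check - 1L]) > 0.5]
      if (length(off)) {
        stop(sprintf(
          "rr_series: rr[%d] = %.6g ms disagrees with beat-time difference %.6g ms (> 0.5 ms)",
          off[1L], rr[off[1L]], implied[off[1L] - 1L]))
      }
    }
  }
  structure(list(beat_times = beat_times, rr = rr, label = as.character(label),
                 gaps = as.integer(gaps)),
            class = "rr_series")
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("RR-interval series%s: %d beats over %.1f s, mean RR %.1f ms (SD %.2f)\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              length(x$rr), diff(range(x$beat_times)), mean(x$rr),
              stats::sd(x$rr)))
  invisible(x)
}

#' @export
length.rr_series <- function(x) length(x$rr)

#' Uniformly sampled signal
#'
#' Container for a regularly sampled trace (raw ECG, or a simulated
#' oscillator output).
#'
#' @param values numeric vector, length >= 2.
#' @param sampling_rate sampling rate in Hz, > 0.
#' @param start_time time of the first sample in seconds.
#' @return An object of class `"uniform_signal"`.
#' @export
uniform_signal <- function(values, sampling_rate, start_time = 0) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("uniform_signal: need at least 2 samples")
  if (!is.finite(sampling_rate) || sampling_rate <= 0) {
    stop("uniform_signal: sampling_rate must be > 0")
  }
  structure(list(values = values, sampling_rate = as.numeric(sampling_rate),
                 start_time = as.numeric(start_time)),
            class = "uniform_signal")
}

#' Sample times of a uniform signal
#' @param x a [uniform_signal()].
#' @return numeric vector of sample times in seconds.
#' @export
signal_times <- function(x) {
  stopifnot(inherits(x, "uniform_signal"))
  x$start_time + (seq_along(x$values) - 1) / x$sampling_rate
}

#' @export
print.uniform_signal <- function(x, ...) {
  cat(sprintf("Uniform signal: %d samples at %g Hz (%.3f s)\n",
              length(x$values), x$sampling_rate,
              (length(x$values) - 1) / x$sampling_rate))
  invisible(x)
}

# Resolve (times, values) pairs from the containers accepted by the
# spectral / autocorrelation front ends.
signal_xy <- function(x) {
  if (inherits(x, "rr_series")) {
    list(times = x$beat_times, values = x$rr)
  } else if (inherits(x, "uniform_signal")) {
    list(times = signal_times(x), values = x$values)
  } else {
    stop("expected an rr_series or uniform_signal")
  }
}
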