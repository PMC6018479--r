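#' Remove baseline drift from an ECG trace
#'
#' Zero-phase high-pass filtering (2nd-order Butterworth applied forward and
#' backward), so R-peak timing is not shifted.
#'
#' @param sig a [uniform_signal()].
#' @param cutoff_hz high-pass corner frequency; must be below Nyquist.
#' @return A [uniform_signal()] of the same length and rate.
#' @export
remove_baseline <- function(sig, cutoff_hz = 0.5) {
  stopifnot(inherits(sig, "uniform_signal"))
  nyq <- sig$sampling_rate / 2
  if (!is.numeric(cutoff_hz) || cutoff_hz <= 0 || cutoff_hz >= nyq) {
    stop("remove_baseline: cutoff_hz must be in (0, Nyquist)")
  }
  bf <- signal::butter(2, cutoff_hz / nyq, type = "high")
  out <- signal::filtfilt(bf, sig$values)
  uniform_signal(out, sig$sampling_rate, sig$start_time)
}

#' Detect R-wave peaks in a baseline-corrected ECG
#'
#' Band-pass (5--40 Hz) QRS emphasis, squaring, and an adaptive threshold of
#' `threshold_factor` times the rolling median of the squared amplitude
#' (floored at 5% of the global squared maximum so a quiet baseline cannot
#' drive the threshold to zero).  Candidate runs above threshold are refined
#' to the local maximum of the raw trace; peaks closer than `refractory_s`
#' keep only the larger amplitude.
#'
#' @param sig a baseline-corrected [uniform_signal()].
#' @param refractory_s minimum peak separation in seconds (default 0.05,
#'   safely below rodent RR intervals).
#' @param threshold_factor multiple of the rolling median (default 8).
#' @param band QRS emphasis band in Hz.
#' @return A list of class `"beat_annotations"` with `peak_times` (s,
#'   strictly increasing) and `quality_flags` (`"ok"` for detected peaks).
#'   A trace with no detectable peaks yields an empty annotation with a
#'   warning, not an error.
#' @export
detect_r_peaks <- function(sig, refractory_s = 0.05, threshold_factor = 8,
                           band = c(5, 40)) {
  stopifnot(inherits(sig, "uniform_signal"))
  if (refractory_s <= 0) stop("detect_r_peaks: refractory_s must be > 0")
  fs <- sig$sampling_rate
  v <- sig$values
  n <- length(v)
  nyq <- fs / 2
  hi <- min(band[2], 0.9 * nyq)
  bf <- signal::butter(2, c(band[1], hi) / nyq, type = "pass")
  emph <- signal::filtfilt(bf, v)
  sq <- emph^2
  k <- min(n - (1 - n %% 2), max(3L, 2L * floor(fs / 2) + 1L))  # ~1 s odd window
  med <- stats::runmed(sq, k, endrule = "median")
  thr <- pmax(threshold_factor * med, 0.05 * max(sq))
  cand <- which(sq > thr)
  if (!length(cand) || max(sq) == 0) {
    warning("detect_r_peaks: no peaks found")
    return(structure(list(peak_times = numeric(), quality_flags = character()),
                     class = "beat_annotations"))
  }
  # group contiguous runs of candidates (gaps < refractory merge)
  gap <- max(1L, round(refractory_s * fs))
  breaks <- which(diff(cand) > gap)
  starts <- cand[c(1L, breaks + 1L)]
  ends <- cand[c(breaks, length(cand))]
  half <- max(1L, round(0.01 * fs))  # +-10 ms refinement window on raw trace
  idx <- mapply(function(a, b) {
    lo <- max(1L, a - half); hi2 <- min(n, b + half)
    lo + which.max(v[lo:hi2]) - 1L
  }, starts, ends)
  amp <- v[idx]
  # refractory enforcement: keep the larger peak of any too-close pair
  ord <- order(idx)
  idx <- idx[ord]; amp <- amp[ord]
  keep <- rep(TRUE, length(idx))
  last <- 1L
  for (i in seq_along(idx)[-1L]) {
    if ((idx[i] - idx[last]) / fs < refractory_s) {
      if (amp[i] > amp[last]) { keep[last] <- FALSE; last <- i } else keep[i] <- FALSE
    } else last <- i
  }
  idx <- idx[keep]
  structure(list(peak_times = sig$start_time + (idx - 1L) / fs,
                 quality_flags = rep("ok", length(idx))),
            class = "beat_annotations")
}

#' Build an RR series from beat annotations
#'
#' RR intervals are computed between successive `ok` peaks.  Intervals
#' outside `bounds_ms`, or outside mean +/- 4 SD of the in-bounds intervals,
#' are flagged and excluded -- never interpolated.  The number of exclusions
#' is logged; positions following an exclusion are recorded as `gaps` in the
#' returned series.
#'
#' @param ann a `"beat_annotations"` object.
#' @param bounds_ms plausible RR range in ms (default `c(80, 400)`, rodent).
#' @return An [rr_series()]; `attr(, "n_excluded")` holds the exclusion count.
#' @export
rr_from_annotations <- function(ann, bounds_ms = c(80, 400)) {
  stopifnot(inherits(ann, "beat_annotations"))
  pk <- ann$peak_times[ann$quality_flags == "ok"]
  if (length(pk) < 2L) stop("rr_from_annotations: need at least 2 usable peaks")
  rr_all <- diff(pk) * 1000
  in_bounds <- rr_all >= bounds_ms[1] & rr_all <= bounds_ms[2]
  if (any(in_bounds)) {
    mu <- mean(rr_all[in_bounds]); sdv <- stats::sd(rr_all[in_bounds])
    ok <- in_bounds & (is.na(sdv) | sdv == 0 | abs(rr_all - mu) <= 4 * sdv)
  } else ok <- in_bounds
  n_excl <- sum(!ok)
  if (sum(ok) < 1L) stop("rr_from_annotations: no usable RR intervals after exclusion")
  rr <- rr_all[ok]
  bt <- pk[-1L][ok]
  # a retained interval whose predecessor interval was excluded is a gap
  kept <- which(ok)
  gaps <- which(c(FALSE, diff(kept) > 1L))
  hrv_log("rr_from_annotations: %d of %d intervals excluded", n_excl, length(rr_all))
  out <- rr_series(rr = rr, beat_times = bt, gaps = gaps)
  attr(out, "n_excluded") <- n_excl
  out
}

#' Cut an RR series into labelled analysis epochs
#'
#' Non-overlapping contiguous windows of `epoch_length_s` by beat time,
#' starting at the first beat.  Each epoch carries the label of the period
#' containing its midpoint; the trailing partial epoch is dropped (logged).
#'
#' @param rr an [rr_series()].
#' @param epoch_length_s epoch length in seconds (default 150 = 2.5 min).
#' @param labels optional period map: a data frame with columns
#'   `label`, `start`, `end` (seconds, `[start, end)`), or a named list of
#'   `c(start, end)` pairs.
#' @return A list of [rr_series()] epochs (possibly empty, with a warning,
#'   when the record is shorter than one epoch).
#' @export
segment_epochs <- function(rr, epoch_length_s = 150, labels = NULL) {
  stopifnot(inherits(rr, "rr_series"))
  if (epoch_length_s <= 0) stop("segment_epochs: epoch_length_s must be > 0")
  lab_df <- normalize_labels(labels)
  t0 <- rr$beat_times[1L]
  t1 <- rr$beat_times[length(rr$beat_times)]
  n_ep <- floor((t1 - t0) / epoch_length_s)
  if (n_ep < 1L) {
    warning("segment_epochs: record shorter than one epoch; no epochs produced")
    return(list())
  }
  if ((t1 - t0) - n_ep * epoch_length_s > 0) {
    hrv_log("segment_epochs: trailing partial epoch (%.1f s) dropped",
            (t1 - t0) - n_ep * epoch_length_s)
  }
  out <- vector("list", n_ep)
  for (j in seq_len(n_ep)) {
    lo <- t0 + (j - 1) * epoch_length_s
    hi <- t0 + j * epoch_length_s
    sel <- rr$beat_times >= lo & rr$beat_times < hi
    mid <- (lo + hi) / 2
    lab <- rr$label
    if (!is.null(lab_df)) {
      hit <- which(lab_df$start <= mid & mid < lab_df$end)
      lab <- if (length(hit)) lab_df$label[hit[1L]] else ""
    }
    idx <- which(sel)
    gaps_local <- intersect(rr$gaps, idx)
    gaps_local <- match(gaps_local, idx)
    # the first beat of an epoch has no in-epoch predecessor: exempt it
    gaps_local <- unique(c(1L, gaps_local))
    out[[j]] <- rr_series(rr = rr$rr[idx], beat_times = rr$beat_times[idx],
                          label = lab, gaps = gaps_local[gaps_local > 1L])
  }
  out
}

normalize_labels <- function(labels) {
  if (is.null(labels)) return(NULL)
  if (is.data.frame(labels)) {
    stopifnot(all(c("label", "start", "end") %in% names(labels)))
    return(labels)
  }
  data.frame(label = names(labels),
             start = vapply(labels, `[`, 0, 1L),
             end = vapply(labels, `[`, 0, 2L),
             stringsAsFactors = FALSE)
}
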