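#' Piecewise-linear detrending via change-point detection
#'
#' Binary segmentation over a piecewise-linear model: a segment is split at
#' the point minimizing the summed residual sum of squares of separate
#' linear fits when the improvement exceeds a BIC-style penalty
#' (`3 * log(n) * sigma2`, with `sigma2` estimated from first differences).
#' The per-segment ordinary least-squares line is then subtracted.
#' Detrending removes slow drift so the autocorrelation of the residuals
#' reflects beat-to-beat periodicity, not trend.
#'
#' @param x an [rr_series()], [uniform_signal()], or numeric vector.
#' @param penalty RSS-improvement threshold per change point; default
#'   `3 * log(n) * sigma2`.
#' @param min_segment minimum segment length (default 30).
#' @return A list of class `"detrended_series"` with `values` (residuals),
#'   `segment_bounds` (segment end indices), `mu` and `sigma`
#'   (population SD) of the residuals.  Series shorter than `2*min_segment`
#'   fall back to a single segment with a warning.
#' @export
detrend_piecewise <- function(x, penalty = NULL, min_segment = 30) {
  v <- if (inherits(x, "rr_series")) x$rr else if (inherits(x, "uniform_signal")) x$values else as.numeric(x)
  n <- length(v)
  if (n < 3L) stop("detrend_piecewise: series too short")
  short <- n < 2 * min_segment
  if (short) warning("detrend_piecewise: series shorter than 2*min_segment; single-segment fit")
  sigma2 <- mean(diff(v)^2) / 2
  if (sigma2 == 0) sigma2 <- .Machine$double.eps
  if (is.null(penalty)) penalty <- 3 * log(n) * sigma2

  # O(1) segment RSS of a linear fit from cumulative sums
  i <- as.numeric(seq_len(n))
  ci <- cumsum(i); ci2 <- cumsum(i^2)
  cv <- cumsum(v); cv2 <- cumsum(v^2); civ <- cumsum(i * v)
  pre <- function(cs, a, b) cs[b] - ifelse(a > 1, cs[a - 1L], 0)
  seg_rss <- function(a, b) {
    m <- b - a + 1
    st <- pre(ci, a, b); st2 <- pre(ci2, a, b)
    sv <- pre(cv, a, b); sv2 <- pre(cv2, a, b); siv <- pre(civ, a, b)
    sxx <- st2 - st^2 / m
    syy <- sv2 - sv^2 / m
    sxy <- siv - st * sv / m
    pmax(0, ifelse(sxx > 0, syy - sxy^2 / sxx, syy))
  }

  bounds <- integer()
  if (!short) {
    queue <- list(c(1L, n))
    while (length(queue)) {
      seg <- queue[[1L]]; queue <- queue[-1L]
      a <- seg[1L]; b <- seg[2L]
      if (b - a + 1L < 2L * min_segment) next
      cand <- (a + min_segment - 1L):(b - min_segment)
      gain <- seg_rss(a, b) - (seg_rss(a, cand) + seg_rss(cand + 1L, b))
      s <- cand[which.max(gain)]
      if (max(gain) > penalty) {
        bounds <- c(bounds, s)
        queue <- c(queue, list(c(a, s)), list(c(s + 1L, b)))
      }
    }
  }
  bounds <- sort(bounds)
  ends <- c(bounds, n)
  starts <- c(1L, bounds + 1L)
  res <- numeric(n)
  for (k in seq_along(starts)) {
    a <- starts[k]; b <- ends[k]
    idx <- a:b
    t <- i[idx]
    if (length(idx) >= 2L) {
      beta <- sum((t - mean(t)) * (v[idx] - mean(v[idx]))) / sum((t - mean(t))^2)
      res[idx] <- v[idx] - (mean(v[idx]) + beta * (t - mean(t)))
    } else res[idx] <- 0
  }
  structure(list(values = res, segment_bounds = ends,
                 mu = mean(res), sigma = sqrt(mean((res - mean(res))^2))),
            class = "detrended_series")
}

#' Lag-domain autocorrelation of a detrended series
#'
#' `R(d) = 1/(N-d) * sum(xhat[n] * xhat[n+d])` with
#' `xhat = (x - mean(x)) / sigma` standardized by the population SD, so
#' `R(0) = 1` exactly.  The lag `d` counts beats, not seconds, because RR
#' intervals are unevenly spaced in time.  At large `d` the `1/(N-d)`
#' normalization can push `|R(d)|` marginally above 1.
#'
#' @param ds a `"detrended_series"` (or numeric vector, standardized
#'   internally).
#' @param max_lag maximum lag; default `min(floor(N/2), 200)`.
#' @return A list of class `"acf_series"` with `lags` (0..max_lag) and
#'   `values`.
#' @export
rr_autocorrelation <- function(ds, max_lag = NULL) {
  v <- if (inherits(ds, "detrended_series")) ds$values else as.numeric(ds)
  n <- length(v)
  sig <- sqrt(mean((v - mean(v))^2))
  if (sig == 0) stop("rr_autocorrelation: constant residuals (degenerate series)")
  if (is.null(max_lag)) max_lag <- min(floor(n / 2), 200L)
  if (max_lag >= n) stop("rr_autocorrelation: max_lag must be < series length")
  xh <- (v - mean(v)) / sig
  vals <- vapply(0:max_lag, function(d) {
    sum(xh[seq_len(n - d)] * xh[seq.int(1L + d, n)]) / (n - d)
  }, 0)
  structure(list(lags = 0:max_lag, values = vals), class = "acf_series")
}

acf_range_values <- function(acf, d_range) {
  stopifnot(inherits(acf, "acf_series"))
  if (d_range[1] < min(acf$lags) || d_range[2] > max(acf$lags)) {
    stop(sprintf("lag range [%g, %g] outside computed lags [0, %d]",
                 d_range[1], d_range[2], max(acf$lags)))
  }
  acf$values[acf$lags >= d_range[1] & acf$lags <= d_range[2]]
}

#' maxACF: maximum absolute autocorrelation over a lag range
#'
#' Near 1 for a periodic series whose period (in beats) divides into the lag
#' range; near 0 for a random series.
#'
#' @param acf an `"acf_series"`.
#' @param d_range inclusive lag range (default 25--50 beats).
#' @return Value in `[0, 1]` (up to the large-lag normalization tolerance).
#' @export
max_acf <- function(acf, d_range = c(25, 50)) {
  max(abs(acf_range_values(acf, d_range)))
}

#' meanACF: mean absolute autocorrelation over a lag range
#' @inheritParams max_acf
#' @return Value in `[0, 1]`; always `<=` [max_acf()].
#' @export
mean_acf <- function(acf, d_range = c(25, 50)) {
  mean(abs(acf_range_values(acf, d_range)))
}

#' Select a delay embedding for SE.ACF
#'
#' The delay `tau` is the first local minimum of the histogram-based mutual
#' information between `R(d)` and `R(d+tau)` (scanned up to a quarter of the
#' available lags; fallback `tau = 1`, logged).  The pattern length `m` is
#' the smallest dimension whose false-nearest-neighbour fraction falls below
#' `fnn_fraction` (distance-ratio threshold `fnn_threshold`), capped at
#' `max_m`.  The tolerance is `r_factor` times the population SD of the
#' autocorrelation values.
#'
#' @param acf an `"acf_series"`.
#' @param fnn_threshold FNN distance-ratio threshold (default 10).
#' @param max_m cap on the pattern length (default 10).
#' @param mi_bins histogram bins per axis (default 10).
#' @param fnn_fraction acceptance fraction (default 0.05).
#' @param r_factor tolerance multiplier (default 0.4).
#' @return A list of class `"embedding_choice"` with `m`, `tau`, `r`.
#' @export
select_embedding <- function(acf, fnn_threshold = 10, max_m = 10,
                             mi_bins = 10, fnn_fraction = 0.05,
                             r_factor = 0.4) {
  stopifnot(inherits(acf, "acf_series"))
  v <- acf$values
  if (length(unique(v)) < 2L) stop("select_embedding: constant (degenerate) autocorrelation")
  tau_max <- max(2L, floor(length(v) / 4))
  mi <- vapply(seq_len(min(tau_max, length(v) - 2L)), function(tt) {
    mutual_information(v[seq_len(length(v) - tt)], v[seq.int(1L + tt, length(v))], mi_bins)
  }, 0)
  tau <- first_local_minimum(mi)
  if (is.na(tau)) {
    hrv_log("select_embedding: no MI minimum, tau = 1 fallback")
    tau <- 1L
  }
  m <- NA_integer_
  for (mm in seq_len(max_m)) {
    fr <- fnn_fraction_at(v, mm, tau, fnn_threshold)
    if (is.na(fr)) break
    if (fr < fnn_fraction) { m <- mm; break }
  }
  if (is.na(m)) {
    hrv_log("select_embedding: FNN fraction never below %.2f, m = %d cap", fnn_fraction, max_m)
    m <- as.integer(max_m)
  }
  sigma <- sqrt(mean((v - mean(v))^2))
  structure(list(m = as.integer(m), tau = as.integer(tau), r = r_factor * sigma),
            class = "embedding_choice")
}

mutual_information <- function(x, y, nbins) {
  rng <- range(c(x, y))
  if (diff(rng) == 0) return(0)
  brk <- seq(rng[1], rng[2], length.out = nbins + 1)
  ix <- findInterval(x, brk, rightmost.closed = TRUE)
  iy <- findInterval(y, brk, rightmost.closed = TRUE)
  ix[ix < 1L] <- 1L; ix[ix > nbins] <- nbins
  iy[iy < 1L] <- 1L; iy[iy > nbins] <- nbins
  joint <- table(factor(ix, levels = seq_len(nbins)), factor(iy, levels = seq_len(nbins))) / length(x)
  px <- rowSums(joint); py <- colSums(joint)
  pp <- as.numeric(joint)
  pxy <- as.numeric(outer(px, py))
  sel <- pp > 0
  sum(pp[sel] * log(pp[sel] / pxy[sel]))
}

first_local_minimum <- function(z) {
  n <- length(z)
  if (n < 2L) return(NA_integer_)
  for (k in seq_len(n - 1L)) {
    if (z[k] < z[k + 1L] && (k == 1L || z[k] < z[k - 1L])) return(k)
  }
  NA_integer_
}

# Kennel-style false-nearest-neighbour fraction at dimension m, delay tau.
# Temporal neighbours within a Theiler window of tau samples are excluded
# from the search, and the added-coordinate separation must exceed a noise
# floor (1e-8 of the value range) before a neighbour can be called false --
# otherwise near-duplicate templates of a periodic series flag ratios of
# rounding errors.
fnn_fraction_at <- function(v, m, tau, threshold) {
  n <- length(v)
  nv <- n - m * tau
  if (nv < 10L) return(NA_real_)
  emb <- vapply(0:(m - 1L), function(k) v[seq_len(nv) + k * tau], numeric(nv))
  emb <- matrix(emb, nrow = nv)
  dm <- as.matrix(stats::dist(emb))
  for (i in seq_len(nv)) dm[i, max(1L, i - tau):min(nv, i + tau)] <- Inf
  nn <- apply(dm, 1L, which.min)
  dnn <- dm[cbind(seq_len(nv), nn)]
  extra <- abs(v[seq_len(nv) + m * tau] - v[nn + m * tau])
  floor_v <- 1e-8 * diff(range(v))
  false_nb <- ifelse(is.finite(dnn) & dnn > 0,
                     extra / dnn > threshold & extra > floor_v,
                     extra > floor_v)
  mean(false_nb)
}

#' SE.ACF: sample entropy of the autocorrelation function
#'
#' Applies [sample_entropy()] to the autocorrelation values with the
#' FNN/MI-selected embedding.  A value near 0 indicates a regular, periodic
#' autocorrelogram (predictable cycle length); larger values indicate an
#' irregular, rapidly decaying one.
#'
#' @param acf an `"acf_series"`.
#' @param choice an `"embedding_choice"` (default: [select_embedding()]).
#' @return Non-negative entropy, or `NA` with a `"reason"` attribute when
#'   undefined (no template matches).
#' @export
se_acf <- function(acf, choice = NULL) {
  stopifnot(inherits(acf, "acf_series"))
  if (is.null(choice)) choice <- select_embedding(acf)
  sample_entropy(acf$values, m = choice$m, r = choice$r, tau = choice$tau)
}
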