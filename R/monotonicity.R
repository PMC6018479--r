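#' Evaluate a measure over a signal ensemble
#'
#' Applies `measure` (any function mapping a signal to a single real) to
#' every cell of the ensemble, producing the r x k matrix `S` with
#' `S[i, k]` the measure of realization `k` at noise level `c_values[i]`.
#' Failed cells are never imputed: any noise level with a failed cell is
#' excluded whole, with a warning; more than 10% failed cells aborts.
#'
#' @param ens a `"signal_ensemble"`.
#' @param measure function of one signal returning a numeric scalar.
#' @param ... passed on to `measure`.
#' @return A list of class `"measure_matrix"` with `c_values` and `values`
#'   (matrix, rows = noise levels).
#' @export
measure_over_ensemble <- function(ens, measure, ...) {
  stopifnot(inherits(ens, "signal_ensemble"))
  r <- length(ens$c_values); k <- ens$n_realizations
  S <- matrix(NA_real_, r, k)
  fails <- 0L
  for (i in seq_len(r)) for (j in seq_len(k)) {
    v <- tryCatch(as.numeric(measure(ens$signals[[i]][[j]], ...)),
                  error = function(e) NA_real_)
    if (length(v) != 1L || !is.finite(v)) {
      fails <- fails + 1L
      hrv_log("measure_over_ensemble: failure at (C = %g, k = %d)", ens$c_values[i], j)
      v <- NA_real_
    }
    S[i, j] <- v
  }
  if (fails > 0.1 * r * k) {
    stop(sprintf("measure_over_ensemble: %d of %d cells failed (> 10%%)", fails, r * k))
  }
  measure_matrix(ens$c_values, S)
}

measure_matrix <- function(c_values, S) {
  bad <- which(apply(S, 1L, function(row) any(!is.finite(row))))
  if (length(bad)) {
    warning(sprintf("measure matrix: excluding %d incomplete noise level(s): C = %s",
                    length(bad), paste(c_values[bad], collapse = ", ")))
    S <- S[-bad, , drop = FALSE]
    c_values <- c_values[-bad]
  }
  structure(list(c_values = c_values, values = S), class = "measure_matrix")
}

#' Pairwise rank-sum comparison matrix
#'
#' For every pair of noise levels `i < j`, a two-sided Wilcoxon rank-sum
#' test compares the measure distributions; `h[i, j]` is `+1` when the null
#' is rejected at `alpha` with level `j` stochastically larger, `-1` when
#' rejected with `j` smaller, and `0` otherwise (including degenerate
#' identical rows).  The test is exact for group sizes up to 25 without
#' ties; no multiple-testing correction is applied across the pairs.
#'
#' @param S a `"measure_matrix"` (or numeric matrix, rows = conditions).
#' @param alpha significance level in `(0, 0.5)` (default 0.05).
#' @return Upper-triangular integer matrix of class `"h_matrix"` with
#'   entries in `{-1, 0, +1}`.
#' @export
pairwise_h <- function(S, alpha = 0.05) {
  if (inherits(S, "measure_matrix")) S <- S$values
  if (!is.matrix(S) || nrow(S) < 2L) stop("pairwise_h: need a matrix with >= 2 rows")
  if (any(apply(S, 1L, function(x) sum(is.finite(x))) < 3L)) {
    stop("pairwise_h: each row needs >= 3 values")
  }
  if (alpha <= 0 || alpha >= 0.5) stop("pairwise_h: alpha must be in (0, 0.5)")
  r <- nrow(S)
  h <- matrix(0L, r, r)
  for (i in seq_len(r - 1L)) for (j in seq.int(i + 1L, r)) {
    xi <- S[i, ]; xj <- S[j, ]
    if (all(xi == xi[1L]) && all(xj == xj[1L]) && xi[1L] == xj[1L]) {
      hrv_log("pairwise_h: identical constant rows %d, %d; h = 0", i, j)
      next
    }
    wt <- suppressWarnings(stats::wilcox.test(xj, xi))
    if (is.finite(wt$p.value) && wt$p.value < alpha) {
      h[i, j] <- if (unname(wt$statistic) > length(xi) * length(xj) / 2) 1L else -1L
    }
  }
  structure(h, class = c("h_matrix", "matrix"))
}

#' Degree of monotonicity
#'
#' `M = | 2 / (r (r - 1)) * sum_{i < j} h(i, j) |`: the absolute mean of the
#' pairwise rank-sum outcomes.  `M = 1` means every pair of noise levels is
#' significantly ordered in the same direction (perfectly monotone response,
#' either direction); `M = 0` means no ordering.  Being rank-based, `M` is
#' invariant under strictly monotone transforms of the measure.
#'
#' @param h an `"h_matrix"` from [pairwise_h()].
#' @param r number of conditions; defaults to `nrow(h)`.
#' @return Value in `[0, 1]`.
#' @export
degree_of_monotonicity <- function(h, r = nrow(h)) {
  if (r < 2L) stop("degree_of_monotonicity: need r >= 2")
  abs(2 / (r * (r - 1)) * sum(h[upper.tri(h)]))
}

#' Benchmark periodicity measures on a synthetic ensemble
#'
#' Computes the five periodicity measures (tRSE, maxPER, maxACF, meanACF,
#' SE.ACF) for every ensemble cell -- each signal is analysed once and all
#' five are read off the same [periodicity()] fit -- then scores each
#' measure's degree of monotonicity against the noise level.
#'
#' @param ens a `"signal_ensemble"`.
#' @param measures optional named list of custom measure functions (signal
#'   -> scalar); the default uses the five built-in periodicity measures.
#' @param alpha rank-sum significance level (default 0.05).
#' @param config a [run_config()].
#' @return A data frame with columns `measure`, `M`, `n_levels` (noise
#'   levels retained after exclusion).
#' @export
benchmark_all <- function(ens, measures = NULL, alpha = 0.05,
                          config = run_config()) {
  stopifnot(inherits(ens, "signal_ensemble"))
  if (!is.null(measures)) {
    res <- lapply(names(measures), function(nm) {
      S <- measure_over_ensemble(ens, measures[[nm]])
      data.frame(measure = nm,
                 M = degree_of_monotonicity(pairwise_h(S, alpha)),
                 n_levels = length(S$c_values), stringsAsFactors = FALSE)
    })
    return(do.call(rbind, res))
  }
  mats <- ensemble_periodicity_matrices(ens, config)
  res <- lapply(names(mats), function(nm) {
    S <- measure_matrix(ens$c_values, mats[[nm]])
    data.frame(measure = nm,
               M = degree_of_monotonicity(pairwise_h(S, alpha)),
               n_levels = length(S$c_values), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

# one periodicity() fit per cell; returns a named list of r x k matrices
ensemble_periodicity_matrices <- function(ens, config = run_config()) {
  r <- length(ens$c_values); k <- ens$n_realizations
  nms <- c("tRSE", "maxPER", "maxACF", "meanACF", "SE.ACF")
  mats <- lapply(nms, function(nm) matrix(NA_real_, r, k))
  names(mats) <- nms
  for (i in seq_len(r)) for (j in seq_len(k)) {
    co <- tryCatch(stats::coef(periodicity(ens$signals[[i]][[j]], config)),
                   error = function(e) {
                     hrv_log("benchmark: periodicity failed at (C = %g, k = %d): %s",
                             ens$c_values[i], j, conditionMessage(e))
                     stats::setNames(rep(NA_real_, 5L), nms)
                   })
    for (nm in nms) mats[[nm]][i, j] <- co[[nm]]
  }
  mats
}
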