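#' Periodicity analysis of an RR-interval series or signal
#'
#' The package's central fit: computes the two spectral periodicity measures
#' (tRSE, maxPER) from the band-limited relative Lomb-Scargle spectrum, and
#' the three autocorrelation measures (maxACF, meanACF, SE.ACF) from the
#' change-point-detrended series, in one pass.
#'
#' @param x an [rr_series()] (RR values at their own beat times) or a
#'   [uniform_signal()] (e.g. a simulated oscillator output).
#' @param config a [run_config()]; governs the band, bin count, lag range,
#'   embedding selection, and detrending.
#' @return An object of class `"hrv_periodicity"`: a list with `measures`
#'   (named numeric: tRSE, maxPER, maxACF, meanACF, SE.ACF), `notes`
#'   (reasons for any `NA` measure -- never silent), `spectrum`
#'   (`"relative_spectrum"`), `periodogram`, `acf` (`"acf_series"`),
#'   `detrended`, `embedding`, `config`, and `call`.  Methods: `print`,
#'   `summary`, `coef`, `plot`.
#' @export
#' @examples
#' rr <- generate_rr_cmv(n_beats = 300, jitter_ms = 2)
#' fit <- periodicity(rr)
#' coef(fit)
periodicity <- function(x, config = run_config()) {
  xy <- signal_xy(x)
  notes <- character()
  measures <- c(tRSE = NA_real_, maxPER = NA_real_, maxACF = NA_real_,
                meanACF = NA_real_, SE.ACF = NA_real_)
  dur <- xy$times[length(xy$times)] - xy$times[1L]
  band <- config$spectral_band
  pg <- rs <- NULL
  sp <- tryCatch({
    grid <- default_freq_grid(dur, band, config$oversample)
    pg <- lomb_scargle(xy$times, xy$values, grid)
    rs <- relative_spectrum(pg, band, config$normalization)
    measures[["tRSE"]] <- trse(rs, config$trse_bins)
    measures[["maxPER"]] <- max_per(rs)
  }, error = function(e) notes <<- c(notes, paste("spectral:", conditionMessage(e))))
  ds <- acf_s <- emb <- NULL
  tryCatch({
    ds <- suppressWarnings(detrend_piecewise(xy$values, min_segment = config$min_segment))
    max_lag <- min(floor(length(xy$values) / 2), config$acf_max_lag)
    acf_s <- rr_autocorrelation(ds, max_lag)
    dr <- config$acf_d_range
    if (max_lag < dr[1]) {
      notes <- c(notes, sprintf("acf: series too short for lag range [%g, %g]", dr[1], dr[2]))
    } else {
      dr[2] <- min(dr[2], max_lag)
      measures[["maxACF"]] <- max_acf(acf_s, dr)
      measures[["meanACF"]] <- mean_acf(acf_s, dr)
    }
    emb <- select_embedding(acf_s, fnn_threshold = config$fnn_threshold,
                            max_m = config$max_m, mi_bins = config$mi_bins,
                            fnn_fraction = config$fnn_fraction,
                            r_factor = config$se_acf_tolerance_factor)
    v <- se_acf(acf_s, emb)
    if (is.na(v)) {
      notes <- c(notes, paste("SE.ACF:", attr(v, "reason")))
    } else measures[["SE.ACF"]] <- v
  }, error = function(e) notes <<- c(notes, paste("acf:", conditionMessage(e))))
  structure(list(measures = measures, notes = notes, spectrum = rs,
                 periodogram = pg, acf = acf_s, detrended = ds,
                 embedding = emb, config = config, call = match.call()),
            class = "hrv_periodicity")
}

#' @export
coef.hrv_periodicity <- function(object, ...) object$measures

#' @export
print.hrv_periodicity <- function(x, ...) {
  cat("Periodicity measures\n")
  m <- x$measures
  cat(sprintf("  tRSE    %8.4f    maxPER  %8.4f\n", m[["tRSE"]], m[["maxPER"]]))
  cat(sprintf("  maxACF  %8.4f    meanACF %8.4f    SE.ACF %8.4f\n",
              m[["maxACF"]], m[["meanACF"]], m[["SE.ACF"]]))
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' @export
summary.hrv_periodicity <- function(object, ...) {
  out <- list(measures = object$measures, notes = object$notes,
              band = object$config$spectral_band,
              n_freqs = length(object$spectrum$freqs),
              n_segments = length(object$detrended$segment_bounds),
              max_lag = if (!is.null(object$acf)) max(object$acf$lags) else NA,
              embedding = object$embedding)
  class(out) <- "summary.hrv_periodicity"
  out
}

#' @export
print.summary.hrv_periodicity <- function(x, ...) {
  cat("Periodicity analysis summary\n")
  cat(sprintf("  spectral band [%g, %g] Hz over %d frequencies\n",
              x$band[1], x$band[2], x$n_freqs))
  cat(sprintf("  detrending: %d linear segment(s); ACF to lag %s\n",
              x$n_segments, format(x$max_lag)))
  if (!is.null(x$embedding)) {
    cat(sprintf("  SE.ACF embedding: m = %d, tau = %d, r = %.4g\n",
                x$embedding$m, x$embedding$tau, x$embedding$r))
  }
  for (nm in names(x$measures)) cat(sprintf("  %-8s %s\n", nm, format(x$measures[[nm]], digits = 4)))
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' @export
plot.hrv_periodicity <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  if (!is.null(x$spectrum)) {
    graphics::plot(x$spectrum$freqs, x$spectrum$relpower, type = "h",
                   xlab = "Frequency (Hz)", ylab = "Relative power",
                   main = sprintf("Relative spectrum (tRSE = %.3f, maxPER = %.3f)",
                                  x$measures[["tRSE"]], x$measures[["maxPER"]]), ...)
  }
  if (!is.null(x$acf)) {
    graphics::plot(x$acf$lags, x$acf$values, type = "l",
                   xlab = "Lag (beats)", ylab = "Autocorrelation",
                   main = sprintf("ACF (maxACF = %.3f, SE.ACF = %.3f)",
                                  x$measures[["maxACF"]], x$measures[["SE.ACF"]]))
    graphics::abline(h = 0, lty = 3)
    graphics::abline(v = x$config$acf_d_range, lty = 2, col = "grey50")
  }
  invisible(x)
}

#' Per-epoch indices table
#'
#' Segments an RR series into epochs and computes, per epoch, the five
#' periodicity measures and the conventional HRV battery: one row per
#' epoch, ready for group-level statistics.
#'
#' @param rr an [rr_series()].
#' @param config a [run_config()].
#' @param labels optional period map (see [segment_epochs()]).
#' @return A data frame with columns `epoch_id`, `label`, the measures, and
#'   `notes` (semicolon-joined reasons for missing values).
#' @export
epoch_indices <- function(rr, config = run_config(), labels = NULL) {
  eps <- segment_epochs(rr, config$epoch_length, labels)
  if (!length(eps)) return(data.frame())
  hrv_log("epoch_indices: %d epochs, config %s, seed %s", length(eps),
          config_hash(config), format(config$rng_seed))
  rows <- lapply(seq_along(eps), function(j) {
    ep <- eps[[j]]
    per <- periodicity(ep, config)
    std <- hrv_indices(ep, config)
    notes <- c(per$notes, attr(std, "notes"))
    cbind(data.frame(epoch_id = j, label = ep$label, stringsAsFactors = FALSE),
          as.data.frame(as.list(per$measures), check.names = FALSE),
          as.data.frame(std[names(std)], check.names = FALSE),
          data.frame(notes = paste(notes, collapse = "; "), stringsAsFactors = FALSE))
  })
  do.call(rbind, rows)
}
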