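#' Analysis run configuration
#'
#' Bundles every tunable constant of the pipeline.  Defaults follow
#' conventional HRV practice for rodent recordings: 2.5-min epochs, the
#' 0.3--2 Hz periodicity band with 20 entropy bins, ACF lags 25--50 beats,
#' SE.ACF tolerance 0.4 x SD of the ACF, SampEn m = 2 and r = 0.2 x SDNN,
#' and rodent LF (0.1--1 Hz) / HF (1--3.5 Hz) bands.
#'
#' @param epoch_length epoch length in seconds.
#' @param spectral_band periodicity band `[low, high]` in Hz; power below
#'   `low` (very low frequency drift) is excluded before normalization.
#' @param trse_bins number of equal-width frequency bins for tRSE.
#' @param acf_d_range inclusive lag range (beats) for maxACF/meanACF.
#' @param se_acf_tolerance_factor SE.ACF tolerance as a multiple of the
#'   population SD of the autocorrelation values.
#' @param sampen_m SampEn pattern length for the RR series.
#' @param sampen_r_factor SampEn tolerance as a multiple of SDNN.
#' @param lf_band,hf_band low/high frequency bands in Hz.
#' @param rng_seed optional integer seed recorded with the run.
#' @param oversample Lomb-Scargle frequency oversampling factor; the grid
#'   spacing is `1 / (oversample * duration)`.
#' @param acf_max_lag ceiling on the autocorrelation lag (beats); the
#'   effective maximum is `min(floor(N/2), acf_max_lag)`.
#' @param min_segment minimum change-point segment length (beats).
#' @param fnn_threshold false-nearest-neighbour distance-ratio threshold.
#' @param fnn_fraction FNN fraction below which an embedding dimension is
#'   accepted.
#' @param max_m cap on the FNN-selected pattern length.
#' @param mi_bins histogram bins per axis for the mutual information.
#' @param normalization `"in_band"` divides spectral power by the in-band
#'   total (the default, making relative power a probability distribution);
#'   `"full_spectrum"` divides by the total over the whole computed grid.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(epoch_length = 150,
                       spectral_band = c(0.3, 2.0),
                       trse_bins = 20,
                       acf_d_range = c(25, 50),
                       se_acf_tolerance_factor = 0.4,
                       sampen_m = 2,
                       sampen_r_factor = 0.2,
                       lf_band = c(0.1, 1.0),
                       hf_band = c(1.0, 3.5),
                       rng_seed = NULL,
                       oversample = 4,
                       acf_max_lag = 200,
                       min_segment = 30,
                       fnn_threshold = 10,
                       fnn_fraction = 0.05,
                       max_m = 10,
                       mi_bins = 10,
                       normalization = c("in_band", "full_spectrum")) {
  normalization <- match.arg(normalization)
  cfg <- list(epoch_length = epoch_length, spectral_band = spectral_band,
              trse_bins = trse_bins, acf_d_range = acf_d_range,
              se_acf_tolerance_factor = se_acf_tolerance_factor,
              sampen_m = sampen_m, sampen_r_factor = sampen_r_factor,
              lf_band = lf_band, hf_band = hf_band, rng_seed = rng_seed,
              oversample = oversample, acf_max_lag = acf_max_lag,
              min_segment = min_segment, fnn_threshold = fnn_threshold,
              fnn_fraction = fnn_fraction, max_m = max_m, mi_bins = mi_bins,
              normalization = normalization)
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  band_ok <- function(b) length(b) == 2L && is.finite(b[1]) && is.finite(b[2]) && b[1] < b[2]
  if (!band_ok(cfg$spectral_band)) stop("run_config: spectral_band must be [low, high] with low < high")
  if (!band_ok(cfg$lf_band) || !band_ok(cfg$hf_band)) stop("run_config: LF/HF bands must have low < high")
  if (!band_ok(cfg$acf_d_range) || cfg$acf_d_range[1] < 1) stop("run_config: acf_d_range must be [low, high], low >= 1")
  for (f in c("epoch_length", "trse_bins", "se_acf_tolerance_factor",
              "sampen_m", "sampen_r_factor", "oversample", "acf_max_lag",
              "min_segment", "fnn_threshold", "fnn_fraction", "max_m", "mi_bins")) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || !is.finite(cfg[[f]]) || cfg[[f]] <= 0) {
      stop(sprintf("run_config: %s must be a positive scalar", f))
    }
  }
  if (cfg$trse_bins < 2) stop("run_config: trse_bins must be >= 2")
  invisible(cfg)
}

#' Read a run configuration from a JSON or key=value file
#'
#' Field names mirror [run_config()] arguments exactly; unknown names are an
#' error.  Values not present keep their defaults.
#'
#' @param path file path; JSON when the first non-blank character is an
#'   opening brace, otherwise `key = value` lines.
#' @return A `"run_config"`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("read_run_config: file not found: ", path)
  txt <- readLines(path, warn = FALSE)
  body <- paste(trimws(txt), collapse = "")
  if (startsWith(body, "{")) {
    vals <- jsonlite::fromJSON(paste(txt, collapse = "\n"), simplifyVector = TRUE)
  } else {
    lines <- trimws(txt)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    kv <- strsplit(lines, "=", fixed = TRUE)
    vals <- lapply(kv, function(p) {
      v <- trimws(p[2])
      parts <- strsplit(v, "[,[:space:]]+")[[1]]
      num <- suppressWarnings(as.numeric(parts))
      if (anyNA(num)) v else num
    })
    names(vals) <- vapply(kv, function(p) trimws(p[1]), "")
  }
  unknown <- setdiff(names(vals), names(formals(run_config)))
  if (length(unknown)) stop("read_run_config: unknown field(s): ", paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}

#' Short stable hash of a run configuration
#'
#' FNV-1a over the formatted field values; used to stamp log lines and
#' manifests so a run can be matched to its exact configuration.
#'
#' @param cfg a `"run_config"`.
#' @return 8-character hex string.
#' @export
config_hash <- function(cfg) {
  s <- paste(names(cfg), vapply(cfg, function(v) paste(format(v, digits = 15), collapse = ","), ""),
             sep = "=", collapse = ";")
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), b)  # keep in integer range
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

# Structured log line: timestamp + message, to stderr when
# options(hrvper.verbose = TRUE) and/or appended to options(hrvper.log_file).
hrv_log <- function(fmt, ...) {
  txt <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), sprintf(fmt, ...))
  if (isTRUE(getOption("hrvper.verbose", FALSE))) message(txt)
  lf <- getOption("hrvper.log_file", NULL)
  if (!is.null(lf)) cat(txt, "\n", file = lf, append = TRUE, sep = "")
  invisible(txt)
}
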