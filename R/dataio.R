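#' Read an RR-interval series from delimited text
#'
#' Accepts two dialects: two columns (beat time in s, RR in ms) or a single
#' column of RR intervals in ms (beat times reconstructed by cumulative
#' summation).  The delimiter (comma, tab, or whitespace) is sniffed from the
#' first data line.  Blank lines and `#` comments are skipped.
#'
#' @param path file path.
#' @param dialect `"auto"` (by column count), `"time_rr"`, or `"rr"`.
#' @param label period tag attached to the series.
#' @return An [rr_series()].
#' @export
read_rr_series <- function(path, dialect = c("auto", "time_rr", "rr"), label = "") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("read_rr_series: file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  if (!length(keep)) stop("read_rr_series: no data lines in ", path)
  fields <- parse_delimited(lines, keep)
  ncols <- length(fields[[1L]])
  if (dialect == "auto") dialect <- if (ncols >= 2L) "time_rr" else "rr"
  want <- if (dialect == "time_rr") 2L else 1L
  mat <- matrix(NA_real_, length(fields), want)
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < want) {
      stop(sprintf("read_rr_series: line %d has %d column(s), expected %d",
                   keep[i], length(f), want))
    }
    v <- suppressWarnings(as.numeric(f[seq_len(want)]))
    if (anyNA(v)) {
      stop(sprintf("read_rr_series: non-numeric value on line %d: '%s'",
                   keep[i], trimws(lines[keep[i]])))
    }
    mat[i, ] <- v
  }
  if (dialect == "time_rr") {
    rr_series(rr = mat[, 2L], beat_times = mat[, 1L], label = label)
  } else {
    rr_series(rr = mat[, 1L], label = label)
  }
}

# Split the given lines on a delimiter sniffed from the first data line.
parse_delimited <- function(lines, keep) {
  first <- lines[keep[1L]]
  sep <- if (grepl(",", first, fixed = TRUE)) "," else if (grepl("\t", first, fixed = TRUE)) "\t" else "[[:space:]]+"
  lapply(lines[keep], function(l) {
    out <- strsplit(trimws(l), sep)[[1L]]
    trimws(out[nzchar(out)])
  })
}

#' Read a uniformly sampled signal from single-column text
#'
#' @param path file path; one numeric value per line, blank lines skipped.
#' @param sampling_rate sampling rate in Hz (> 0).
#' @param start_time time of the first sample (s).
#' @return A [uniform_signal()].
#' @export
read_signal <- function(path, sampling_rate, start_time = 0) {
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    stop("read_signal: sampling_rate must be > 0")
  }
  if (!file.exists(path)) stop("read_signal: file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  if (length(keep) < 2L) stop("read_signal: need at least 2 samples, got ", length(keep))
  v <- suppressWarnings(as.numeric(trimws(lines[keep])))
  if (anyNA(v)) {
    bad <- keep[which(is.na(v))[1L]]
    stop(sprintf("read_signal: non-numeric value on line %d", bad))
  }
  uniform_signal(v, sampling_rate, start_time)
}

#' Write a per-epoch indices table
#'
#' Tab-separated, one header row, one row per epoch; missing measures are
#' rendered `NA`.  The table round-trips through [read_indices_table()]
#' unchanged to at least 12 significant digits.
#'
#' @param records a non-empty data frame (rows = epochs, columns = measures,
#'   typically from [epoch_indices()]).
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_indices_table <- function(records, path) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop("write_indices_table: records must be a non-empty data frame")
  }
  ok <- tryCatch({
    utils::write.table(format_indices(records), path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    TRUE
  }, error = function(e) stop("write_indices_table: cannot write ", path, ": ",
                              conditionMessage(e)))
  invisible(path)
}

format_indices <- function(df) {
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]])) df[[j]] <- format(df[[j]], digits = 15, trim = TRUE, scientific = FALSE)
  }
  df
}

#' Read back a per-epoch indices table
#' @param path path written by [write_indices_table()].
#' @return A data frame.
#' @export
read_indices_table <- function(path) {
  if (!file.exists(path)) stop("read_indices_table: file not found: ", path)
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}
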