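# File formats: waveform CSV, ground-truth JSON sidecars, ARFF feature
# tables (via foreign) with a CSV mirror.

#' Write a waveform record as CSV
#'
#' Two columns (`time_s`, `amplitude`) with a header line and LF endings.
#'
#' @param record An `apw_record`.
#' @param path Output file.
#' @export
write_waveform_csv <- function(record, path) {
  stopifnot(inherits(record, "apw_record"))
  df <- data.frame(time_s = (seq_along(record$samples) - 1) / record$fs,
                   amplitude = record$samples)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("time_s,amplitude", con, sep = "\n")
  writeLines(paste(format(df$time_s, trim = TRUE, scientific = FALSE),
                   format(df$amplitude, trim = TRUE, scientific = FALSE),
                   sep = ","), con, sep = "\n")
  invisible(path)
}

#' Read a waveform CSV
#'
#' @param path CSV with `time_s` and `amplitude` columns.
#' @param meta Optional metadata list attached to the record.
#' @return An `apw_record`; the sampling rate is inferred from the time
#'   column.
#' @export
read_waveform_csv <- function(path, meta = list()) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "amplitude") %in% names(df)))
    stop("parse error: expected columns time_s, amplitude in ", path)
  dt <- diff(df$time_s)
  if (any(dt <= 0))
    stop("parse error: non-monotone time column at line ",
         which(dt <= 0)[1] + 1)
  fs <- round(1 / median(dt))
  apw_record(df$amplitude, fs = fs, meta = meta)
}

#' Write per-pulse ground truth as JSON
#'
#' @param truth Ground-truth data frame from [generate_recording()].
#' @param path Output file.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' Read a ground-truth JSON sidecar
#' @param path JSON file written by [write_truth_json()].
#' @return Data frame.
#' @export
read_truth_json <- function(path) {
  jsonlite::fromJSON(path)
}

#' Write a feature table as ARFF
#'
#' Numeric attributes in the canonical order, a nominal class attribute
#' `{1,2}`, and `?` markers for missing values. Readable by any standard
#' ARFF parser.
#'
#' @param table An `apw_feature_table`.
#' @param path Output `.arff` file.
#' @param relation Relation name in the header.
#' @export
write_arff <- function(table, path, relation = "apw_features") {
  df <- as.data.frame(table)
  df$subject <- NULL
  if ("class" %in% names(df)) df$class <- factor(df$class, levels = c(1, 2))
  foreign::write.arff(df, path, relation = relation)
  invisible(path)
}

#' Read an ARFF feature table
#'
#' @param path `.arff` file.
#' @return An `apw_feature_table` (without the subject column, which ARFF
#'   does not carry).
#' @export
read_arff <- function(path) {
  df <- foreign::read.arff(path)
  if ("class" %in% names(df))
    df$class <- as.integer(as.character(df$class))
  class(df) <- c("apw_feature_table", "data.frame")
  df
}

#' Export the arrival-time histogram of detected fiducials
#'
#' Counts per fixed-width bin for one fiducial time column; beats where the
#' point is missing are assigned a null timing and fall into the first bin.
#'
#' @param times Numeric vector of arrival times in ms (`NA` = missing).
#' @param bin_ms Bin width in ms.
#' @param max_ms Histogram range upper bound.
#' @return Data frame `bin_start`, `count`.
#' @export
fiducial_histogram <- function(times, bin_ms = 10, max_ms = 600) {
  t0 <- ifelse(is.na(times), 0, times)      # null-timing convention
  breaks <- seq(0, max_ms, by = bin_ms)
  t0 <- pmin(t0, max_ms - 1e-9)
  h <- hist(t0, breaks = breaks, plot = FALSE, right = FALSE)
  data.frame(bin_start = head(breaks, -1), count = h$counts)
}
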