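#' Source-level region time series
#'
#' Container for one subject's source-reconstructed signals: an N x T matrix
#' of real values (regions in rows), the sampling rate, and unique region
#' labels. This is the object the whole pipeline starts from; upstream
#' acquisition, artifact removal and beamforming are out of scope.
#'
#' @param data Numeric matrix, regions x samples.
#' @param fs Sampling rate in Hz.
#' @param region_labels Character vector of unique region names, one per row.
#' @return An object of class `source_ts` (a list with elements `data`,
#'   `fs`, `region_labels`).
#' @examples
#' ts <- source_ts(matrix(rnorm(2 * 2560), 2), fs = 256,
#'                 region_labels = c("r1", "r2"))
#' @export
source_ts <- function(data, fs, region_labels) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop_invalid("signal data must be numeric")
  assert_finite(data, "signal data")
  if (length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop_invalid("fs must be a single positive number (Hz)")
  }
  region_labels <- as.character(region_labels)
  if (length(region_labels) != nrow(data)) {
    stop_invalid("need one region label per row: %d labels for %d rows",
                 length(region_labels), nrow(data))
  }
  if (anyDuplicated(region_labels)) {
    stop_invalid("region labels must be unique (duplicated: %s)",
                 paste(unique(region_labels[duplicated(region_labels)]),
                       collapse = ", "))
  }
  rownames(data) <- region_labels
  structure(list(data = data, fs = fs, region_labels = region_labels),
            class = "source_ts")
}

#' @export
print.source_ts <- function(x, ...) {
  cat(sprintf("<source_ts> %d regions x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  invisible(x)
}

#' @export
dim.source_ts <- function(x) dim(x$data)

#' Write region time series as delimited text
#'
#' One row per region; first column holds the region label, remaining
#' columns the samples. The sampling rate is recorded on a `# fs=` comment
#' line so files round-trip through [read_source_ts()].
#'
#' @param ts A [source_ts()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_source_ts <- function(ts, path) {
  stopifnot(inherits(ts, "source_ts"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%.10g", ts$fs), con)
  df <- data.frame(region_label = ts$region_labels,
                   ts$data, check.names = FALSE)
  utils::write.table(df, con, sep = ",", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read region time series written by [write_source_ts()]
#'
#' @param path File path.
#' @param fs Sampling rate override; required only when the file carries no
#'   `# fs=` header line.
#' @return A [source_ts()] object.
#' @export
read_source_ts <- function(path, fs = NULL) {
  first <- readLines(path, n = 1L)
  skip <- 0L
  if (grepl("^#\\s*fs=", first)) {
    fs <- as.numeric(sub("^#\\s*fs=", "", first))
    skip <- 1L
  }
  if (is.null(fs)) stop_invalid("no '# fs=' header in %s and no fs given", path)
  df <- utils::read.table(path, sep = ",", skip = skip,
                          stringsAsFactors = FALSE)
  source_ts(as.matrix(df[, -1, drop = FALSE]), fs = fs,
            region_labels = df[[1]])
}
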