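#' Canonical frequency bands
#'
#' The five standard bands used throughout the pipeline: delta (0.5-4 Hz),
#' theta (4-8 Hz), alpha (8-13 Hz), beta (13-30 Hz) and gamma (30-48 Hz).
#' Band edges are configurable wherever a band set is accepted; these are
#' the defaults.
#'
#' @return A data.frame with columns `name`, `low`, `high` (Hz).
#' @examples
#' canonical_bands()
#' @export
canonical_bands <- function() {
  data.frame(
    name = c("delta", "theta", "alpha", "beta", "gamma"),
    low  = c(0.5, 4, 8, 13, 30),
    high = c(4, 8, 13, 30, 48),
    stringsAsFactors = FALSE
  )
}

#' Define a frequency band
#'
#' @param name Band name.
#' @param low,high Band edges in Hz, `0 < low < high`.
#' @return A one-row data.frame compatible with [canonical_bands()].
#' @export
band_definition <- function(name, low, high) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop_invalid("band name must be a non-empty string")
  }
  if (!is.finite(low) || !is.finite(high) || low <= 0 || high <= low) {
    stop_invalid("band edges must satisfy 0 < low < high (got [%s, %s])",
                 format(low), format(high))
  }
  data.frame(name = name, low = low, high = high, stringsAsFactors = FALSE)
}

# Validate a band table (possibly user-supplied via config).
validate_bands <- function(bands) {
  need <- c("name", "low", "high")
  if (!is.data.frame(bands) || !all(need %in% names(bands))) {
    stop_invalid("bands must be a data.frame with columns name, low, high")
  }
  if (anyDuplicated(bands$name)) stop_invalid("band names must be unique")
  for (i in seq_len(nrow(bands))) {
    band_definition(bands$name[i], bands$low[i], bands$high[i])
  }
  bands
}
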