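#' Zero-phase Butterworth band-pass filtering
#'
#' Applies an order-`order` Butterworth band-pass forward and backward
#' (via [signal::filtfilt()]), so the net phase response is zero. Zero-phase
#' application matters here: downstream connectivity is phase-based, and a
#' causal IIR pass would distort the very phase relations being measured.
#'
#' @param ts A [source_ts()] object.
#' @param low,high Band edges in Hz; both must lie below the Nyquist
#'   frequency `fs/2`.
#' @param order Filter order (default 4).
#' @return A filtered [source_ts()] of the same shape.
#' @examples
#' ts <- source_ts(matrix(rnorm(2560), 1), 256, "r1")
#' alpha <- bandpass_filter(ts, 8, 13)
#' @export
bandpass_filter <- function(ts, low, high, order = 4) {
  stopifnot(inherits(ts, "source_ts"))
  nyq <- ts$fs / 2
  if (!is.finite(low) || !is.finite(high) || low <= 0 || high <= low) {
    stop_invalid("band edges must satisfy 0 < low < high")
  }
  if (high >= nyq) {
    stop_invalid("band edge %g Hz is at or above Nyquist (%g Hz)", high, nyq)
  }
  assert_finite(ts$data, "signal data")
  if (ncol(ts$data) < 3 * ts$fs) {
    stop_invalid("need at least 3 s of signal for stable filtering (got %.2f s)",
                 ncol(ts$data) / ts$fs)
  }
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  out <- t(apply(ts$data, 1L, function(x) signal::filtfilt(bf, x)))
  source_ts(out, ts$fs, ts$region_labels)
}

#' Decompose region signals into the canonical bands
#'
#' Runs [bandpass_filter()] once per band and returns the named list of
#' band-limited copies. Defaults to the five canonical bands of
#' [canonical_bands()].
#'
#' @param ts A [source_ts()] object.
#' @param bands Band table (`name`, `low`, `high`); defaults to
#'   [canonical_bands()].
#' @param order Butterworth order passed through to [bandpass_filter()].
#' @return Named list of [source_ts()], one entry per band.
#' @export
decompose_bands <- function(ts, bands = canonical_bands(), order = 4) {
  bands <- validate_bands(bands)
  out <- lapply(seq_len(nrow(bands)), function(i) {
    bandpass_filter(ts, bands$low[i], bands$high[i], order = order)
  })
  names(out) <- bands$name
  out
}

# Analytic signal of a real vector via the frequency-domain Hilbert
# transform: double the positive-frequency half of the spectrum, zero the
# negative half, keep DC (and Nyquist, when T is even) untouched.
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[2:(n / 2)] <- 2
    h[n / 2 + 1] <- 1
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

#' Instantaneous phase of band-limited signals
#'
#' Phase is the argument of the analytic signal, computed per region over
#' the full recording (no epoching). The estimate is only meaningful for
#' band-limited input; this contract is documented, not enforced. The first
#' and last `edge_trim_s` seconds are flagged in the returned object so
#' connectivity estimation can drop transform edge effects.
#'
#' @param ts A band-limited [source_ts()] object.
#' @param edge_trim_s Seconds flagged at each edge (default 1).
#' @return A `phase_series` object: list with `phases` (N x T matrix of
#'   wrapped phases in radians), `fs`, `region_labels`, and `edge_samples`,
#'   the per-edge count of flagged samples.
#' @export
instantaneous_phase <- function(ts, edge_trim_s = 1) {
  stopifnot(inherits(ts, "source_ts"))
  v <- apply(ts$data, 1L, stats::var)
  if (any(v == 0)) {
    stop_invalid("constant (zero-variance) channel(s): %s",
                 paste(ts$region_labels[v == 0], collapse = ", "))
  }
  ph <- t(apply(ts$data, 1L, function(x) Arg(analytic_signal(x))))
  structure(list(phases = ph, fs = ts$fs, region_labels = ts$region_labels,
                 edge_samples = as.integer(round(edge_trim_s * ts$fs))),
            class = "phase_series")
}

#' @export
print.phase_series <- function(x, ...) {
  cat(sprintf("<phase_series> %d regions x %d samples @ %g Hz (%d edge samples flagged)\n",
              nrow(x$phases), ncol(x$phases), x$fs, x$edge_samples))
  invisible(x)
}

# Drop the flagged edge samples from a phase_series (used before PLM).
trim_edges <- function(phases) {
  e <- phases$edge_samples
  Tn <- ncol(phases$phases)
  if (e <= 0) return(phases)
  if (2 * e >= Tn) stop_invalid("edge trim (%d samples/side) leaves no data", e)
  phases$phases <- phases$phases[, (e + 1):(Tn - e), drop = FALSE]
  phases$edge_samples <- 0L
  phases
}
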