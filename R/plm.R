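#' PLM estimation settings
#'
#' The phase linearity measurement integrates the power spectrum
#' `|S_Z(f)|^2` of the interferometric signal
#' `z(t) = exp(i * (phi_i - phi_j))` over the low frequencies `|f| <= B`
#' and divides by the total power. `B` is the integration half-bandwidth;
#' 1 Hz is the conventional choice. Discarding the DC bin
#' removes the zero-lag component, which is the metric's guard against
#' volume conduction / instantaneous mixing: two identical phase series
#' yield a purely DC spectrum and score 0 rather than a spuriously perfect
#' coupling.
#'
#' @param B Integration half-bandwidth in Hz (default 1).
#' @param spectral_estimator `"periodogram"` (default; deterministic,
#'   parameter-free) or `"welch"` (segment-averaged, noise-resilient).
#' @param welch_segment_s Welch segment length in seconds; must be at least
#'   `2 / B` so the band `|f| <= B` spans several frequency bins.
#' @param discard_dc Zero the f = 0 bin before integrating (default TRUE).
#' @param epoch_s Optional epoch length in seconds; when set, the phase
#'   record is cut into non-overlapping epochs and the per-epoch PLM
#'   matrices are averaged. Default NULL = full recording.
#' @return A `plm_config` list.
#' @export
plm_config <- function(B = 1,
                       spectral_estimator = c("periodogram", "welch"),
                       welch_segment_s = 8,
                       discard_dc = TRUE,
                       epoch_s = NULL) {
  spectral_estimator <- match.arg(spectral_estimator)
  if (!is.finite(B) || B <= 0) stop_invalid("B must be positive (Hz)")
  if (spectral_estimator == "welch" && welch_segment_s < 2 / B) {
    stop_invalid("welch_segment_s must be >= 2/B = %g s", 2 / B)
  }
  structure(list(B = B, spectral_estimator = spectral_estimator,
                 welch_segment_s = welch_segment_s,
                 discard_dc = isTRUE(discard_dc),
                 epoch_s = epoch_s),
            class = "plm_config")
}

# Power spectrum (periodogram) of a complex series, DFT bin ordering.
periodogram_psd <- function(z) {
  Mod(stats::fft(z))^2 / length(z)
}

# Welch PSD of a complex series: non-overlapping Hann-windowed segments,
# averaged. Returned on the segment-length frequency grid.
welch_psd <- function(z, seg_len) {
  n <- length(z)
  n_seg <- n %/% seg_len
  if (n_seg < 1L) stop_invalid("signal shorter than one Welch segment")
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_len) / (seg_len + 1))
  acc <- numeric(seg_len)
  for (k in seq_len(n_seg)) {
    seg <- z[((k - 1L) * seg_len + 1L):(k * seg_len)] * w
    acc <- acc + Mod(stats::fft(seg))^2
  }
  acc / (n_seg * sum(w^2))
}

# PLM from an already-computed PSD on an fs-sampled DFT grid.
plm_from_psd <- function(psd, fs, B, discard_dc) {
  n <- length(psd)
  tot_all <- sum(psd)
  if (discard_dc) psd[1] <- 0
  # |f| for DFT bin k (0-based) is min(k, n-k) * fs / n
  k <- seq_len(n) - 1L
  freq <- pmin(k, n - k) * fs / n
  tot <- sum(psd)
  if (tot <= 1e-12 * tot_all || !is.finite(tot)) {
    warning("degenerate constant phase difference: zero spectral power after DC removal; PLM set to 0",
            call. = FALSE)
    return(0)
  }
  sum(psd[freq <= B]) / tot
}

#' Phase linearity measurement for one region pair
#'
#' Forms the interferometric signal `z(t) = exp(i * (phi_i(t) - phi_j(t)))`,
#' estimates its power spectrum `|S_Z(f)|^2`, and returns the fraction of
#' power concentrated within `|f| <= B`. Values lie in `[0, 1]`;
#' the statistic is symmetric in its arguments and invariant to positive
#' rescaling of the underlying signals (phases are unchanged).
#'
#' @param phase_i,phase_j Numeric phase vectors (radians), equal length.
#' @param fs Sampling rate in Hz.
#' @param cfg A [plm_config()].
#' @return PLM value in `[0, 1]`.
#' @export
plm_pair <- function(phase_i, phase_j, fs, cfg = plm_config()) {
  if (length(phase_i) != length(phase_j)) {
    stop_invalid("phase vectors differ in length (%d vs %d)",
                 length(phase_i), length(phase_j))
  }
  assert_finite(phase_i, "phase_i")
  assert_finite(phase_j, "phase_j")
  d <- phase_i - phase_j
  # canonical sign: PLM is invariant under d -> -d (mirrored spectrum,
  # symmetric integration band); flipping to a canonical orientation makes
  # plm_pair(x, y) and plm_pair(y, x) bit-identical, not just equal in
  # exact arithmetic
  nz <- which(d != 0)
  if (length(nz) > 0 && d[nz[1]] < 0) d <- -d
  z <- exp(1i * d)
  psd <- switch(cfg$spectral_estimator,
    periodogram = periodogram_psd(z),
    welch = welch_psd(z, seg_len = as.integer(round(cfg$welch_segment_s * fs)))
  )
  plm_from_psd(psd, fs, cfg$B, cfg$discard_dc)
}

#' Per-subject PLM connectivity matrix
#'
#' Computes [plm_pair()] for every unordered region pair of a
#' `phase_series`. Flagged edge samples are dropped first. The result is a
#' symmetric nonnegative matrix with zero diagonal and entries in `[0, 1]`.
#' With `cfg$epoch_s` set, the record is split into non-overlapping epochs
#' and the per-epoch matrices averaged.
#'
#' @param phases A `phase_series` from [instantaneous_phase()].
#' @param cfg A [plm_config()].
#' @param band Optional band name stored with the matrix.
#' @return A `conn_matrix`: numeric matrix with attributes `band` and
#'   region labels as dimnames.
#' @export
plm_matrix <- function(phases, cfg = plm_config(), band = NA_character_) {
  stopifnot(inherits(phases, "phase_series"))
  ph <- trim_edges(phases)
  N <- nrow(ph$phases)
  if (N < 2L) stop_invalid("need at least 2 regions")
  Tn <- ncol(ph$phases)
  if (!is.null(cfg$epoch_s)) {
    len <- as.integer(round(cfg$epoch_s * ph$fs))
    n_ep <- Tn %/% len
    if (n_ep < 1L) stop_invalid("record shorter than one epoch (%g s)", cfg$epoch_s)
    acc <- matrix(0, N, N)
    for (k in seq_len(n_ep)) {
      cols <- ((k - 1L) * len + 1L):(k * len)
      acc <- acc + plm_matrix_full(ph$phases[, cols, drop = FALSE], ph$fs, cfg)
    }
    A <- acc / n_ep
  } else {
    A <- plm_matrix_full(ph$phases, ph$fs, cfg)
  }
  dimnames(A) <- list(ph$region_labels, ph$region_labels)
  conn_matrix(A, band = band)
}

# All-pairs PLM on a raw phase matrix (rows = regions).
plm_matrix_full <- function(phase_mat, fs, cfg) {
  N <- nrow(phase_mat)
  A <- matrix(0, N, N)
  for (i in seq_len(N - 1L)) {
    for (j in (i + 1L):N) {
      v <- plm_pair(phase_mat[i, ], phase_mat[j, ], fs, cfg)
      A[i, j] <- v
      A[j, i] <- v
    }
  }
  A
}

#' Construct / validate a connectivity matrix
#'
#' @param A Symmetric nonnegative matrix, entries in `[0, 1]`, zero diagonal.
#' @param band Band name stored as an attribute.
#' @return `A` with class `conn_matrix`.
#' @export
conn_matrix <- function(A, band = NA_character_) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stop_invalid("connectivity matrix must be square")
  assert_finite(A, "connectivity matrix")
  if (max(abs(A - t(A))) > 1e-12) stop_invalid("connectivity matrix must be symmetric")
  if (any(A < 0) || any(A > 1)) {
    stop_invalid("connectivity entries must lie in [0, 1] (range %g..%g)",
                 min(A), max(A))
  }
  if (any(diag(A) != 0)) stop_invalid("connectivity diagonal must be zero")
  attr(A, "band") <- band
  class(A) <- c("conn_matrix", class(A))
  A
}

#' Write a connectivity matrix as labelled CSV
#' @param A A `conn_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_conn_matrix <- function(A, path) {
  df <- data.frame(region_label = rownames(A), unclass(A),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a connectivity matrix written by [write_conn_matrix()]
#' @param path File path.
#' @param band Band name to attach.
#' @return A `conn_matrix`.
#' @export
read_conn_matrix <- function(path, band = NA_character_) {
  df <- utils::read.csv(path, check.names = FALSE)
  A <- as.matrix(df[, -1, drop = FALSE])
  rownames(A) <- df[[1]]
  conn_matrix(A, band = band)
}
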