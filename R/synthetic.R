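#' Specification of a synthetic cohort
#'
#' Defines the generative conditions for a two-group cohort of source-level
#' region signals. Each subject is a set of noisy phase oscillators running
#' at the carrier frequency, pulled toward a shared driver phase with
#' per-region strength `k`. Hub regions of PD-like subjects receive an
#' additive coupling increment (`effect_size`, optionally heterogeneous
#' across subjects via `effect_sd`), planting a hub-strength increase that
#' propagates through PLM connectivity into eigenvector centrality. Pseudo
#' clinical scores are generated as an affine function of each subject's
#' realized increment plus Gaussian noise, so score-centrality correlations
#' are recoverable by construction.
#'
#' @param n_pd,n_hc Group sizes (each at least 2). Defaults 47 + 47.
#' @param atlas Partition data.frame (`region_label`, `group`) defining the
#'   simulated regions; defaults to the full 90-region
#'   [default_lobe_partition()]. Use [reduced_atlas()] for fast studies.
#' @param fs Sampling rate in Hz (default 256).
#' @param duration_s Seconds of signal per subject (default 60).
#' @param carrier_band Two-element `(low, high)` in Hz of the oscillation
#'   carrying the effect (default alpha, `c(8, 13)`); `fs` must exceed
#'   twice its upper edge.
#' @param base_coupling Baseline driver-coupling strength `k` in `[0, 1)`
#'   shared by all regions (default 0.2).
#' @param hub_regions Labels receiving the planted increment; default all
#'   frontal regions of `atlas`.
#' @param effect_size Mean additive coupling increment for hub regions of
#'   PD-like subjects; `base_coupling + effect_size` must stay below 1.
#' @param effect_sd Between-subject SD of the realized increment
#'   (default 0.15), making score-centrality correlations recoverable.
#' @param score_noise_sd SD of pseudo-UPDRS-III noise (default 3).
#' @param seed Master seed; all per-subject seeds derive from it.
#' @param freq_jitter Half-width in Hz of the fixed per-region carrier
#'   detuning pattern (default 2). Detuning keeps uncoupled region pairs
#'   incoherent; the per-region offsets are a fixed property of the atlas
#'   so that group contrasts are not washed out by subject-level
#'   frequency reshuffling.
#' @param phase_noise_sd Phase diffusion in rad/sqrt(s) (default 2).
#' @param driver_noise_sd Driver phase diffusion in rad/sqrt(s)
#'   (default 0.5).
#' @param coupling_rate_hz Rate scale of the coupling pull: a region with
#'   strength `k` relaxes toward the driver at `2*pi*coupling_rate_hz*k`
#'   rad/s (default 4).
#' @param background_amp Amplitude of 1/f background noise relative to the
#'   unit-amplitude oscillation (default 0.5).
#' @param subject_jitter Half-width in Hz of the additional per-subject
#'   carrier jitter (default 0.25).
#' @return A validated `cohort_spec` list.
#' @export
cohort_spec <- function(n_pd = 47, n_hc = 47,
                        atlas = default_lobe_partition(),
                        fs = 256, duration_s = 60,
                        carrier_band = c(8, 13),
                        base_coupling = 0.2,
                        hub_regions = NULL,
                        effect_size = 0.3,
                        effect_sd = 0.15,
                        score_noise_sd = 3,
                        seed = 1,
                        freq_jitter = 2,
                        phase_noise_sd = 2,
                        driver_noise_sd = 0.5,
                        coupling_rate_hz = 4,
                        background_amp = 0.5,
                        subject_jitter = 0.25) {
  atlas <- validate_partition(atlas)
  labels <- atlas$region_label
  if (anyDuplicated(labels)) stop_invalid("duplicate region labels in atlas")
  if (is.null(hub_regions)) {
    hub_regions <- labels[atlas$group == "frontal"]
  }
  if (n_pd < 2 || n_hc < 2) stop_invalid("n_pd and n_hc must both be >= 2")
  if (length(carrier_band) != 2 || carrier_band[1] <= 0 ||
      carrier_band[2] <= carrier_band[1]) {
    stop_invalid("carrier_band must be (low, high) with 0 < low < high")
  }
  if (fs <= 2 * carrier_band[2]) {
    stop_invalid("fs = %g Hz must exceed twice the carrier upper edge (%g Hz)",
                 fs, carrier_band[2])
  }
  if (base_coupling < 0 || effect_size < 0 ||
      base_coupling + effect_size >= 1) {
    stop_invalid("need 0 <= base_coupling + effect_size < 1 (got %g + %g)",
                 base_coupling, effect_size)
  }
  bad <- setdiff(hub_regions, labels)
  if (length(bad) > 0) {
    stop_invalid("hub_regions not in region label set: %s",
                 paste(bad, collapse = ", "))
  }
  if (duration_s < 10) stop_invalid("duration_s must be at least 10 s")
  if (score_noise_sd < 0 || effect_sd < 0) {
    stop_invalid("noise standard deviations must be nonnegative")
  }
  structure(list(
    n_pd = as.integer(n_pd), n_hc = as.integer(n_hc),
    atlas = atlas, region_labels = labels,
    n_regions = length(labels),
    fs = fs, duration_s = duration_s,
    carrier_band = carrier_band,
    base_coupling = base_coupling,
    hub_regions = hub_regions,
    effect_size = effect_size, effect_sd = effect_sd,
    score_noise_sd = score_noise_sd,
    seed = as.integer(seed),
    freq_jitter = freq_jitter,
    phase_noise_sd = phase_noise_sd,
    driver_noise_sd = driver_noise_sd,
    coupling_rate_hz = coupling_rate_hz,
    background_amp = background_amp,
    subject_jitter = subject_jitter
  ), class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(paste0(
    "<cohort_spec> %d PD-like + %d HC-like, %d regions @ %g Hz, %g s\n",
    "  carrier %g-%g Hz, base coupling %g, effect %g (sd %g) on %d hub regions\n"),
    x$n_pd, x$n_hc, x$n_regions, x$fs, x$duration_s,
    x$carrier_band[1], x$carrier_band[2], x$base_coupling,
    x$effect_size, x$effect_sd, length(x$hub_regions)))
  invisible(x)
}

# 1/f-amplitude background noise, unit variance, length n.
pink_noise <- function(n, fs) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  k <- seq_len(n) - 1L
  freq <- pmin(k, n - k) * fs / n
  amp <- 1 / sqrt(pmax(freq, 0.5))  # flatten below 0.5 Hz
  amp[1] <- 0                        # no DC
  x <- Re(stats::fft(W * amp, inverse = TRUE) / n)
  x / stats::sd(x)
}

#' Simulate one subject's region signals
#'
#' Integrates the stochastic coupled-phase model with the Euler-Maruyama
#' scheme: region `i`'s phase advances at its (jittered) carrier frequency,
#' is pulled toward the shared driver phase at rate
#' `2*pi*coupling_rate_hz*k_i*sin(psi - phi_i)`, and diffuses with
#' `phase_noise_sd`. The emitted signal is `cos(phi_i)` plus scaled 1/f
#' background noise. Hub regions of PD-like subjects use
#' `k = base_coupling + effect_realized`; everyone else `k = base_coupling`.
#'
#' @param spec A [cohort_spec()].
#' @param record One-row data.frame with at least `group` and
#'   `effect_realized` (see [generate_cohort()]).
#' @param seed Integer seed; output is deterministic given `(spec, record,
#'   seed)`.
#' @return A [source_ts()] of size `n_regions x (duration_s * fs)`.
#' @export
simulate_subject <- function(spec, record, seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!all(c("group", "effect_realized") %in% names(record))) {
    stop_invalid("record needs fields 'group' and 'effect_realized'")
  }
  N <- spec$n_regions
  Tn <- as.integer(round(spec$duration_s * spec$fs))
  dt <- 1 / spec$fs
  f0 <- mean(spec$carrier_band)
  k <- rep(spec$base_coupling, N)
  if (identical(as.character(record$group), "PD")) {
    hub <- spec$region_labels %in% spec$hub_regions
    k[hub] <- pmin(k[hub] + record$effect_realized, 1 - 1e-6)
  }
  g <- 2 * pi * spec$coupling_rate_hz * k   # pull rate, rad/s
  # Fixed per-region carrier offsets: evenly spaced across +/- freq_jitter,
  # assigned in a fixed shuffled order so no lobe gets systematically fast
  # or slow oscillators. Regional peak frequency is a property of the
  # atlas, not of the subject; subjects add only a small personal jitter.
  region_offset <- if (N > 1) {
    ord <- with_seed(7L, sample.int(N))
    spec$freq_jitter * (2 * (ord - 0.5) / N - 1)
  } else 0

  with_seed(seed, {
    f_i <- f0 + region_offset +
      stats::runif(N, -spec$subject_jitter, spec$subject_jitter)
    phi <- matrix(0, N, Tn)
    phi[, 1] <- stats::runif(N, 0, 2 * pi)
    psi <- cumsum(c(stats::runif(1, 0, 2 * pi),
                    2 * pi * f0 * dt +
                      spec$driver_noise_sd * sqrt(dt) * stats::rnorm(Tn - 1L)))
    noise <- matrix(stats::rnorm(N * (Tn - 1L)), N, Tn - 1L) *
      (spec$phase_noise_sd * sqrt(dt))
    drift <- 2 * pi * f_i * dt
    for (t in seq_len(Tn - 1L)) {
      phi[, t + 1L] <- phi[, t] + drift +
        g * sin(psi[t] - phi[, t]) * dt + noise[, t]
    }
    sig <- cos(phi)
    if (spec$background_amp > 0) {
      for (i in seq_len(N)) {
        sig[i, ] <- sig[i, ] + spec$background_amp * pink_noise(Tn, spec$fs)
      }
    }
    source_ts(sig, spec$fs, spec$region_labels)
  })
}

#' Attach pseudo clinical scores to a cohort table
#'
#' PD-like subjects get `updrs3 = 12 + 45 * effect_realized + noise`
#' (truncated at 0, noise SD = `spec$score_noise_sd`) and a disease
#' duration `2 + 10 * effect_realized + noise` years (SD 1.5, floor 0.5);
#' HC-like subjects get `updrs3 = 0` and no duration. The affine link makes
#' the score-centrality correlation recoverable whenever the planted effect
#' is heterogeneous (`effect_sd > 0`).
#'
#' @param records Cohort data.frame with `group` and `effect_realized`.
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @return `records` with `updrs3` and `disease_duration` filled in.
#' @export
assign_clinical_scores <- function(records, spec, seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  pd <- records$group == "PD"
  if (any(pd & !is.finite(records$effect_realized))) {
    stop_invalid("PD-like records must have effect_realized set")
  }
  with_seed(seed, {
    n_pd <- sum(pd)
    records$updrs3 <- 0
    records$updrs3[pd] <- pmax(
      0, 12 + 45 * records$effect_realized[pd] +
        stats::rnorm(n_pd, 0, spec$score_noise_sd))
    records$disease_duration <- NA_real_
    records$disease_duration[pd] <- pmax(
      0.5, 2 + 10 * records$effect_realized[pd] + stats::rnorm(n_pd, 0, 1.5))
  })
  records
}

#' Generate a full synthetic cohort
#'
#' Builds the cohort table (ids, groups, sex at the 30:17 male:female ratio
#' of the emulated study, age ~ N(65, 9.7), realized effects, pseudo
#' clinical scores) and simulates every subject's signals. Per-subject
#' seeds derive deterministically from `spec$seed`, so a cohort is
#' reproducible subject by subject.
#'
#' @param spec A [cohort_spec()].
#' @return List with `cohort` (data.frame: subject_id, group, sex, age,
#'   updrs3, disease_duration, effect_realized) and `signals` (named list
#'   of [source_ts()], one per subject).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_pd + spec$n_hc
  group <- rep(c("PD", "HC"), c(spec$n_pd, spec$n_hc))
  sex_for <- function(m) {          # deterministic ~30:17 M:F split
    n_m <- round(m * 30 / 47)
    rep(c("M", "F"), c(n_m, m - n_m))
  }
  records <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    group = group,
    sex = c(sex_for(spec$n_pd), sex_for(spec$n_hc)),
    stringsAsFactors = FALSE
  )
  records <- with_seed(derive_seed(spec$seed, 0L), {
    records$age <- round(pmax(40, stats::rnorm(n, 65, 9.7)), 1)
    eff <- pmax(0, stats::rnorm(spec$n_pd, spec$effect_size, spec$effect_sd))
    eff <- pmin(eff, 1 - spec$base_coupling - 1e-6)
    records$effect_realized <- 0
    records$effect_realized[records$group == "PD"] <- eff
    records
  })
  records <- assign_clinical_scores(records, spec,
                                    seed = derive_seed(spec$seed, 1L))
  signals <- lapply(seq_len(n), function(i) {
    simulate_subject(spec, records[i, ], seed = derive_seed(spec$seed, i + 1L))
  })
  names(signals) <- records$subject_id
  list(cohort = records, signals = signals)
}

#' Write a cohort table as CSV
#' @param cohort Cohort data.frame from [generate_cohort()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(cohort, path) {
  cols <- c("subject_id", "group", "sex", "age", "updrs3", "disease_duration")
  utils::write.csv(cohort[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate a cohort table CSV
#' @param path CSV with header
#'   `subject_id,group,sex,age,updrs3,disease_duration`.
#' @return Cohort data.frame.
#' @export
read_cohort_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "updrs3")
  if (!all(need %in% names(df))) {
    stop_invalid("cohort table must contain columns %s",
                 paste(need, collapse = ", "))
  }
  bad <- setdiff(unique(df$group), c("PD", "HC"))
  if (length(bad) > 0) {
    stop_invalid("group labels outside {PD, HC}: %s", paste(bad, collapse = ", "))
  }
  if (anyDuplicated(df$subject_id)) stop_invalid("duplicate subject ids")
  df
}
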