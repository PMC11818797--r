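phase_ramp <- function(freq, fs = 256, dur = 60, phi0 = 0) {
  2 * pi * freq * seq(0, dur - 1 / fs, by = 1 / fs) + phi0
}

test_that("tones offset by less than B give near-perfect PLM", {
  fs <- 256
  p <- plm_pair(phase_ramp(10, fs), phase_ramp(10.5, fs), fs)
  expect_gte(p, 0.95)
})

test_that("independent random-walk phases give near-zero PLM", {
  fs <- 256
  vals <- vapply(1:20, function(s) {
    withr::with_seed(s, {
      walk <- function() cumsum(2 * pi * 10 / fs +
                                  rnorm(fs * 20, 0, 0.8))
      plm_pair(walk(), walk(), fs)
    })
  }, numeric(1))
  expect_lt(mean(vals), 0.1)
})

test_that("PLM is symmetric and bounded in [0, 1]", {
  fs <- 128
  withr::with_seed(42, {
    for (i in 1:5) {
      x <- cumsum(rnorm(fs * 15, 2 * pi * 9 / fs, 0.2))
      y <- cumsum(rnorm(fs * 15, 2 * pi * 11 / fs, 0.2))
      pxy <- plm_pair(x, y, fs)
      pyx <- plm_pair(y, x, fs)
      expect_identical(pxy, pyx)
      expect_gte(pxy, 0)
      expect_lte(pxy, 1)
    }
  })
})

test_that("PLM is invariant to positive rescaling of the source signals", {
  fs <- 128
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  raw <- rbind(cos(2 * pi * 10 * t) + 0.3 * withr::with_seed(1, rnorm(length(t))),
               cos(2 * pi * 10.6 * t) + 0.3 * withr::with_seed(2, rnorm(length(t))))
  p1 <- instantaneous_phase(source_ts(raw, fs, c("a", "b")))
  p2 <- instantaneous_phase(source_ts(raw * c(3, 0.2), fs, c("a", "b")))
  expect_equal(plm_pair(p1$phases[1, ], p1$phases[2, ], fs),
               plm_pair(p2$phases[1, ], p2$phases[2, ], fs),
               tolerance = 1e-12)
})

test_that("identical phases (instantaneous mixing) score 0, not 1", {
  fs <- 128
  ph <- cumsum(rnorm(fs * 15, 2 * pi * 10 / fs, 0.1))
  expect_warning(p <- plm_pair(ph, ph, fs), "degenerate")
  expect_identical(p, 0)
})

test_that("plm_matrix equals the entrywise plm_pair loop and is valid", {
  fs <- 128
  spec <- mini_spec(3, effect_size = 0.6, effect_sd = 0)
  rec <- data.frame(group = "PD", effect_realized = 0.6)
  ts <- simulate_subject(spec, rec, seed = 11)
  ph <- instantaneous_phase(bandpass_filter(ts, 8, 13))
  A <- plm_matrix(ph, band = "alpha")

  expect_true(isSymmetric(unclass(A)))
  expect_true(all(diag(A) == 0))
  expect_gte(min(A), 0)
  expect_lte(max(A), 1)
  expect_identical(attr(A, "band"), "alpha")

  trimmed <- plmnet:::trim_edges(ph)
  cfg <- plm_config()
  for (idx in list(c(1, 2), c(3, 7), c(5, 12))) {
    expect_identical(A[idx[1], idx[2]],
                     plm_pair(trimmed$phases[idx[1], ],
                              trimmed$phases[idx[2], ], fs, cfg))
  }
})

test_that("a single strongly coupled pair dominates a 3-region matrix", {
  atlas3 <- data.frame(
    region_label = c("Precentral_L", "Insula_L", "Thalamus_L"),
    group = c("frontal", "insular", "subcortical"))
  hubs <- atlas3$region_label[1:2]
  top_is_pair <- vapply(1:20, function(s) {
    spec <- cohort_spec(n_pd = 2, n_hc = 2, atlas = atlas3, fs = 128,
                        duration_s = 20, base_coupling = 0,
                        effect_size = 0.9, effect_sd = 0,
                        hub_regions = hubs, seed = 1)
    rec <- data.frame(group = "PD", effect_realized = 0.9)
    ts <- simulate_subject(spec, rec, seed = s)
    A <- plm_matrix(instantaneous_phase(bandpass_filter(ts, 8, 13)))
    A[hubs[1], hubs[2]] > max(A[hubs[1], 3], A[hubs[2], 3])
  }, logical(1))
  expect_gte(mean(top_is_pair), 0.9)
})

test_that("periodogram and Welch estimators rank pairs consistently", {
  spec <- mini_spec(5)
  rec <- data.frame(group = "PD", effect_realized = 0.3)
  ts <- simulate_subject(spec, rec, seed = 7)
  ph <- instantaneous_phase(bandpass_filter(ts, 8, 13))
  A_per <- plm_matrix(ph, plm_config(spectral_estimator = "periodogram"))
  A_wel <- plm_matrix(ph, plm_config(spectral_estimator = "welch",
                                     welch_segment_s = 4))
  rho <- cor(A_per[upper.tri(A_per)], A_wel[upper.tri(A_wel)],
             method = "spearman")
  expect_gt(rho, 0.9)
})

test_that("epoch-averaged matrices stay valid and close to full-record PLM", {
  spec <- mini_spec(9)
  rec <- data.frame(group = "HC", effect_realized = 0)
  ts <- simulate_subject(spec, rec, seed = 3)
  ph <- instantaneous_phase(bandpass_filter(ts, 8, 13))
  A_full <- plm_matrix(ph)
  A_ep <- plm_matrix(ph, plm_config(epoch_s = 6))
  expect_gte(min(A_ep), 0)
  expect_lte(max(A_ep), 1)
  expect_gt(cor(A_full[upper.tri(A_full)], A_ep[upper.tri(A_ep)]), 0.8)
})

test_that("conn_matrix validation catches malformed input", {
  A <- matrix(c(0, 0.5, 0.5, 0), 2)
  expect_s3_class(conn_matrix(A), "conn_matrix")
  expect_error(conn_matrix(matrix(c(0, 2, 2, 0), 2)), "\\[0, 1\\]")
  expect_error(conn_matrix(matrix(c(0, 0.1, 0.6, 0), 2)), "symmetric")
  expect_error(conn_matrix(matrix(c(0.3, 0.1, 0.1, 0), 2)), "diagonal")
})
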