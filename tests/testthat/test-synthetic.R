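test_that("cohort spec validates its invariants", {
  expect_s3_class(mini_spec(1), "cohort_spec")
  expect_error(mini_spec(1, n = 1), "n_pd")
  expect_error(mini_spec(1, effect_size = 0.9), "base_coupling")
  expect_error(cohort_spec(fs = 20, carrier_band = c(8, 13)), "twice")
  expect_error(mini_spec(1, hub_regions = "NotARegion"), "NotARegion")
  expect_error(cohort_spec(n_pd = 2, n_hc = 2, atlas = reduced_atlas(2),
                           fs = 128, duration_s = 5), "10 s")
})

test_that("simulated subjects have the contracted shape and are deterministic", {
  spec <- cohort_spec(n_pd = 2, n_hc = 2, atlas = reduced_atlas(2),
                      fs = 128, duration_s = 10.5)
  rec <- data.frame(group = "PD", effect_realized = 0.3)
  ts1 <- simulate_subject(spec, rec, seed = 5)
  ts2 <- simulate_subject(spec, rec, seed = 5)
  expect_identical(ts1, ts2)
  expect_identical(dim(ts1$data), c(12L, as.integer(10.5 * 128)))
  expect_true(all(is.finite(ts1$data)))
  expect_identical(ts1$region_labels, spec$region_labels)

  ts3 <- simulate_subject(spec, rec, seed = 6)
  expect_false(identical(ts1$data, ts3$data))
})

test_that("with no planted effect PD-like and HC-like share the generative law", {
  spec <- mini_spec(1, effect_size = 0, effect_sd = 0)
  pd <- simulate_subject(spec, data.frame(group = "PD", effect_realized = 0),
                         seed = 9)
  hc <- simulate_subject(spec, data.frame(group = "HC", effect_realized = 0),
                         seed = 9)
  expect_identical(pd$data, hc$data)
})

test_that("clinical scores follow the affine law in the planted effect", {
  spec <- mini_spec(1, effect_sd = 0.15, score_noise_sd = 0)
  rec <- data.frame(group = rep(c("PD", "HC"), each = 5),
                    effect_realized = c(seq(0.1, 0.5, by = 0.1), rep(0, 5)))
  out <- assign_clinical_scores(rec, spec, seed = 3)
  pd <- out$group == "PD"
  expect_equal(cor(out$updrs3[pd], out$effect_realized[pd]), 1)
  expect_true(all(out$updrs3[!pd] == 0))
  expect_true(all(is.na(out$disease_duration[!pd])))
  expect_true(all(out$disease_duration[pd] > 0))

  # noise-dominated limit: correlation collapses toward zero
  spec_noisy <- mini_spec(1, score_noise_sd = 1e6)
  rs <- vapply(1:30, function(s) {
    o <- assign_clinical_scores(rec, spec_noisy, seed = s)
    suppressWarnings(cor(o$updrs3[pd], o$effect_realized[pd]))
  }, numeric(1))
  expect_lt(abs(mean(rs, na.rm = TRUE)), 0.3)
})

test_that("generated cohorts have the study's size, structure, and determinism", {
  spec <- cohort_spec(n_pd = 47, n_hc = 47, atlas = reduced_atlas(2),
                      fs = 128, duration_s = 10, seed = 2)
  # cohort table only (signals for 94 subjects are exercised at n = 4 below)
  gen <- generate_cohort(spec)
  tab <- gen$cohort
  expect_identical(nrow(tab), 94L)
  expect_identical(sum(tab$group == "PD"), 47L)
  expect_identical(sum(tab$group == "HC"), 47L)
  expect_identical(sum(tab$group == "PD" & tab$sex == "M"), 30L)
  expect_false(anyDuplicated(tab$subject_id) > 0)
  expect_true(all(tab$updrs3[tab$group == "HC"] == 0))
  expect_true(all(tab$updrs3 >= 0 & is.finite(tab$updrs3)))

  spec4 <- cohort_spec(n_pd = 2, n_hc = 2, atlas = reduced_atlas(2),
                       fs = 128, duration_s = 10, seed = 11)
  g1 <- generate_cohort(spec4)
  g2 <- generate_cohort(spec4)
  expect_identical(g1, g2)
  expect_identical(length(g1$signals), 4L)
  expect_true(all(vapply(g1$signals, function(s)
    identical(dim(s$data), c(12L, 1280L)), logical(1))))
})

test_that("mean frontal centrality is non-decreasing in the planted effect", {
  frontal_ec <- function(effect, seed) {
    spec <- mini_spec(1, effect_size = effect, effect_sd = 0)
    rec <- data.frame(group = "PD", effect_realized = effect)
    ts <- simulate_subject(spec, rec, seed)
    r <- subject_centrality(ts, mini_bands(), partition = spec$atlas)
    r$lobes$ec_mean[r$lobes$lobe == "frontal"]
  }
  means <- vapply(c(0, 0.3, 0.6), function(eff) {
    mean(vapply(1:50, function(s) frontal_ec(eff, s), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("cohort tables round-trip through CSV with validation", {
  spec <- cohort_spec(n_pd = 3, n_hc = 3, atlas = reduced_atlas(2),
                      fs = 128, duration_s = 10, seed = 4)
  tab <- generate_cohort(spec)$cohort
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_table(tab, path)
  back <- read_cohort_table(path)
  expect_identical(back$subject_id, tab$subject_id)
  expect_identical(back$group, tab$group)
  expect_equal(back$updrs3, tab$updrs3)

  bad <- tab; bad$group[1] <- "XX"
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort_table(bad, path2)
  expect_error(read_cohort_table(path2), "XX")
})
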