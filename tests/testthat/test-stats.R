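test_that("exhaustive permutation p is exact on a hand-enumerable case", {
  res <- permutation_test(c(1, 2, 3), c(10, 11, 12), seed = 1)
  # C(6,3) = 20 assignments; |mean diff| >= 9 only for the true split
  # and its mirror -> p = 2/20
  expect_true(res$exhaustive)
  expect_identical(res$n_perm, 20L)
  expect_equal(res$p, 0.1)
  expect_equal(res$statistic, 9)
  expect_identical(res$direction, "B_higher")
})

test_that("sampled permutation p agrees with the exhaustive value", {
  exact <- permutation_test(c(1, 2, 3), c(10, 11, 12), seed = 1)$p
  sampled <- permutation_test(c(1, 2, 3), c(10, 11, 12), n_perm = 50000,
                              seed = 7, method = "sampled")$p
  expect_lt(abs(sampled - exact), 0.01)

  # larger case, still enumerable
  withr::with_seed(5, {
    a <- rnorm(6); b <- rnorm(6) + 0.8
  })
  exact <- permutation_test(a, b, seed = 1)$p
  sampled <- permutation_test(a, b, n_perm = 50000, seed = 3,
                              method = "sampled")$p
  expect_lt(abs(sampled - exact), 0.01)
})

test_that("degenerate identical groups give p = 1", {
  res <- permutation_test(c(2, 2, 2), c(2, 2, 2), seed = 1)
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
})

test_that("permutation p-values are calibrated under the null", {
  # two groups from the same distribution, 2000 replicate datasets
  rejections <- withr::with_seed(99, {
    vapply(1:2000, function(i) {
      a <- rnorm(10); b <- rnorm(10)
      permutation_test(a, b, n_perm = 499, seed = i)$p < 0.05
    }, logical(1))
  })
  expect_gte(mean(rejections), 0.03)
  expect_lte(mean(rejections), 0.07)
})

test_that("permutation test rejects invalid input", {
  expect_error(permutation_test(1, c(1, 2)), "at least 2")
  expect_error(permutation_test(c(1, NA, 2), c(1, 2)), "non-finite")
})

test_that("BH step-up matches hand computation and edge cases", {
  res <- bh_fdr(c(0.01, 0.02, 0.03, 0.04, 0.20))
  expect_equal(res$p_adjusted, c(0.05, 0.05, 0.05, 0.05, 0.20))
  expect_identical(res$rejected, c(rep(TRUE, 4), FALSE))

  expect_equal(bh_fdr(0.037)$p_adjusted, 0.037)
  expect_equal(bh_fdr(rep(0.2, 4))$p_adjusted, rep(0.2, 4))
  expect_error(bh_fdr(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_fdr(c(0.5, 1.2)), "\\(0, 1\\]")
})

test_that("BH rejections contain the Bonferroni rejections", {
  withr::with_seed(8, {
    for (i in 1:20) {
      p <- runif(12)^2
      bh <- bh_fdr(p, q = 0.05)$rejected
      bonf <- p <= 0.05 / length(p)
      expect_true(all(bh[bonf]))
    }
  })
})

test_that("Pearson correlation matches closed forms", {
  x <- 1:5
  expect_equal(pearson_correlation(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_correlation(x, -x)$r, -1)
  res <- pearson_correlation(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
  expect_equal(res$r, 0.8)
  # p from the exact t transform with n - 2 df
  tval <- 0.8 * sqrt(3 / (1 - 0.64))
  expect_equal(res$p, 2 * pt(tval, df = 3, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_error(pearson_correlation(c(1, 1, 1), c(1, 2, 3)), "variance")
  expect_error(pearson_correlation(1:2, 2:3), "n >= 3")
})

test_that("group comparison runs per band x lobe with per-band FDR", {
  lt <- expand.grid(subject_id = sprintf("S%02d", 1:12),
                    band = c("alpha", "beta"),
                    lobe = c("frontal", "occipital"),
                    stringsAsFactors = FALSE)
  cohort <- data.frame(subject_id = sprintf("S%02d", 1:12),
                       group = rep(c("PD", "HC"), each = 6),
                       sex = rep(c("M", "M", "M", "M", "F", "F"), 2),
                       updrs3 = c(rnorm(6, 25, 5), rep(0, 6)))
  withr::with_seed(2, lt$ec_mean <- rnorm(nrow(lt), 0.3, 0.02))
  # plant a strong alpha-frontal difference
  sel <- lt$band == "alpha" & lt$lobe == "frontal" &
    lt$subject_id %in% cohort$subject_id[cohort$group == "PD"]
  lt$ec_mean[sel] <- lt$ec_mean[sel] + 0.2

  res <- run_group_comparison(lt, cohort, n_perm = 2000, seed = 4)
  expect_identical(nrow(res), 4L)
  hit <- res[res$band == "alpha" & res$lobe == "frontal", ]
  expect_identical(hit$direction, "PD_higher")
  expect_true(hit$significant)
  expect_true(all(res$p_fdr >= res$p_raw - 1e-15))
  # determinism
  res2 <- run_group_comparison(lt, cohort, n_perm = 2000, seed = 4)
  expect_identical(res, res2)

  # sex-stratified rerun keeps only one sex
  resM <- run_group_comparison(lt, cohort, n_perm = 500, seed = 4,
                               subgroup = "M")
  expect_true(all(resM$n_pd == 4 & resM$n_hc == 4))
  # empty subgroup rejected
  cohort_allM <- cohort; cohort_allM$sex <- "M"
  expect_error(run_group_comparison(lt, cohort_allM, subgroup = "F"),
               "fewer than 2")
  # missing rows rejected with ids
  expect_error(run_group_comparison(lt[-1, ], cohort, n_perm = 100),
               "S01")
})

test_that("correlations are restricted to significant cells by default", {
  lt <- expand.grid(subject_id = sprintf("S%02d", 1:12),
                    band = "alpha", lobe = c("frontal", "occipital"),
                    stringsAsFactors = FALSE)
  cohort <- data.frame(subject_id = sprintf("S%02d", 1:12),
                       group = rep(c("PD", "HC"), each = 6),
                       updrs3 = 0, disease_duration = NA_real_)
  withr::with_seed(6, {
    lt$ec_mean <- rnorm(nrow(lt), 0.3, 0.01)
    pdsel <- cohort$group == "PD"
    cohort$updrs3[pdsel] <- rnorm(6, 25, 6)
    cohort$disease_duration[pdsel] <- runif(6, 1, 10)
  })
  cmp <- data.frame(band = "alpha", lobe = c("frontal", "occipital"),
                    significant = c(TRUE, FALSE))
  res <- run_correlations(lt, cohort, comparison = cmp)
  expect_identical(unique(res$lobe), "frontal")
  expect_setequal(res$variable, c("updrs3", "disease_duration"))
  expect_true(all(abs(res$r) <= 1))
  expect_true(all(res$n == 6))

  all_cells <- run_correlations(lt, cohort, comparison = NULL)
  expect_identical(nrow(all_cells), 4L)
})
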