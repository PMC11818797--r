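# Shared fixtures for Monte-Carlo studies at desk scale: 10+10 subjects,
# 12 regions (two per lobe), 20 s at 128 Hz, alpha band only, 999
# permutations per test. Heavy runs are computed once per session and
# cached, so the calibration tests and the property tests share them.

mini_bands <- function() data.frame(name = "alpha", low = 8, high = 13,
                                    stringsAsFactors = FALSE)

mini_spec <- function(seed, effect_size = 0.3, effect_sd = 0.15, n = 10,
                      base_coupling = 0.2, ...) {
  cohort_spec(n_pd = n, n_hc = n, atlas = reduced_atlas(2), fs = 128,
              duration_s = 20, base_coupling = base_coupling,
              effect_size = effect_size, effect_sd = effect_sd,
              seed = seed, ...)
}

# Cohort -> long lobe EC table (carrier band only).
mini_lobe_table <- function(spec) {
  gen <- generate_cohort(spec)
  lob <- vector("list", length(gen$signals))
  for (i in seq_along(gen$signals)) {
    r <- subject_centrality(gen$signals[[i]], mini_bands(),
                            partition = spec$atlas)
    r$lobes$subject_id <- gen$cohort$subject_id[i]
    lob[[i]] <- r$lobes
  }
  list(cohort = gen$cohort, lobe_table = do.call(rbind, lob))
}

# One simulated cohort through connectivity, centrality and statistics.
mini_cohort_run <- function(seed, effect_size = 0.3, effect_sd = 0.15,
                            n_perm = 999) {
  spec <- mini_spec(seed, effect_size, effect_sd)
  mt <- mini_lobe_table(spec)
  cmp <- run_group_comparison(mt$lobe_table, mt$cohort, n_perm = n_perm,
                              seed = seed)
  cor <- run_correlations(mt$lobe_table, mt$cohort, comparison = NULL)
  list(cmp = cmp, cor = cor)
}

.mc_cache <- new.env(parent = emptyenv())

# 500 null cohorts (no planted effect, no effect heterogeneity): frontal
# raw p per cohort, plus whether BH at q = 0.05 rejected anything.
null_cohort_stats <- function(n_cohorts = 500) {
  key <- paste0("null", n_cohorts)
  if (is.null(.mc_cache[[key]])) {
    front_p <- numeric(n_cohorts)
    any_rejection <- logical(n_cohorts)
    for (s in seq_len(n_cohorts)) {
      run <- mini_cohort_run(s, effect_size = 0, effect_sd = 0)
      front_p[s] <- run$cmp$p_raw[run$cmp$lobe == "frontal"]
      any_rejection[s] <- any(run$cmp$significant)
    }
    .mc_cache[[key]] <- list(front_p = front_p,
                             any_rejection = any_rejection)
  }
  .mc_cache[[key]]
}

# 100 cohorts with the calibrated planted effect: FDR-corrected frontal
# significance, whether frontal had the smallest raw p, and the frontal
# EC vs pseudo-UPDRS correlation.
effect_cohort_stats <- function(n_cohorts = 100) {
  key <- paste0("effect", n_cohorts)
  if (is.null(.mc_cache[[key]])) {
    frontal_sig <- logical(n_cohorts)
    frontal_minp <- logical(n_cohorts)
    r_updrs <- numeric(n_cohorts)
    for (s in seq_len(n_cohorts)) {
      run <- mini_cohort_run(s)
      frontal_sig[s] <- run$cmp$significant[run$cmp$lobe == "frontal"]
      frontal_minp[s] <-
        which.min(run$cmp$p_raw) == which(run$cmp$lobe == "frontal")
      r_updrs[s] <- run$cor$r[run$cor$lobe == "frontal" &
                                run$cor$variable == "updrs3"]
    }
    .mc_cache[[key]] <- list(frontal_sig = frontal_sig,
                             frontal_minp = frontal_minp,
                             r_updrs = r_updrs)
  }
  .mc_cache[[key]]
}

# Random symmetric nonnegative matrix with zero diagonal.
random_conn <- function(n, max_val = 1) {
  A <- matrix(stats::runif(n * n, 0, max_val), n)
  A <- (A + t(A)) / 2
  diag(A) <- 0
  A
}
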