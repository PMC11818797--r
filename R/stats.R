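#' Two-group permutation test on the absolute mean difference
#'
#' The statistic is `|mean(a) - mean(b)|`, compared to its distribution
#' under random relabelling of the pooled observations. When the number of
#' distinct group-A assignments `choose(n, n_a)` does not exceed `n_perm`
#' the null distribution is enumerated exhaustively and the p-value is the
#' exact proportion of assignments with a statistic at least as large as
#' the observed one; otherwise `n_perm` random relabellings are drawn and
#' `p = (1 + #{surrogate >= observed}) / (1 + n_perm)` (the add-one
#' smoothing guarantees `p > 0`; set `smooth = FALSE` for the plain
#' proportion).
#'
#' Two-sidedness is inherent in the absolute-difference statistic; the
#' direction of the observed difference is reported separately.
#'
#' @param values_a,values_b Numeric vectors, each with at least 2 finite
#'   observations.
#' @param n_perm Number of random relabellings (default 50000).
#' @param seed Integer seed for the relabelling draws.
#' @param smooth Add-one smoothing for the sampled p (default TRUE).
#' @param method `"auto"` (exhaustive when feasible), `"exhaustive"`
#'   (error if `choose(n, n_a) > n_perm`), or `"sampled"` (always draw
#'   `n_perm` relabellings).
#' @return List with `statistic`, `p`, `direction` (`"A_higher"` /
#'   `"B_higher"`), `n_perm` (permutations used), `exhaustive` (logical),
#'   `seed`.
#' @examples
#' permutation_test(c(1, 2, 3), c(10, 11, 12), seed = 1)$p  # exact: 0.1
#' @export
permutation_test <- function(values_a, values_b, n_perm = 50000, seed = 1,
                             smooth = TRUE,
                             method = c("auto", "exhaustive", "sampled")) {
  method <- match.arg(method)
  values_a <- as.numeric(values_a); values_b <- as.numeric(values_b)
  if (length(values_a) < 2 || length(values_b) < 2) {
    stop_invalid("each group needs at least 2 observations")
  }
  assert_finite(values_a, "values_a"); assert_finite(values_b, "values_b")
  pooled <- c(values_a, values_b)
  n_a <- length(values_a); n <- length(pooled)
  mean_a <- mean(values_a); mean_b <- mean(values_b)
  observed <- abs(mean_a - mean_b)
  total <- sum(pooled); tol <- 1e-12 * max(1, observed)

  # |mean(a)-mean(b)| as a function of sum(a) only
  stat_from_suma <- function(sa) {
    abs(sa / n_a - (total - sa) / (n - n_a))
  }
  n_comb <- choose(n, n_a)
  use_exhaustive <- switch(method,
    auto = n_comb <= n_perm,
    exhaustive = if (n_comb > n_perm) {
      stop_invalid("exhaustive enumeration infeasible: %g assignments > n_perm", n_comb)
    } else TRUE,
    sampled = FALSE)
  if (use_exhaustive) {
    idx <- utils::combn(n, n_a)
    sums <- colSums(matrix(pooled[idx], nrow = n_a))
    stats <- stat_from_suma(sums)
    p <- sum(stats >= observed - tol) / n_comb
    used <- as.integer(n_comb); exhaustive <- TRUE
  } else {
    stats <- with_seed(seed, {
      vapply(seq_len(n_perm),
             function(i) stat_from_suma(sum(pooled[sample.int(n, n_a)])),
             numeric(1))
    })
    hits <- sum(stats >= observed - tol)
    p <- if (smooth) (1 + hits) / (1 + n_perm) else hits / n_perm
    used <- as.integer(n_perm); exhaustive <- FALSE
  }
  list(statistic = observed, p = p,
       direction = if (mean_a >= mean_b) "A_higher" else "B_higher",
       n_perm = used, exhaustive = exhaustive, seed = as.integer(seed))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (via [stats::p.adjust()]) with rejection flags
#' at level `q`.
#'
#' @param p_values Numeric p-values in `(0, 1]`.
#' @param q FDR level (default 0.05).
#' @return List with `p_adjusted` and logical `rejected`.
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  p_values <- as.numeric(p_values)
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    stop_invalid("p-values must lie in (0, 1]")
  }
  adj <- stats::p.adjust(p_values, method = "BH")
  list(p_adjusted = adj, rejected = adj <= q)
}

#' Pearson correlation with t-based p-value
#'
#' Sample Pearson r and the two-sided p-value from the t transform with
#' `n - 2` degrees of freedom (via [stats::cor.test()]).
#'
#' @param x,y Numeric vectors, `n >= 3`, finite, nonzero variance.
#' @return List with `r`, `p`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop_invalid("x and y differ in length")
  if (length(x) < 3) stop_invalid("need n >= 3 observations")
  assert_finite(x, "x"); assert_finite(y, "y")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop_invalid("zero-variance input; correlation undefined")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Permutation comparison of lobe centrality between groups
#'
#' Runs one permutation test per (band, lobe) cell of a long-format lobe
#' centrality table and applies Benjamini-Hochberg correction. By default
#' the FDR family is the six lobes within each band (matching per-band
#' reporting); `fdr_family = "global"` corrects across all band x lobe
#' tests at once. An optional sex filter reruns the comparison on one sex.
#'
#' @param lobe_table Data.frame with columns `subject_id`, `band`, `lobe`,
#'   `ec_mean` covering every subject x band x lobe cell.
#' @param cohort Cohort data.frame with `subject_id`, `group`, and (for
#'   subgroup analyses) `sex`.
#' @param bands Bands to test; default all bands present.
#' @param n_perm Permutations per test (default 50000).
#' @param seed Master seed; per-test seeds derive from it.
#' @param subgroup Optional `"M"` or `"F"` filter.
#' @param fdr_family `"band"` (default) or `"global"`.
#' @param q FDR level (default 0.05).
#' @return Data.frame with one row per test: `band`, `lobe`,
#'   `observed_abs_mean_diff`, `p_raw`, `p_fdr`, `significant`,
#'   `direction` (`"PD_higher"`/`"HC_higher"`), `n_pd`, `n_hc`,
#'   `n_permutations`, `seed`.
#' @export
run_group_comparison <- function(lobe_table, cohort, bands = NULL,
                                 n_perm = 50000, seed = 1, subgroup = NULL,
                                 fdr_family = c("band", "global"), q = 0.05) {
  fdr_family <- match.arg(fdr_family)
  need <- c("subject_id", "band", "lobe", "ec_mean")
  if (!all(need %in% names(lobe_table))) {
    stop_invalid("lobe_table must have columns %s", paste(need, collapse = ", "))
  }
  if (!is.null(subgroup)) {
    subgroup <- match.arg(subgroup, c("M", "F"))
    cohort <- cohort[cohort$sex == subgroup, , drop = FALSE]
    if (length(unique(cohort$group[cohort$group == "PD"])) == 0 ||
        sum(cohort$group == "PD") < 2 || sum(cohort$group == "HC") < 2) {
      stop_invalid("subgroup '%s' leaves fewer than 2 subjects in a group",
                   subgroup)
    }
    lobe_table <- lobe_table[lobe_table$subject_id %in% cohort$subject_id, ,
                             drop = FALSE]
  }
  bands <- bands %||% unique(lobe_table$band)
  lobes <- unique(lobe_table$lobe)
  grp <- cohort$group[match(lobe_table$subject_id, cohort$subject_id)]
  if (anyNA(grp)) {
    stop_invalid("subjects missing from cohort table: %s",
                 paste(unique(lobe_table$subject_id[is.na(grp)]), collapse = ", "))
  }
  rows <- list(); idx <- 0L
  for (b in bands) {
    for (lo in lobes) {
      sel <- lobe_table$band == b & lobe_table$lobe == lo
      a <- lobe_table$ec_mean[sel & grp == "PD"]
      h <- lobe_table$ec_mean[sel & grp == "HC"]
      n_expected_pd <- sum(cohort$group == "PD")
      n_expected_hc <- sum(cohort$group == "HC")
      if (length(a) != n_expected_pd || length(h) != n_expected_hc) {
        miss <- setdiff(cohort$subject_id, lobe_table$subject_id[sel])
        stop_invalid("missing lobe EC rows for band %s, lobe %s: %s",
                     b, lo, paste(miss, collapse = ", "))
      }
      idx <- idx + 1L
      test_seed <- derive_seed(seed, idx)
      pt <- permutation_test(a, h, n_perm = n_perm, seed = test_seed)
      rows[[idx]] <- data.frame(
        band = b, lobe = lo,
        observed_abs_mean_diff = pt$statistic,
        p_raw = pt$p,
        direction = if (pt$direction == "A_higher") "PD_higher" else "HC_higher",
        n_pd = length(a), n_hc = length(h),
        n_permutations = pt$n_perm, seed = test_seed,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  if (fdr_family == "band") {
    res$p_fdr <- NA_real_
    for (b in unique(res$band)) {
      sel <- res$band == b
      res$p_fdr[sel] <- bh_fdr(res$p_raw[sel], q)$p_adjusted
    }
  } else {
    res$p_fdr <- bh_fdr(res$p_raw, q)$p_adjusted
  }
  res$significant <- res$p_fdr <= q
  res[, c("band", "lobe", "observed_abs_mean_diff", "p_raw", "p_fdr",
          "significant", "direction", "n_pd", "n_hc", "n_permutations",
          "seed")]
}

#' Correlate lobe centrality with clinical variables
#'
#' Pearson correlation of per-subject lobe EC against clinical scores,
#' within the patient group only. By default only the (band, lobe) cells
#' flagged significant in a prior group comparison are tested (mirroring a
#' follow-up analysis restricted to regions showing a group difference);
#' pass `comparison = NULL` to test every cell. BH correction is applied
#' across all correlations computed.
#'
#' @param lobe_table Long lobe centrality table (see
#'   [run_group_comparison()]).
#' @param cohort Cohort data.frame with `subject_id`, `group`, `updrs3`,
#'   `disease_duration`.
#' @param comparison Result of [run_group_comparison()], or NULL for all
#'   cells.
#' @param variables Clinical columns to correlate (default UPDRS-III and
#'   disease duration).
#' @param q FDR level (default 0.05).
#' @return Data.frame: `band`, `lobe`, `variable`, `r`, `p_raw`, `p_fdr`,
#'   `n`.
#' @export
run_correlations <- function(lobe_table, cohort, comparison = NULL,
                             variables = c("updrs3", "disease_duration"),
                             q = 0.05) {
  pd <- cohort[cohort$group == "PD", , drop = FALSE]
  cells <- if (is.null(comparison)) {
    unique(lobe_table[, c("band", "lobe")])
  } else {
    comparison[comparison$significant, c("band", "lobe"), drop = FALSE]
  }
  if (nrow(cells) == 0) {
    return(data.frame(band = character(), lobe = character(),
                      variable = character(), r = numeric(),
                      p_raw = numeric(), p_fdr = numeric(), n = integer(),
                      stringsAsFactors = FALSE))
  }
  rows <- list(); idx <- 0L
  for (i in seq_len(nrow(cells))) {
    sel <- lobe_table$band == cells$band[i] & lobe_table$lobe == cells$lobe[i]
    sub <- lobe_table[sel, , drop = FALSE]
    ec <- sub$ec_mean[match(pd$subject_id, sub$subject_id)]
    for (v in variables) {
      y <- pd[[v]]
      ok <- is.finite(ec) & is.finite(y)
      if (sum(ok) < 3 || stats::var(y[ok]) == 0) next
      ct <- pearson_correlation(ec[ok], y[ok])
      idx <- idx + 1L
      rows[[idx]] <- data.frame(
        band = cells$band[i], lobe = cells$lobe[i], variable = v,
        r = ct$r, p_raw = ct$p, n = ct$n, stringsAsFactors = FALSE)
    }
  }
  if (idx == 0L) {
    return(data.frame(band = character(), lobe = character(),
                      variable = character(), r = numeric(),
                      p_raw = numeric(), p_fdr = numeric(), n = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, rows)
  res$p_fdr <- bh_fdr(res$p_raw, q)$p_adjusted
  res[, c("band", "lobe", "variable", "r", "p_raw", "p_fdr", "n")]
}
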