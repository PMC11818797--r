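#' Pipeline configuration
#'
#' Bundles everything a full run needs: either a synthetic [cohort_spec()]
#' or paths to real inputs (a directory of per-subject signal files, a
#' cohort CSV, a partition CSV) — exactly one of the two — plus the band
#' set, PLM settings, permutation count, seed, FDR level and output
#' directory.
#'
#' @param out_dir Output directory (created if absent).
#' @param synthetic Optional [cohort_spec()] for a simulated cohort.
#' @param signals_dir Directory of per-subject signal files named
#'   `<subject_id>.csv` (see [write_source_ts()]).
#' @param cohort_csv Cohort metadata CSV (see [read_cohort_table()]).
#' @param partition_csv Lobe partition CSV; default partition used when
#'   omitted with real inputs.
#' @param bands Band table (default [canonical_bands()]).
#' @param plm A [plm_config()].
#' @param n_perm Permutations per test (default 50000).
#' @param seed Master seed for permutation draws.
#' @param q FDR level (default 0.05).
#' @param subgroups Character vector among `c("M", "F")`: sex-stratified
#'   reruns of the group comparison.
#' @param edge_trim_s Seconds trimmed per edge before PLM (default 1).
#' @param correlate_all Correlate every (band, lobe) cell instead of only
#'   the significant ones (default FALSE).
#' @param roi_filter Apply the cerebellar-exclusion filter when the signal
#'   labels come from the AAL-116 set (default TRUE).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            synthetic = NULL,
                            signals_dir = NULL, cohort_csv = NULL,
                            partition_csv = NULL,
                            bands = canonical_bands(),
                            plm = plm_config(),
                            n_perm = 50000, seed = 1, q = 0.05,
                            subgroups = character(),
                            edge_trim_s = 1,
                            correlate_all = FALSE,
                            roi_filter = TRUE) {
  real <- !is.null(signals_dir) || !is.null(cohort_csv)
  synth <- !is.null(synthetic)
  if (real == synth) {
    stop_invalid("provide exactly one of: synthetic spec, or real input paths")
  }
  if (synth) stopifnot(inherits(synthetic, "cohort_spec"))
  if (real) {
    if (is.null(signals_dir) || is.null(cohort_csv)) {
      stop_invalid("real input mode needs both signals_dir and cohort_csv")
    }
    for (p in c(signals_dir, cohort_csv, partition_csv)) {
      if (!is.null(p) && !file.exists(p)) stop_invalid("input path missing: %s", p)
    }
  }
  structure(list(out_dir = out_dir, synthetic = synthetic,
                 signals_dir = signals_dir, cohort_csv = cohort_csv,
                 partition_csv = partition_csv,
                 bands = validate_bands(bands), plm = plm,
                 n_perm = n_perm, seed = as.integer(seed), q = q,
                 subgroups = subgroups, edge_trim_s = edge_trim_s,
                 correlate_all = isTRUE(correlate_all),
                 roi_filter = isTRUE(roi_filter)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; a `synthetic:` block
#' maps to [cohort_spec()] arguments (with `atlas: reduced` /
#' `atlas_n_per_lobe:` selecting [reduced_atlas()]).
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  synthetic <- NULL
  if (!is.null(y$synthetic)) {
    s <- y$synthetic
    if (identical(s$atlas, "reduced")) {
      s$atlas <- reduced_atlas(s$atlas_n_per_lobe %||% 2)
    }
    s$atlas_n_per_lobe <- NULL
    if (!is.null(s$carrier_band)) s$carrier_band <- as.numeric(s$carrier_band)
    synthetic <- do.call(cohort_spec, s)
  }
  bands <- if (is.null(y$bands)) canonical_bands() else
    do.call(rbind, lapply(y$bands, as.data.frame))
  plm <- if (is.null(y$plm)) plm_config() else do.call(plm_config, y$plm)
  pipeline_config(
    out_dir = y$out_dir %||% "plmnet_results",
    synthetic = synthetic,
    signals_dir = y$signals_dir, cohort_csv = y$cohort_csv,
    partition_csv = y$partition_csv,
    bands = bands, plm = plm,
    n_perm = y$n_perm %||% 50000, seed = y$seed %||% 1,
    q = y$q %||% 0.05,
    subgroups = as.character(y$subgroups %||% character()),
    edge_trim_s = y$edge_trim_s %||% 1,
    correlate_all = y$correlate_all %||% FALSE,
    roi_filter = y$roi_filter %||% TRUE)
}

#' Validate pipeline inputs
#'
#' Checks label agreement between signals, partition and cohort table and
#' reports per-file shapes. Returns a report rather than stopping, so all
#' problems surface at once.
#'
#' @param config A [pipeline_config()].
#' @return List with `failures` (character; empty when consistent) and
#'   `info` (per-input summaries).
#' @export
validate_inputs <- function(config) {
  failures <- character(); info <- list()
  if (!is.null(config$synthetic)) {
    spec <- config$synthetic
    info$mode <- "synthetic"
    info$n_subjects <- spec$n_pd + spec$n_hc
    info$n_regions <- spec$n_regions
    missing <- setdiff(spec$region_labels, spec$atlas$region_label)
    if (length(missing) > 0) {
      failures <- c(failures, sprintf("regions missing from partition: %s",
                                      paste(missing, collapse = ", ")))
    }
    return(list(failures = failures, info = info))
  }
  info$mode <- "real"
  cohort <- tryCatch(read_cohort_table(config$cohort_csv),
                     error = function(e) {
                       failures <<- c(failures, conditionMessage(e)); NULL
                     })
  partition <- if (is.null(config$partition_csv)) default_lobe_partition() else
    tryCatch(read_lobe_partition(config$partition_csv),
             error = function(e) {
               failures <<- c(failures, conditionMessage(e)); NULL
             })
  files <- list.files(config$signals_dir, pattern = "\\.csv$",
                      full.names = TRUE)
  info$n_signal_files <- length(files)
  if (!is.null(cohort)) {
    ids <- tools::file_path_sans_ext(basename(files))
    miss <- setdiff(cohort$subject_id, ids)
    if (length(miss) > 0) {
      failures <- c(failures, sprintf("no signal file for subject(s): %s",
                                      paste(miss, collapse = ", ")))
    }
  }
  if (length(files) > 0 && !is.null(partition)) {
    ts <- tryCatch(read_source_ts(files[1]), error = function(e) NULL)
    if (!is.null(ts)) {
      info$first_signal_shape <- dim(ts$data)
      labels <- ts$region_labels
      if (config$roi_filter && all(labels %in% aal116_labels())) {
        labels <- apply_roi_filter(labels)
      }
      miss <- setdiff(labels, partition$region_label)
      if (length(miss) > 0) {
        failures <- c(failures,
                      sprintf("partition missing region(s): %s",
                              paste(miss, collapse = ", ")))
      }
    }
  }
  list(failures = failures, info = info)
}

#' Band-resolved lobe centrality for one subject
#'
#' The per-subject core of the pipeline: band decomposition, phase
#' extraction, PLM matrix, eigenvector centrality, lobe averaging.
#'
#' @param ts A [source_ts()].
#' @param bands Band table.
#' @param plm A [plm_config()].
#' @param partition Partition data.frame.
#' @param edge_trim_s Edge trim passed to [instantaneous_phase()].
#' @return List with `regions` (data.frame band, region_label, ec),
#'   `lobes` (data.frame band, lobe, ec_mean) and `matrices` (named list
#'   of `conn_matrix` per band).
#' @export
subject_centrality <- function(ts, bands = canonical_bands(),
                               plm = plm_config(),
                               partition = default_lobe_partition(),
                               edge_trim_s = 1) {
  by_band <- decompose_bands(ts, bands)
  regions <- list(); lobes <- list(); matrices <- list()
  for (b in names(by_band)) {
    ph <- instantaneous_phase(by_band[[b]], edge_trim_s = edge_trim_s)
    A <- plm_matrix(ph, plm, band = b)
    ec <- eigenvector_centrality(A)
    lv <- lobe_average(ec, partition)
    matrices[[b]] <- A
    regions[[b]] <- data.frame(band = b, region_label = names(ec$scores),
                               ec = unname(ec$scores),
                               stringsAsFactors = FALSE)
    lobes[[b]] <- data.frame(band = b, lobe = names(lv),
                             ec_mean = unname(lv), stringsAsFactors = FALSE)
  }
  list(regions = do.call(rbind, regions), lobes = do.call(rbind, lobes),
       matrices = matrices)
}

#' Run the full pipeline
#'
#' Cohort in (simulated or from disk), statistics out: per-subject, per-band
#' PLM connectivity matrices, region- and lobe-level eigenvector centrality
#' tables, permutation group comparisons with BH-FDR, clinical correlations,
#' a run manifest, and a log. Rerunning with an identical configuration
#' reproduces identical result CSVs.
#'
#' @param config A [pipeline_config()].
#' @param write_matrices Write one CSV per subject x band connectivity
#'   matrix (default FALSE; they are large).
#' @param quiet Suppress progress messages (default TRUE).
#' @return Invisibly, a list with `cohort`, `ec_regions`, `ec_lobes`,
#'   `comparison`, `correlations`, `subgroup_comparisons`, `out_dir`.
#' @export
run_pipeline <- function(config, write_matrices = FALSE, quiet = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  val <- validate_inputs(config)
  if (length(val$failures) > 0) {
    stop_invalid("input validation failed:\n  %s",
                 paste(val$failures, collapse = "\n  "))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  log_lines <- character()
  say <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                    sprintf(fmt, ...))
    log_lines <<- c(log_lines, line)
    if (!quiet) message(line)
  }
  stage_times <- list(started = format(Sys.time()))

  # --- inputs ---------------------------------------------------------
  if (!is.null(config$synthetic)) {
    say("stage simulate: generating %d + %d subjects",
        config$synthetic$n_pd, config$synthetic$n_hc)
    gen <- generate_cohort(config$synthetic)
    cohort <- gen$cohort; signals <- gen$signals
    partition <- config$synthetic$atlas
    digests <- list(synthetic_seed = config$synthetic$seed)
  } else {
    cohort <- read_cohort_table(config$cohort_csv)
    partition <- if (is.null(config$partition_csv)) default_lobe_partition()
                 else read_lobe_partition(config$partition_csv)
    files <- file.path(config$signals_dir,
                       paste0(cohort$subject_id, ".csv"))
    signals <- lapply(files, read_source_ts)
    names(signals) <- cohort$subject_id
    digests <- as.list(tools::md5sum(c(config$cohort_csv, files)))
  }
  stage_times$inputs_ready <- format(Sys.time())

  # --- manifest (written before results) ------------------------------
  manifest <- list(
    package = "plmnet",
    version = as.character(utils::packageVersion("plmnet")),
    config = config_snapshot(config),
    seeds = list(master = config$seed),
    input_digests = digests,
    stage_times = stage_times)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  # --- per-subject connectivity + centrality --------------------------
  regions <- list(); lobes <- list()
  mat_dir <- file.path(config$out_dir, "connectivity")
  if (write_matrices) dir.create(mat_dir, showWarnings = FALSE)
  for (i in seq_along(signals)) {
    sid <- names(signals)[i]
    ts <- signals[[i]]
    if (config$roi_filter && all(ts$region_labels %in% aal116_labels())) {
      keep <- apply_roi_filter(ts$region_labels)
      ts <- source_ts(ts$data[keep, , drop = FALSE], ts$fs, keep)
    }
    res <- tryCatch(
      subject_centrality(ts, config$bands, config$plm, partition,
                         config$edge_trim_s),
      error = function(e) {
        stop_invalid("stage centrality failed for subject %s: %s",
                     sid, conditionMessage(e))
      })
    res$regions$subject_id <- sid
    res$lobes$subject_id <- sid
    regions[[i]] <- res$regions
    lobes[[i]] <- res$lobes
    if (write_matrices) {
      for (b in names(res$matrices)) {
        write_conn_matrix(res$matrices[[b]],
                          file.path(mat_dir, sprintf("%s_%s.csv", sid, b)))
      }
    }
    if (i %% 10 == 0) say("stage connectivity/centrality: %d/%d subjects",
                          i, length(signals))
  }
  ec_regions <- do.call(rbind, regions)[, c("subject_id", "band",
                                            "region_label", "ec")]
  ec_lobes <- do.call(rbind, lobes)[, c("subject_id", "band", "lobe",
                                        "ec_mean")]
  stage_times$centrality_done <- format(Sys.time())
  say("stage centrality: done (%d subjects x %d bands)",
      length(signals), nrow(config$bands))

  # --- statistics -----------------------------------------------------
  comparison <- run_group_comparison(ec_lobes, cohort,
                                     n_perm = config$n_perm,
                                     seed = config$seed, q = config$q)
  correlations <- run_correlations(
    ec_lobes, cohort,
    comparison = if (config$correlate_all) NULL else comparison,
    q = config$q)
  subgroup_comparisons <- list()
  for (sg in config$subgroups) {
    subgroup_comparisons[[sg]] <- run_group_comparison(
      ec_lobes, cohort, n_perm = config$n_perm,
      seed = derive_seed(config$seed, match(sg, c("M", "F")) + 1000L),
      subgroup = sg, q = config$q)
  }
  stage_times$stats_done <- format(Sys.time())
  say("stage stats: %d tests, %d significant after FDR",
      nrow(comparison), sum(comparison$significant))

  # --- outputs --------------------------------------------------------
  wcsv <- function(df, name) {
    utils::write.csv(df, file.path(config$out_dir, name), row.names = FALSE,
                     quote = FALSE)
  }
  write_cohort_table(cohort, file.path(config$out_dir, "cohort.csv"))
  wcsv(ec_regions, "ec_regions.csv")
  wcsv(ec_lobes, "ec_lobes.csv")
  wcsv(comparison, "comparison.csv")
  wcsv(correlations, "correlations.csv")
  for (sg in names(subgroup_comparisons)) {
    wcsv(subgroup_comparisons[[sg]], sprintf("comparison_%s.csv", sg))
  }
  manifest$stage_times <- stage_times
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(log_lines, log_path)
  invisible(list(cohort = cohort, ec_regions = ec_regions,
                 ec_lobes = ec_lobes, comparison = comparison,
                 correlations = correlations,
                 subgroup_comparisons = subgroup_comparisons,
                 out_dir = config$out_dir))
}

# Serializable snapshot of a config (atlas/partition reduced to sizes).
config_snapshot <- function(config) {
  s <- unclass(config)
  if (!is.null(s$synthetic)) {
    sp <- unclass(s$synthetic)
    sp$atlas <- sprintf("<%d regions, %d groups>", nrow(sp$atlas),
                        length(unique(sp$atlas$group)))
    sp$region_labels <- NULL
    s$synthetic <- sp
  }
  s$bands <- apply(s$bands, 1L, function(r)
    sprintf("%s:%s-%s", r[["name"]], r[["low"]], r[["high"]]))
  s$plm <- unclass(s$plm)
  s
}
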