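#' AAL-116 region labels
#'
#' The packaged label list for the Automated Anatomical Labeling atlas:
#' 90 cerebral regions (45 left/right pairs) followed by 26 cerebellar and
#' vermal regions.
#'
#' @return Character vector of 116 labels.
#' @export
aal116_labels <- function() {
  path <- system.file("extdata", "aal116_labels.csv", package = "plmnet",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)$region_label
}

#' Cerebellar-exclusion region filter
#'
#' Drops cerebellar and vermis labels, keeping the original order. Applied
#' to the full AAL-116 list this retains the 90 cerebral regions used for
#' network analysis; cerebellar sources are excluded for their lower
#' reconstruction reliability.
#'
#' @param region_labels Character vector of labels drawn from the AAL-116
#'   set (see [aal116_labels()]).
#' @return The filtered label vector.
#' @examples
#' length(apply_roi_filter(aal116_labels()))  # 90
#' @export
apply_roi_filter <- function(region_labels) {
  region_labels <- as.character(region_labels)
  known <- aal116_labels()
  unknown <- setdiff(region_labels, known)
  if (length(unknown) > 0) {
    stop_invalid("unknown region label(s): %s", paste(unknown, collapse = ", "))
  }
  keep <- !grepl("^(Cerebelum|Vermis)", region_labels)
  region_labels[keep]
}

#' Default lobe partition for the 90 AAL cerebral regions
#'
#' Maps each of the 90 regions to one of six groups: frontal, insular,
#' temporal, parietal, occipital, subcortical. The shipped mapping follows
#' conventional AAL lobe groupings (anterior/mid cingulate with frontal,
#' posterior cingulate with parietal, Rolandic operculum with frontal); it
#' is a convention of this package, editable via [read_lobe_partition()].
#'
#' @return A data.frame with columns `region_label`, `group`.
#' @export
default_lobe_partition <- function() {
  path <- system.file("extdata", "aal90_lobes.csv", package = "plmnet",
                      mustWork = TRUE)
  validate_partition(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Read a lobe partition CSV
#'
#' @param path CSV with columns `region_label`, `group`.
#' @return Validated partition data.frame.
#' @export
read_lobe_partition <- function(path) {
  validate_partition(utils::read.csv(path, stringsAsFactors = FALSE))
}

lobe_names <- function() {
  c("frontal", "insular", "temporal", "parietal", "occipital", "subcortical")
}

validate_partition <- function(partition) {
  if (!is.data.frame(partition) ||
      !all(c("region_label", "group") %in% names(partition))) {
    stop_invalid("partition must have columns region_label, group")
  }
  if (anyDuplicated(partition$region_label)) {
    stop_invalid("partition maps some region more than once")
  }
  bad <- setdiff(unique(partition$group), lobe_names())
  if (length(bad) > 0) {
    stop_invalid("unknown partition group(s): %s", paste(bad, collapse = ", "))
  }
  partition
}

#' Reduced six-lobe atlas for fast simulations
#'
#' Takes the first `n_per_lobe` regions of each group from the default
#' partition, preserving atlas order. Useful for Monte-Carlo studies where
#' the full 90-region network would be needlessly slow.
#'
#' @param n_per_lobe Regions retained per group (default 2).
#' @return A partition data.frame (subset of [default_lobe_partition()]).
#' @export
reduced_atlas <- function(n_per_lobe = 2) {
  part <- default_lobe_partition()
  keep <- unlist(lapply(lobe_names(), function(g) {
    which(part$group == g)[seq_len(min(n_per_lobe, sum(part$group == g)))]
  }))
  part[sort(keep), , drop = FALSE]
}
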