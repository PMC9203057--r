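#' Remove samples with anomalously low read depth
#'
#' Within each group defined by a metadata column, removes every sample
#' whose total read depth falls more than three standard deviations below
#' the group mean depth (threshold = mean - k * sd). Groups are evaluated
#' independently, so an outlier is judged only against its own group.
#'
#' @param table a `feature_table`.
#' @param meta sample metadata data.frame covering all samples.
#' @param grouping metadata column defining the groups (default
#'   `"source_dataset"`: thresholds are dataset-specific because merged
#'   studies differ systematically in depth).
#' @param k number of standard deviations below the mean (default 3).
#' @param sd_type `"sample"` for the n-1 estimator (default) or
#'   `"population"` for the n denominator.
#' @return list with `table` (filtered `feature_table`) and `report`
#'   (a `qc_report`, see [qc_report()]).
#' @export
filter_low_depth <- function(table, meta, grouping = "source_dataset",
                             k = 3, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  meta <- align_metadata(table, meta)
  if (!grouping %in% names(meta))
    stop("no metadata column '", grouping, "'", call. = FALSE)
  depths <- sample_depths(table)
  groups <- meta[[grouping]]
  removed <- data.frame(sample_id = character(), depth = numeric(),
                        group_threshold = numeric())
  for (g in unique(groups)) {
    d <- depths[groups == g]
    if (length(d) < 2L) {
      warning("group '", g, "' has a single sample; depth filter skipped ",
              "(sd undefined)", call. = FALSE)
      next
    }
    s <- stats::sd(d)
    if (sd_type == "population") s <- s * sqrt((length(d) - 1) / length(d))
    thr <- mean(d) - k * s
    bad <- d[d < thr]
    if (length(bad))
      removed <- rbind(removed, data.frame(
        sample_id = names(bad), depth = unname(bad), group_threshold = thr))
  }
  keep <- setdiff(sample_ids(table), removed$sample_id)
  list(table = subset_samples(table, keep),
       report = qc_report(removed_low_depth = removed, retained = keep))
}

#' Remove samples dominated by a single ASV
#'
#' Removes every sample in which the most abundant single ASV accounts for
#' strictly more than `threshold` of the reads. Zero-depth samples are
#' removed too, flagged separately (dominance is undefined there).
#'
#' @param table a `feature_table`.
#' @param threshold maximum tolerated single-ASV read fraction
#'   (default 0.75; removal requires fraction > threshold, so a sample at
#'   exactly 75% is retained).
#' @return list with `table` and `report` as in [filter_low_depth()].
#' @export
filter_dominated <- function(table, threshold = 0.75) {
  depths <- sample_depths(table)
  zero <- names(depths)[depths == 0]
  frac <- rep(NA_real_, nrow(table$counts))
  names(frac) <- sample_ids(table)
  pos <- depths > 0
  if (any(pos))
    frac[pos] <- apply(table$counts[pos, , drop = FALSE], 1L, max) /
      depths[pos]
  dominated <- names(frac)[!is.na(frac) & frac > threshold]
  keep <- setdiff(sample_ids(table), c(zero, dominated))
  rep <- qc_report(
    removed_dominated = data.frame(sample_id = dominated,
                                   max_asv_fraction = unname(frac[dominated])),
    removed_zero_depth = zero,
    retained = keep)
  list(table = subset_samples(table, keep), report = rep)
}

#' Quality-control report
#'
#' Records which samples a QC step removed and why. The removed and
#' retained sets are disjoint and jointly cover the input samples.
#'
#' @param removed_low_depth data.frame (sample_id, depth, group_threshold).
#' @param removed_dominated data.frame (sample_id, max_asv_fraction).
#' @param removed_zero_depth character vector of zero-depth sample ids.
#' @param retained character vector of retained sample ids.
#' @return an object of class `qc_report`.
#' @export
qc_report <- function(removed_low_depth = NULL, removed_dominated = NULL,
                      removed_zero_depth = character(), retained = character()) {
  removed <- c(removed_low_depth$sample_id, removed_dominated$sample_id,
               removed_zero_depth)
  if (length(intersect(removed, retained)))
    stop("removed and retained sample sets overlap", call. = FALSE)
  structure(list(removed_low_depth = removed_low_depth,
                 removed_dominated = removed_dominated,
                 removed_zero_depth = removed_zero_depth,
                 retained = retained),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("qc_report:", length(x$retained), "samples retained\n")
  if (NROW(x$removed_low_depth))
    cat("  low depth:", paste(x$removed_low_depth$sample_id, collapse = ", "),
        "\n")
  if (NROW(x$removed_dominated))
    cat("  single-ASV dominated:",
        paste(x$removed_dominated$sample_id, collapse = ", "), "\n")
  if (length(x$removed_zero_depth))
    cat("  zero depth:", paste(x$removed_zero_depth, collapse = ", "), "\n")
  invisible(x)
}

#' All removed sample ids in a QC report
#' @param report a `qc_report`.
#' @return character vector.
#' @export
removed_samples <- function(report) {
  c(report$removed_low_depth$sample_id, report$removed_dominated$sample_id,
    report$removed_zero_depth)
}

#' Run both QC filters in the standard order
#'
#' Depth filter first (per group), then the single-ASV dominance filter.
#' The order matters only at boundary cases (a dominated sample inflates
#' its group's depth statistics); it is fixed here so that reruns are
#' comparable.
#'
#' @inheritParams filter_low_depth
#' @inheritParams filter_dominated
#' @return list with `table` and a merged `report`.
#' @export
qc_filter <- function(table, meta, grouping = "source_dataset", k = 3,
                      threshold = 0.75) {
  step1 <- filter_low_depth(table, meta, grouping, k)
  step2 <- filter_dominated(step1$table, threshold)
  list(table = step2$table,
       report = qc_report(
         removed_low_depth = step1$report$removed_low_depth,
         removed_dominated = step2$report$removed_dominated,
         removed_zero_depth = step2$report$removed_zero_depth,
         retained = step2$report$retained))
}

#' Rarefy a feature table to a common depth
#'
#' Subsamples every sample's reads without replacement (multivariate
#' hypergeometric) to exactly `depth` reads, removing depth bias before
#' diversity calculations. `depth = "auto"` uses 90% of the minimum
#' sample depth, floored to an integer. Deterministic given `seed`.
#'
#' @param table a `feature_table`.
#' @param depth positive integer target depth, or `"auto"` for
#'   `floor(0.9 * min(sample_depths(table)))`.
#' @param seed integer RNG seed; required so that every rarefaction is
#'   logged and reproducible.
#' @param drop_empty drop ASV columns that end up all-zero (default keeps
#'   them so ASV id spaces stay aligned).
#' @return a rarefied `feature_table` with attribute `"rarefaction_depth"`.
#' @export
rarefy <- function(table, depth = "auto", seed, drop_empty = FALSE) {
  if (missing(seed)) stop("rarefy() requires an explicit seed", call. = FALSE)
  depths <- sample_depths(table)
  if (identical(depth, "auto")) depth <- floor(0.9 * min(depths))
  depth <- as.integer(depth)
  if (depth <= 0) stop("rarefaction depth must be positive", call. = FALSE)
  shallow <- names(depths)[depths < depth]
  if (length(shallow))
    stop("samples shallower than rarefaction depth ", depth, ": ",
         paste(shallow, collapse = ", "), call. = FALSE)
  out <- with_seed(seed, {
    t(apply(table$counts, 1L, subsample_counts, depth = depth))
  })
  dimnames(out) <- dimnames(table$counts)
  res <- feature_table(out, taxonomy = table$taxonomy)
  if (drop_empty)
    res <- subset_samples(res, drop_empty = TRUE)
  attr(res, "rarefaction_depth") <- depth
  res
}

# Draw `depth` reads without replacement from one sample's count vector
# (one multivariate hypergeometric draw).
subsample_counts <- function(x, depth) {
  total <- sum(x)
  if (depth == total) return(x)
  reads <- rep.int(seq_along(x), x)
  tabulate(reads[sample.int(total, depth)], nbins = length(x))
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring
# the caller's RNG afterwards.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
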