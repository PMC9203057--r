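#' ASVs present in a set of samples
#'
#' Presence is operationalized as count >= `min_count` in at least
#' `min_prevalence` of the named samples. Defaults (>= 1 read in >= 1
#' sample) are the loosest reading of "present in the group"; both
#' thresholds are exposed because counts are monotone non-increasing in
#' either.
#'
#' @param table a `feature_table`.
#' @param samples character vector of sample ids (non-empty subset of
#'   the table's samples).
#' @param min_count minimum per-sample count to call an ASV present in a
#'   sample (default 1).
#' @param min_prevalence minimum number of samples in which the ASV must
#'   be present (default 1).
#' @return character vector of ASV ids.
#' @export
presence_profile <- function(table, samples, min_count = 1,
                             min_prevalence = 1) {
  if (!length(samples)) stop("empty sample set", call. = FALSE)
  missing <- setdiff(samples, sample_ids(table))
  if (length(missing))
    stop("unknown sample ids: ", paste(missing, collapse = ", "),
         call. = FALSE)
  sub <- table$counts[samples, , drop = FALSE]
  prev <- colSums(sub >= min_count)
  asv_ids(table)[prev >= min_prevalence]
}

#' ASVs exclusively shared by one wildlife population and humans
#'
#' Counts the ASVs present in the urban wildlife population and in
#' humans but absent from the rural wildlife population
#' (`n_urban_exclusive`), and the mirror-image count
#' (`n_rural_exclusive`). An excess of urban-exclusive sharing is the
#' presence-based signature of humanization.
#'
#' @param table a `feature_table` (presence judged on these counts;
#'   rarefied counts recommended).
#' @param meta sample metadata.
#' @param human_samples character vector of human sample ids (defaults
#'   to every sample with `host_species == "human"`).
#' @param urban_pop,rural_pop values of `grouping` naming the urban and
#'   rural wildlife populations.
#' @param grouping metadata column naming populations (default
#'   `"population"`).
#' @param min_count,min_prevalence presence thresholds, see
#'   [presence_profile()].
#' @return list of class `sharing_result`: counts, the ASV id lists
#'   behind them, and the three sample sets used.
#' @export
exclusive_shared_counts <- function(table, meta, human_samples = NULL,
                                    urban_pop, rural_pop,
                                    grouping = "population",
                                    min_count = 1, min_prevalence = 1) {
  meta <- align_metadata(table, meta)
  if (is.null(human_samples))
    human_samples <- meta$sample_id[meta$host_species == "human"]
  urban_samples <- meta$sample_id[meta[[grouping]] == urban_pop]
  rural_samples <- meta$sample_id[meta[[grouping]] == rural_pop]
  sets <- list(urban = urban_samples, rural = rural_samples,
               human = human_samples)
  if (any(lengths(sets) == 0L))
    stop("empty sample set(s): ",
         paste(names(sets)[lengths(sets) == 0L], collapse = ", "),
         call. = FALSE)
  if (length(intersect(urban_samples, rural_samples)) ||
      length(intersect(human_samples, c(urban_samples, rural_samples))))
    stop("urban, rural and human sample sets must be disjoint",
         call. = FALSE)
  p_urban <- presence_profile(table, urban_samples, min_count, min_prevalence)
  p_rural <- presence_profile(table, rural_samples, min_count, min_prevalence)
  p_human <- presence_profile(table, human_samples, min_count, min_prevalence)
  urban_excl <- setdiff(intersect(p_urban, p_human), p_rural)
  rural_excl <- setdiff(intersect(p_rural, p_human), p_urban)
  structure(list(n_urban_exclusive = length(urban_excl),
                 n_rural_exclusive = length(rural_excl),
                 urban_exclusive_asvs = urban_excl,
                 rural_exclusive_asvs = rural_excl,
                 urban_samples = urban_samples,
                 rural_samples = rural_samples,
                 human_samples = human_samples,
                 replicates = NULL, seed = NULL),
            class = "sharing_result")
}

#' Exclusive sharing with equal-n subsampling of the rural population
#'
#' Rural populations are often larger than urban ones, which inflates
#' rural presence sets. Each replicate draws (without replacement) as
#' many rural samples as there are urban samples and recomputes
#' [exclusive_shared_counts()]; replicate pairs and their means are
#' reported. Deterministic given `seed`.
#'
#' @inheritParams exclusive_shared_counts
#' @param n_reps number of subsampling replicates (default 10).
#' @param seed RNG seed (required).
#' @return a `sharing_result` whose `replicates` element is a data.frame
#'   (replicate, n_urban_exclusive, n_rural_exclusive) and whose
#'   top-level counts are the replicate means.
#' @export
subsampled_sharing <- function(table, meta, human_samples = NULL,
                               urban_pop, rural_pop,
                               grouping = "population", n_reps = 10, seed,
                               min_count = 1, min_prevalence = 1) {
  if (missing(seed))
    stop("subsampled_sharing requires a seed", call. = FALSE)
  base <- exclusive_shared_counts(table, meta, human_samples, urban_pop,
                                  rural_pop, grouping, min_count,
                                  min_prevalence)
  n_urban <- length(base$urban_samples)
  n_rural <- length(base$rural_samples)
  if (n_rural < n_urban)
    stop("rural population (", n_rural, ") smaller than urban (", n_urban,
         "): subsampling runs rural -> urban size only", call. = FALSE)
  reps <- with_seed(seed, lapply(seq_len(n_reps), function(r) {
    rural_sub <- sample(base$rural_samples, n_urban)
    keep <- c(base$urban_samples, rural_sub, base$human_samples)
    m <- meta[meta$sample_id %in% keep, , drop = FALSE]
    res <- exclusive_shared_counts(subset_samples(table, keep), m,
                                   base$human_samples, urban_pop, rural_pop,
                                   grouping, min_count, min_prevalence)
    c(n_urban_exclusive = res$n_urban_exclusive,
      n_rural_exclusive = res$n_rural_exclusive)
  }))
  reps <- data.frame(replicate = seq_len(n_reps), do.call(rbind, reps))
  out <- base
  out$replicates <- reps
  out$seed <- seed
  out$n_urban_exclusive <- mean(reps$n_urban_exclusive)
  out$n_rural_exclusive <- mean(reps$n_rural_exclusive)
  out$unsubsampled <- c(n_urban_exclusive = base$n_urban_exclusive,
                        n_rural_exclusive = base$n_rural_exclusive)
  out
}

#' @export
print.sharing_result <- function(x, ...) {
  cat("sharing_result:\n")
  cat(sprintf("  urban-exclusive (urban wildlife & humans, not rural): %s\n",
              format(x$n_urban_exclusive)))
  cat(sprintf("  rural-exclusive (rural wildlife & humans, not urban): %s\n",
              format(x$n_rural_exclusive)))
  if (!is.null(x$replicates))
    cat(sprintf("  (means over %d equal-n subsampling replicates, seed %s)\n",
                nrow(x$replicates), format(x$seed)))
  invisible(x)
}
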