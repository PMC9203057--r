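#' Rerun an analysis with samples excluded
#'
#' Sensitivity protocol for suspected outliers: the analysis closure is
#' evaluated on the reduced sample set. Distance-based analyses should
#' subset an already-computed distance matrix (see
#' [drop_dm_samples()]) rather than recompute it, unless the metric
#' itself depends on the sample set.
#'
#' @param analysis function taking a character vector of sample ids and
#'   returning a result with a `p_value` element.
#' @param all_samples the base run's sample ids.
#' @param exclude sample ids to remove (must exist in `all_samples`).
#' @return the analysis result on `setdiff(all_samples, exclude)`.
#' @export
rerun_without <- function(analysis, all_samples, exclude = character()) {
  missing <- setdiff(exclude, all_samples)
  if (length(missing))
    stop("excluded ids not in the analysis inputs: ",
         paste(missing, collapse = ", "), call. = FALSE)
  analysis(setdiff(all_samples, exclude))
}

#' Drop samples from a distance matrix
#' @param dm a `dist_matrix`.
#' @param samples ids to keep.
#' @return the submatrix as a `dist_matrix`.
#' @export
drop_dm_samples <- function(dm, samples) {
  as_dist_matrix(unclass(dm)[samples, samples, drop = FALSE])
}

#' Repeat an analysis on random fixed-size subsamples of one group
#'
#' Guards against uneven sampling: `n_reps` independent draws of `k`
#' samples (without replacement) from the named group, the rest of the
#' sample set held fixed, the analysis repeated per draw. Deterministic
#' given `seed`.
#'
#' @inheritParams rerun_without
#' @param group_samples sample ids of the group being subsampled.
#' @param k subsample size (default 10, must not exceed the group size).
#' @param n_reps number of replicate draws (default 5).
#' @param seed RNG seed (required).
#' @return list of `n_reps` analysis results; each carries the drawn ids
#'   as attribute `"subsample"`.
#' @export
subsample_runs <- function(analysis, all_samples, group_samples, k = 10,
                           n_reps = 5, seed) {
  if (missing(seed)) stop("subsample_runs requires a seed", call. = FALSE)
  if (!all(group_samples %in% all_samples))
    stop("group samples not all present in the analysis inputs",
         call. = FALSE)
  if (k > length(group_samples))
    stop("k = ", k, " exceeds the group size ", length(group_samples),
         call. = FALSE)
  fixed <- setdiff(all_samples, group_samples)
  with_seed(seed, lapply(seq_len(n_reps), function(r) {
    draw <- sample(group_samples, k)
    res <- analysis(c(fixed, draw))
    attr(res, "subsample") <- draw
    res
  }))
}

#' Consensus significance across sensitivity runs
#'
#' The strictest reading of "significant in all analyses": the
#' consensus is significant only if every run rejects at `alpha`. A
#' subsample block (a list of replicate results, as returned by
#' [subsample_runs()]) counts as one run that is significant only when
#' all of its replicates are (set `subsample_rule = "majority"` for the
#' laxer reading).
#'
#' @param runs named list; each element is either a single result with a
#'   `p_value` or a list of such results (a subsample block).
#' @param alpha significance level (default 0.05).
#' @param subsample_rule `"all"` (default) or `"majority"`.
#' @return list of class `consensus_report`: per-run table and
#'   `consensus_significant`.
#' @export
consensus <- function(runs, alpha = 0.05,
                      subsample_rule = c("all", "majority")) {
  subsample_rule <- match.arg(subsample_rule)
  if (!length(runs)) stop("need at least one run", call. = FALSE)
  if (is.null(names(runs)))
    names(runs) <- paste0("run", seq_along(runs))
  is_block <- vapply(runs, function(r) is.null(r$p_value), logical(1))
  sig <- vapply(seq_along(runs), function(i) {
    if (!is_block[i]) return(runs[[i]]$p_value <= alpha)
    ps <- vapply(runs[[i]], function(r) r$p_value, numeric(1))
    if (subsample_rule == "all") all(ps <= alpha)
    else mean(ps <= alpha) > 0.5
  }, logical(1))
  p_disp <- vapply(seq_along(runs), function(i) {
    if (!is_block[i]) return(runs[[i]]$p_value)
    max(vapply(runs[[i]], function(r) r$p_value, numeric(1)))
  }, numeric(1))
  structure(list(
    runs = data.frame(run = names(runs), p_value = p_disp,
                      is_subsample_block = is_block, significant = sig),
    alpha = alpha,
    consensus_significant = all(sig)),
    class = "consensus_report")
}

#' @export
print.consensus_report <- function(x, ...) {
  cat("consensus_report (alpha =", x$alpha, "):\n")
  print(x$runs, row.names = FALSE)
  cat("  consensus significant:", x$consensus_significant, "\n")
  invisible(x)
}
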