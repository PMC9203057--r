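#' Centered log-ratio transform of one sample's counts
#'
#' Maps a composition to real space: y = log(x + pc) - mean(log(x + pc)),
#' so the transformed vector sums to zero. A pseudocount (default 1)
#' keeps zeros finite; it may be 0 only when all counts are positive.
#'
#' @param x non-negative count vector, length >= 2.
#' @param pseudocount added to every count before the log (default 1).
#' @return real vector summing to zero.
#' @export
clr_transform <- function(x, pseudocount = 1) {
  if (length(x) < 2L) stop("CLR needs at least two parts", call. = FALSE)
  if (pseudocount < 0) stop("pseudocount must be >= 0", call. = FALSE)
  if (pseudocount == 0 && any(x == 0))
    stop("pseudocount 0 requires strictly positive counts", call. = FALSE)
  l <- log(x + pseudocount)
  l - mean(l)
}

#' Per-ASV CLR mean difference between two groups
#'
#' The effect size reported alongside the ANCOM W statistic: for each
#' ASV, the mean CLR value among samples of `levels[2]` minus the mean
#' among samples of `levels[1]` (conventionally urban minus rural, so
#' positive values mean urban-enriched).
#'
#' @param table a `feature_table`.
#' @param meta sample metadata.
#' @param group metadata column with (at least) the two levels compared.
#' @param levels character vector of two levels, `c(reference, focal)`.
#'   Defaults to `c("rural", "urban")` on the `urban_status` column.
#' @param pseudocount passed to [clr_transform()].
#' @return named numeric vector over ASVs (focal minus reference).
#' @export
clr_mean_difference <- function(table, meta, group = "urban_status",
                                levels = c("rural", "urban"),
                                pseudocount = 1) {
  stopifnot(length(levels) == 2L)
  meta <- align_metadata(table, meta)
  g <- as.character(meta[[group]])
  for (lv in levels)
    if (!any(g == lv))
      stop("group level '", lv, "' has no samples", call. = FALSE)
  clr <- t(apply(table$counts, 1L, clr_transform, pseudocount = pseudocount))
  colMeans(clr[g == levels[2], , drop = FALSE]) -
    colMeans(clr[g == levels[1], , drop = FALSE])
}

#' ANCOM differential-abundance test
#'
#' Analysis of composition of microbiomes: for each ASV i, its log-ratio
#' to every other ASV j, log((x_i + pc) / (x_j + pc)), is tested for a
#' group effect. W_raw(i) counts how many of those m - 1 tests reject
#' after Benjamini-Hochberg correction within ASV i; W_norm = W_raw
#' divided by the number of evaluable ratios. ASVs with W_norm above 0.7
#' are flagged strongly significant and above 0.5 weakly significant.
#' With no covariates the per-ratio test is the Mann-Whitney rank-sum
#' test; with covariates it is a linear model on the log-ratio
#' (`lr ~ group + covariates`) with a two-sided t-test of the group
#' coefficient, allowing e.g. host species to be adjusted for when
#' pooling wildlife populations.
#'
#' @param table a `feature_table` (rarefied counts recommended for
#'   consistency with the rest of the pipeline).
#' @param meta sample metadata.
#' @param group metadata column; exactly two of its levels are compared.
#' @param levels two levels `c(reference, focal)`; samples at other
#'   levels (e.g. semiurban) are excluded. Default `c("rural", "urban")`.
#' @param covariates character vector of metadata columns to adjust for
#'   (default none).
#' @param alpha per-ASV rejection level after correction (default 0.05).
#' @param p_adjust_method multiplicity correction within each ASV's m - 1
#'   p-values: `"holm"` (default, matching the reference ANCOM
#'   implementation; it keeps the W statistic quiet when one ASV's
#'   correlated log-ratios shift by chance), `"BH"`, `"bonferroni"` or
#'   `"none"`.
#' @param pseudocount added before log-ratios (default 1).
#' @return data.frame of class `ancom_result` with one row per ASV:
#'   `asv_id`, `w_raw`, `n_tests`, `w_norm`, `clr_mean_diff`,
#'   `significant_at_0.7`, `significant_at_0.5`.
#' @export
ancom_w <- function(table, meta, group = "urban_status",
                    levels = c("rural", "urban"), covariates = character(),
                    alpha = 0.05, p_adjust_method = c("holm", "BH",
                                                      "bonferroni", "none"),
                    pseudocount = 1) {
  p_adjust_method <- match.arg(p_adjust_method)
  stopifnot(length(levels) == 2L)
  meta <- align_metadata(table, meta)
  keep <- meta[[group]] %in% levels
  if (!any(meta[[group]] == levels[1]) || !any(meta[[group]] == levels[2]))
    stop("both group levels must be non-empty", call. = FALSE)
  tab <- subset_samples(table, meta$sample_id[keep])
  meta <- meta[keep, , drop = FALSE]
  g <- factor(meta[[group]], levels = levels)
  m <- ncol(tab$counts)
  if (m < 2L) stop("ANCOM needs at least two ASVs", call. = FALSE)

  lx <- log(tab$counts + pseudocount)
  covar_df <- if (length(covariates))
    data.frame(lapply(meta[covariates], factor)) else NULL

  # p-value of the group effect for the log-ratio of columns i and j;
  # the same value serves both ordered pairs (i,j) and (j,i).
  pair_p <- matrix(NA_real_, m, m)
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      lr <- lx[, i] - lx[, j]
      if (max(lr) - min(lr) < 1e-12) next  # constant ratio: untestable
      pair_p[i, j] <- pair_p[j, i] <-
        if (is.null(covar_df)) rank_sum_p(lr, g)
        else lm_group_p(lr, g, covar_df)
    }
  }

  w_raw <- integer(m)
  n_tests <- integer(m)
  for (i in seq_len(m)) {
    p <- pair_p[i, -i]
    p <- p[!is.na(p)]
    n_tests[i] <- length(p)
    if (length(p))
      w_raw[i] <- sum(stats::p.adjust(p, method = p_adjust_method) <= alpha)
  }
  w_norm <- ifelse(n_tests > 0, w_raw / n_tests, 0)

  clr_diff <- clr_mean_difference(tab, meta, group, levels, pseudocount)
  out <- data.frame(asv_id = asv_ids(tab), w_raw = w_raw, n_tests = n_tests,
                    w_norm = w_norm, clr_mean_diff = unname(clr_diff),
                    significant_at_0.7 = w_norm > 0.7,
                    significant_at_0.5 = w_norm > 0.5,
                    check.names = FALSE)
  class(out) <- c("ancom_result", "data.frame")
  out
}

# Mann-Whitney two-sided p via the normal approximation with tie
# correction (matches wilcox.test(..., exact = FALSE, correct = FALSE)).
rank_sum_p <- function(x, g) {
  r <- rank(x)
  n1 <- sum(g == levels(g)[1])
  n2 <- length(x) - n1
  u <- sum(r[g == levels(g)[1]]) - n1 * (n1 + 1) / 2
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 *
    ((length(x) + 1) - sum(ties^3 - ties) / (length(x) * (length(x) - 1)))
  if (sigma2 <= 0) return(NA_real_)
  z <- (u - n1 * n2 / 2) / sqrt(sigma2)
  2 * stats::pnorm(-abs(z))
}

# Two-sided t-test of the group coefficient in lr ~ group + covariates.
lm_group_p <- function(lr, g, covar_df) {
  df <- data.frame(lr = lr, .group = g, covar_df)
  fit <- stats::lm(lr ~ ., data = df)
  ct <- summary(fit)$coefficients
  row <- grep("^\\.group", rownames(ct))
  if (!length(row)) return(NA_real_)
  ct[row[1], "Pr(>|t|)"]
}

# Subsets of the full result table are ordinary data.frames.
#' @export
`[.ancom_result` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) class(out) <- "data.frame"
  out
}

#' @export
print.ancom_result <- function(x, ...) {
  cat(sprintf("ancom_result: %d ASVs tested\n", nrow(x)))
  cat(sprintf("  W > 0.7: %d ASVs; W > 0.5: %d ASVs\n",
              sum(x$significant_at_0.7), sum(x$significant_at_0.5)))
  top <- x[order(-x$w_norm, -abs(x$clr_mean_diff)), ][1, ]
  cat(sprintf("  top ASV: %s (W = %.3f, CLR diff = %.3f)\n",
              top$asv_id, top$w_norm, top$clr_mean_diff))
  invisible(x)
}
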