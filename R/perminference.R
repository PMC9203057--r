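# Named group-label vector for the samples of a distance matrix.
dm_groups <- function(dm, meta, grouping) {
  if (!grouping %in% names(meta))
    stop("no metadata column '", grouping, "'", call. = FALSE)
  idx <- match(rownames(dm), meta$sample_id)
  if (anyNA(idx))
    stop("samples missing from metadata: ",
         paste(rownames(dm)[is.na(idx)], collapse = ", "), call. = FALSE)
  stats::setNames(as.character(meta[[grouping]][idx]), rownames(dm))
}

#' Pairwise dissimilarities between (or within) two sample groups
#'
#' For two distinct groups returns each of the |g1| x |g2| cross-group
#' dissimilarities once; for `g1 == g2` returns the choose(n, 2)
#' within-group values.
#'
#' @param dm a `dist_matrix`.
#' @param meta sample metadata.
#' @param g1,g2 group labels in the `grouping` column.
#' @param grouping metadata column defining groups (default
#'   `"population"`).
#' @return numeric vector of dissimilarities.
#' @export
between_group_distances <- function(dm, meta, g1, g2,
                                    grouping = "population") {
  labels <- dm_groups(dm, meta, grouping)
  pull_between(dm, labels, g1, g2)
}

# Core extraction working from a label vector (reused under permutation).
pull_between <- function(dm, labels, g1, g2) {
  i <- which(labels == g1)
  j <- which(labels == g2)
  if (!length(i)) stop("unknown or empty group '", g1, "'", call. = FALSE)
  if (!length(j)) stop("unknown or empty group '", g2, "'", call. = FALSE)
  if (g1 == g2) {
    if (length(i) < 2L) return(numeric())
    return(dm[i, i][upper.tri(matrix(0, length(i), length(i)))])
  }
  as.vector(dm[i, j])
}

#' Monte Carlo permutation comparison of two sets of between-group
#' dissimilarities
#'
#' The central convergence test: is the mean dissimilarity of pair A
#' (e.g. urban wildlife vs humans) smaller than that of pair B (rural
#' wildlife vs humans)? The observed statistic is
#' `mean(d(pair_A)) - mean(d(pair_B))`. The null is built by shuffling
#' group labels among the samples whose labels distinguish the two pairs
#' (groups occurring in both pairs, such as the human set, stay fixed),
#' preserving the distance structure itself. With `n_perm = "exact"` all
#' distinct label assignments are enumerated instead (only supported when
#' exactly two groups vary).
#'
#' @param dm a `dist_matrix`.
#' @param meta sample metadata.
#' @param pair_A,pair_B character vectors of two group labels each.
#' @param grouping metadata column defining groups.
#' @param n_perm number of Monte Carlo permutations (default 999), or
#'   `"exact"`.
#' @param tail `"two_sided"` (default), `"A_less"` (alternative: pair A's
#'   mean is smaller), or `"A_greater"`.
#' @param seed RNG seed, required unless `n_perm = "exact"`.
#' @return list of class `group_comparison`: observed statistic, p-value
#'   (with the +1 Monte Carlo correction, so never exactly 0), the means
#'   of the two distance sets, and bookkeeping fields.
#' @export
mc_group_comparison <- function(dm, meta, pair_A, pair_B,
                                grouping = "population", n_perm = 999,
                                tail = c("two_sided", "A_less", "A_greater"),
                                seed = NULL) {
  tail <- match.arg(tail)
  stopifnot(length(pair_A) == 2L, length(pair_B) == 2L)
  labels <- dm_groups(dm, meta, grouping)
  dA <- pull_between(dm, labels, pair_A[1], pair_A[2])
  dB <- pull_between(dm, labels, pair_B[1], pair_B[2])
  if (!length(dA) || !length(dB))
    stop("a compared pair yields zero dissimilarities", call. = FALSE)
  obs <- mean(dA) - mean(dB)

  varying <- setdiff(union(pair_A, pair_B),
                     intersect(unique(pair_A), unique(pair_B)))
  vidx <- which(labels %in% varying)
  stat_for <- function(lab) {
    mean(pull_between(dm, lab, pair_A[1], pair_A[2])) -
      mean(pull_between(dm, lab, pair_B[1], pair_B[2]))
  }

  if (identical(n_perm, "exact")) {
    if (length(varying) != 2L)
      stop("exact enumeration supported only when two groups vary",
           call. = FALSE)
    i1 <- which(labels[vidx] == varying[1])
    combos <- utils::combn(length(vidx), length(i1))
    null <- apply(combos, 2L, function(sel) {
      lab <- labels
      lab[vidx] <- varying[2]
      lab[vidx[sel]] <- varying[1]
      stat_for(lab)
    })
    # observed assignment is one of the enumerated ones: exact p
    p <- switch(tail,
      two_sided = mean(abs(null) >= abs(obs) - 1e-12),
      A_less    = mean(null <= obs + 1e-12),
      A_greater = mean(null >= obs - 1e-12))
    n_used <- ncol(combos)
  } else {
    if (is.null(seed))
      stop("Monte Carlo permutation requires a seed", call. = FALSE)
    null <- with_seed(seed, vapply(seq_len(n_perm), function(k) {
      lab <- labels
      lab[vidx] <- lab[vidx][sample.int(length(vidx))]
      stat_for(lab)
    }, numeric(1)))
    p <- switch(tail,
      two_sided = (sum(abs(null) >= abs(obs) - 1e-12) + 1) / (n_perm + 1),
      A_less    = (sum(null <= obs + 1e-12) + 1) / (n_perm + 1),
      A_greater = (sum(null >= obs - 1e-12) + 1) / (n_perm + 1))
    n_used <- n_perm
  }

  structure(list(pair_A = pair_A, pair_B = pair_B,
                 mean_A = mean(dA), mean_B = mean(dB),
                 stat_observed = obs, p_value = p,
                 n_permutations = n_used, tail = tail, seed = seed,
                 grouping = grouping),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("group_comparison: mean d(%s) - mean d(%s)\n",
              paste(x$pair_A, collapse = "~"),
              paste(x$pair_B, collapse = "~")))
  cat(sprintf("  stat = %.4f (means %.4f vs %.4f), p = %.4g [%s, %d perms]\n",
              x$stat_observed, x$mean_A, x$mean_B, x$p_value, x$tail,
              x$n_permutations))
  invisible(x)
}

#' Multi-term PERMANOVA on a distance matrix
#'
#' Partitions the total sum of squares of a dissimilarity matrix among
#' model terms via the Gower-centered inner-product matrix
#' G = -1/2 J D^2 J: the term sums of squares are traces of projections
#' of G onto nested model subspaces (sequential sums of squares in the
#' order given, as in `adonis2` by-terms). Significance is assessed by
#' raw permutation of sample identities, recomputing each term's
#' pseudo-F.
#'
#' @param dm a `dist_matrix`.
#' @param meta sample metadata.
#' @param terms character vector of metadata column names, in model
#'   order, e.g. `c("host_species", "population", "urban_status")`.
#' @param n_perm number of permutations (default 999).
#' @param seed RNG seed (required when `n_perm > 0`).
#' @return data.frame of class `adonis_result` with one row per term plus
#'   `Residual` and `Total` rows; columns `term`, `df`, `sum_sq`, `r2`,
#'   `pseudo_f`, `p_value`.
#' @export
adonis_dm <- function(dm, meta, terms, n_perm = 999, seed = NULL) {
  dm <- as_dist_matrix(dm)
  n <- nrow(dm)
  idx <- match(rownames(dm), meta$sample_id)
  if (anyNA(idx)) stop("samples missing from metadata", call. = FALSE)
  facs <- lapply(terms, function(tm) {
    if (!tm %in% names(meta))
      stop("no metadata column '", tm, "'", call. = FALSE)
    f <- factor(meta[[tm]][idx])
    if (nlevels(f) < 2L)
      stop("term '", tm, "' has fewer than two levels", call. = FALSE)
    f
  })
  names(facs) <- terms

  G <- gower_center(dm)
  ss_total <- sum(diag(G))

  # Orthonormal bases of the nested (cumulative) model subspaces.
  qs <- vector("list", length(terms))
  ranks <- integer(length(terms))
  X <- matrix(1, n, 1)
  for (k in seq_along(terms)) {
    X <- cbind(X, stats::model.matrix(~f, data.frame(f = facs[[k]]))[, -1,
                                                                     drop = FALSE])
    qr_x <- qr(X)
    ranks[k] <- qr_x$rank
    qs[[k]] <- qr.Q(qr_x)[, seq_len(qr_x$rank), drop = FALSE]
  }
  dfs <- diff(c(1L, ranks))
  if (any(dfs == 0L))
    warning("collinear term(s) absorb 0 df: ",
            paste(terms[dfs == 0L], collapse = ", "), call. = FALSE)
  df_res <- n - ranks[length(ranks)]

  # tr(H_k G) for each cumulative hat matrix H_k = Q_k Q_k' (the
  # intercept projection contributes 0 because G is centered).
  part <- function(Gm) {
    fits <- vapply(qs, function(Q) sum((Gm %*% Q) * Q), numeric(1))
    ss <- diff(c(0, fits))
    ss_res <- sum(diag(Gm)) - fits[length(fits)]
    f <- ifelse(dfs > 0, (ss / dfs) / (ss_res / df_res), NA_real_)
    list(ss = ss, ss_res = ss_res, f = f)
  }
  obs <- part(G)

  p <- rep(NA_real_, length(terms))
  if (n_perm > 0) {
    if (is.null(seed)) stop("adonis_dm requires a seed", call. = FALSE)
    exceed <- numeric(length(terms))
    with_seed(seed, for (b in seq_len(n_perm)) {
      pr <- sample.int(n)
      fp <- part(G[pr, pr])$f
      exceed <- exceed + (!is.na(fp) & fp >= obs$f - 1e-12)
    })
    p <- ifelse(is.na(obs$f), NA_real_, (exceed + 1) / (n_perm + 1))
  }

  out <- data.frame(
    term = c(terms, "Residual", "Total"),
    df = c(dfs, df_res, n - 1L),
    sum_sq = c(obs$ss, obs$ss_res, ss_total),
    r2 = c(obs$ss, obs$ss_res, ss_total) / ss_total,
    pseudo_f = c(obs$f, NA, NA),
    p_value = c(p, NA, NA))
  class(out) <- c("adonis_result", "data.frame")
  out
}

#' Homogeneity of multivariate dispersions (PERMDISP)
#'
#' Samples are embedded by PCoA (axes with positive eigenvalues only);
#' each sample's distance to its group centroid in that space is the
#' dispersion datum. The group effect on these distances is tested with a
#' one-way F statistic whose null distribution comes from permuting the
#' centroid distances among samples.
#'
#' @param dm a `dist_matrix`.
#' @param meta sample metadata.
#' @param group metadata column defining the groups; every group must
#'   have at least two samples.
#' @param n_perm permutations (default 999).
#' @param seed RNG seed.
#' @return list of class `permdisp_result`: per-group mean dispersions,
#'   `f_statistic`, `p_value`, `n_permutations`.
#' @export
permdisp <- function(dm, meta, group, n_perm = 999, seed = NULL) {
  labels <- dm_groups(dm, meta, group)
  f <- factor(labels)
  if (nlevels(f) < 2L) stop("need at least two groups", call. = FALSE)
  if (any(table(f) < 2L))
    stop("singleton group(s): ",
         paste(names(which(table(f) < 2L)), collapse = ", "), call. = FALSE)
  ord <- pcoa(dm)
  pos <- ord$eigenvalues > max(ord$eigenvalues) * 1e-10
  coords <- ord$coordinates[, pos, drop = FALSE]
  centroids <- apply(coords, 2L, function(col) tapply(col, f, mean))
  z <- sqrt(rowSums((coords - centroids[as.integer(f), , drop = FALSE])^2))

  f_stat <- function(zv) {
    m <- tapply(zv, f, mean)
    ng <- tabulate(f)
    ss_b <- sum(ng * (m - mean(zv))^2)
    ss_w <- sum((zv - m[as.integer(f)])^2)
    (ss_b / (nlevels(f) - 1)) / (ss_w / (length(zv) - nlevels(f)))
  }
  obs <- f_stat(z)
  p <- NA_real_
  if (n_perm > 0) {
    if (is.null(seed)) stop("permdisp requires a seed", call. = FALSE)
    null <- with_seed(seed, vapply(seq_len(n_perm),
                                   function(b) f_stat(z[sample.int(length(z))]),
                                   numeric(1)))
    p <- (sum(null >= obs - 1e-12) + 1) / (n_perm + 1)
  }
  structure(list(dispersions = tapply(z, f, mean), f_statistic = obs,
                 p_value = p, n_permutations = n_perm, seed = seed),
            class = "permdisp_result")
}

#' @export
print.permdisp_result <- function(x, ...) {
  cat("permdisp_result: F =", signif(x$f_statistic, 4),
      ", p =", signif(x$p_value, 4), "\n")
  print(signif(x$dispersions, 4))
  invisible(x)
}

#' Kruskal-Wallis test of alpha diversity across groups
#'
#' Thin wrapper around [stats::kruskal.test()] (rank H statistic with tie
#' correction, chi-square p on k-1 df) keyed by sample id, with the
#' degenerate all-tied case mapped to H = 0, p = 1.
#'
#' @param values data.frame with `sample_id` and a `value` column, or a
#'   named numeric vector keyed by sample id.
#' @param meta sample metadata.
#' @param group metadata column defining groups.
#' @return list with `h_statistic`, `df`, `p_value`.
#' @export
kruskal_wallis <- function(values, meta, group) {
  if (is.data.frame(values))
    values <- stats::setNames(values$value, values$sample_id)
  idx <- match(names(values), meta$sample_id)
  if (anyNA(idx)) stop("samples missing from metadata", call. = FALSE)
  g <- factor(meta[[group]][idx])
  if (nlevels(g) < 2L) stop("need at least two groups", call. = FALSE)
  if (length(unique(values)) == 1L)
    return(list(h_statistic = 0, df = nlevels(g) - 1L, p_value = 1))
  kt <- stats::kruskal.test(values, g)
  list(h_statistic = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value)
}
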