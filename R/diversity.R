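#' Binary Sorensen-Dice dissimilarity between two samples
#'
#' Presence/absence dissimilarity 1 - 2|A n B| / (|A| + |B|), where A and
#' B are the sets of ASVs with count > 0. Used to test convergence of
#' community *membership*: it responds to shared presence regardless of
#' abundance, which is the signal expected when wildlife acquire
#' human-associated ASVs at initially low abundance.
#'
#' @param x,y non-negative count vectors of equal length.
#' @return dissimilarity in `[0, 1]`.
#' @export
sorensen_dice <- function(x, y) {
  check_pair(x, y)
  a <- x > 0
  b <- y > 0
  na <- sum(a)
  nb <- sum(b)
  if (na + nb == 0)
    stop("Sorensen-Dice undefined: both samples are empty", call. = FALSE)
  1 - 2 * sum(a & b) / (na + nb)
}

#' Bray-Curtis dissimilarity between two samples
#'
#' Abundance-weighted dissimilarity 1 - 2 sum(min(x_i, y_i)) / (sum x +
#' sum y). Scale-sensitive, so tables should be rarefied to a common
#' depth first.
#'
#' @param x,y non-negative count vectors of equal length, each with a
#'   positive sum.
#' @return dissimilarity in `[0, 1]`.
#' @export
bray_curtis <- function(x, y) {
  check_pair(x, y)
  sx <- sum(x)
  sy <- sum(y)
  if (sx == 0 || sy == 0)
    stop("Bray-Curtis undefined for a zero-sum sample", call. = FALSE)
  1 - 2 * sum(pmin(x, y)) / (sx + sy)
}

check_pair <- function(x, y) {
  if (length(x) != length(y))
    stop("count vectors differ in length", call. = FALSE)
  if (any(x < 0) || any(y < 0))
    stop("counts must be non-negative", call. = FALSE)
  invisible(NULL)
}

#' All-pairs beta-diversity distance matrix
#'
#' Computes the full symmetric sample-by-sample dissimilarity matrix for
#' one metric. The matrix agrees entrywise with the scalar metric
#' functions; pairwise loops are replaced by matrix algebra for speed.
#'
#' @param table a `feature_table`, normally rarefied to a common depth
#'   (a warning is issued when sample depths are unequal).
#' @param metric `"sorensen_dice"` or `"bray_curtis"`.
#' @return square numeric matrix with sample ids as dimnames, zero
#'   diagonal, class `c("dist_matrix", "matrix")`.
#' @export
beta_matrix <- function(table, metric = c("sorensen_dice", "bray_curtis")) {
  metric <- match.arg(metric)
  counts <- table$counts
  depths <- rowSums(counts)
  if (any(depths == 0)) {
    bad <- rownames(counts)[depths == 0]
    stop("zero-depth samples (dissimilarity undefined): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (length(unique(depths)) > 1L)
    warning("sample depths are unequal; rarefy before beta diversity",
            call. = FALSE)
  if (metric == "sorensen_dice") {
    p <- (counts > 0) * 1
    shared <- tcrossprod(p)               # |A n B|
    sizes <- rowSums(p)
    tot <- outer(sizes, sizes, "+")
    d <- 1 - 2 * shared / tot
  } else {
    # 1 - 2 sum(min)/(sx+sy) == sum|x-y| / (sx+sy)
    man <- as.matrix(stats::dist(counts, method = "manhattan"))
    d <- man / outer(depths, depths, "+")
  }
  diag(d) <- 0
  as_dist_matrix(d)
}

#' Mark/validate a square labelled dissimilarity matrix
#'
#' @param d square numeric matrix, symmetric, zero diagonal, finite
#'   non-negative entries, sample ids as dimnames.
#' @return `d` with class `c("dist_matrix", "matrix")`.
#' @export
as_dist_matrix <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop("distance matrix not square", call. = FALSE)
  if (is.null(rownames(d)))
    stop("distance matrix must carry sample labels", call. = FALSE)
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-10, check.attributes = FALSE)))
    stop("distance matrix not symmetric", call. = FALSE)
  if (any(!is.finite(d)) || any(d < -1e-12))
    stop("distances must be finite and non-negative", call. = FALSE)
  if (any(abs(diag(d)) > 1e-12))
    stop("distance matrix diagonal must be zero", call. = FALSE)
  colnames(d) <- rownames(d)
  class(d) <- c("dist_matrix", "matrix")
  d
}

#' Read / write a distance matrix TSV (square, labelled)
#' @param path file path.
#' @return a `dist_matrix`.
#' @export
read_dist_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1L)
  as_dist_matrix(as.matrix(df))
}

#' @rdname read_dist_matrix
#' @param d a `dist_matrix`.
#' @export
write_dist_matrix <- function(d, path) {
  df <- data.frame(sample_id = rownames(d), unclass(d), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Chao1 richness estimate
#'
#' Nonparametric richness estimator extrapolating unseen ASVs from
#' singleton (F1) and doubleton (F2) frequencies. The bias-corrected form
#' S_obs + F1 (F1 - 1) / (2 (F2 + 1)) is the default because it stays
#' defined when no doubletons are observed; the classic form
#' S_obs + F1^2 / (2 F2) is available via `bias_corrected = FALSE`.
#'
#' @param x non-negative integer count vector for one sample.
#' @param bias_corrected logical, default `TRUE`.
#' @return estimate, always >= observed richness.
#' @export
chao1 <- function(x, bias_corrected = TRUE) {
  if (any(x < 0) || any(x != round(x)))
    stop("Chao1 requires non-negative integer counts", call. = FALSE)
  s_obs <- sum(x > 0)
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  if (bias_corrected) return(s_obs + f1 * (f1 - 1) / (2 * (f2 + 1)))
  if (f2 == 0) {
    if (f1 == 0) return(s_obs)
    return(s_obs + f1 * (f1 - 1) / 2)  # classic form's F2 = 0 fallback
  }
  s_obs + f1^2 / (2 * f2)
}

#' Shannon entropy of a sample
#'
#' H = -sum p_i log_base(p_i) over ASVs with positive counts. Base 2 by
#' default (entropy in bits), matching common amplicon tooling; natural
#' log via `base = exp(1)`.
#'
#' @param x non-negative count vector with positive sum.
#' @param base logarithm base (default 2).
#' @return entropy >= 0.
#' @export
shannon <- function(x, base = 2) {
  if (any(x < 0)) stop("counts must be non-negative", call. = FALSE)
  tot <- sum(x)
  if (tot == 0) stop("Shannon undefined for an empty sample", call. = FALSE)
  p <- x[x > 0] / tot
  -sum(p * log(p, base = base))
}

#' Per-sample alpha diversity table
#'
#' @param table a `feature_table` (rarefied for comparability).
#' @param metrics any of `"chao1"`, `"shannon"`.
#' @param base Shannon logarithm base.
#' @return data.frame with `sample_id` and one column per metric.
#' @export
alpha_diversity <- function(table, metrics = c("chao1", "shannon"),
                            base = 2) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  out <- data.frame(sample_id = sample_ids(table))
  if ("chao1" %in% metrics)
    out$chao1 <- apply(table$counts, 1L, chao1)
  if ("shannon" %in% metrics)
    out$shannon <- apply(table$counts, 1L, shannon, base = base)
  out
}

# Gower-centered inner-product matrix G = -1/2 J D^2 J with J = I - 11'/n.
# Shared by PCoA, PERMANOVA and PERMDISP.
gower_center <- function(d) {
  a <- -0.5 * d^2
  rm <- rowMeans(a)
  sweep(sweep(a, 1L, rm), 2L, rm) + mean(a)
}

#' Principal coordinates analysis (classical metric scaling)
#'
#' Eigendecomposition of the Gower-double-centered matrix -1/2 J D^2 J.
#' Axes are ordered by descending eigenvalue. Negative eigenvalues (from
#' non-Euclidean dissimilarities such as Bray-Curtis) are reported
#' untouched; their coordinate columns are zeroed, and no Lingoes or
#' Cailliez correction is applied.
#'
#' @param dm a `dist_matrix`.
#' @param n_axes number of axes to return (default all).
#' @return list of class `pcoa_result` with `labels`, `coordinates`
#'   (samples x axes), `eigenvalues` and `proportion_explained` (relative
#'   to the sum of positive eigenvalues).
#' @export
pcoa <- function(dm, n_axes = nrow(dm) - 1L) {
  dm <- as_dist_matrix(dm)
  n <- nrow(dm)
  if (n_axes > n) stop("n_axes exceeds the number of samples", call. = FALSE)
  e <- eigen(gower_center(dm), symmetric = TRUE)
  ord <- order(e$values, decreasing = TRUE)
  vals <- e$values[ord]
  vecs <- e$vectors[, ord, drop = FALSE]
  coords <- vecs %*% diag(sqrt(pmax(vals, 0)), nrow = length(vals))
  coords[, vals <= 0] <- 0
  keep <- seq_len(n_axes)
  pos_sum <- sum(vals[vals > 0])
  structure(list(
    labels = rownames(dm),
    coordinates = matrix(coords[, keep, drop = FALSE], nrow = n,
                         dimnames = list(rownames(dm),
                                         paste0("PC", keep))),
    eigenvalues = vals[keep],
    proportion_explained = if (pos_sum > 0) pmax(vals[keep], 0) / pos_sum
                           else rep(0, n_axes)),
    class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("pcoa_result: %d samples, %d axes\n", length(x$labels),
              ncol(x$coordinates)))
  k <- min(3L, length(x$eigenvalues))
  cat("  first eigenvalues:",
      paste(signif(x$eigenvalues[seq_len(k)], 4), collapse = ", "), "\n")
  cat("  proportion explained:",
      paste(signif(x$proportion_explained[seq_len(k)], 3), collapse = ", "),
      "\n")
  invisible(x)
}

#' Write PCoA coordinates as TSV plus a JSON sidecar of eigenvalues
#' @param ord a `pcoa_result`.
#' @param path coordinate TSV path; the sidecar gets `.json` appended.
#' @return `path`, invisibly.
#' @export
write_ordination <- function(ord, path) {
  df <- data.frame(sample_id = ord$labels, ord$coordinates,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(eigenvalues = ord$eigenvalues,
         proportion_explained = ord$proportion_explained),
    paste0(path, ".json"), digits = NA)
  invisible(path)
}
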