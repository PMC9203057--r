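# Shared fixture builders: everything is generated in code, seeded.

# Minimal valid metadata for a set of sample ids.
make_meta <- function(ids, host_species = "coyote", population = "popA",
                      urban_status = "rural", source_dataset = "ds1") {
  data.frame(sample_id = ids,
             host_species = rep_len(host_species, length(ids)),
             population = rep_len(population, length(ids)),
             urban_status = rep_len(urban_status, length(ids)),
             source_dataset = rep_len(source_dataset, length(ids)),
             stringsAsFactors = FALSE)
}

# Random small feature table with roughly equal depths.
random_table <- function(n = 6, m = 10, depth = 400, seed = 1) {
  set.seed(seed)
  probs <- matrix(rgamma(n * m, shape = 0.8), n, m)
  counts <- t(vapply(seq_len(n), function(i)
    rmultinom(1, depth, probs[i, ])[, 1], numeric(m)))
  dimnames(counts) <- list(sprintf("s%02d", seq_len(n)),
                           sprintf("asv%02d", seq_len(m)))
  feature_table(counts)
}

# Euclidean distance matrix from a coordinate matrix (rows = samples).
euclid_dm <- function(xy) {
  rownames(xy) <- sprintf("s%02d", seq_len(nrow(xy)))
  as_dist_matrix(as.matrix(dist(xy)))
}

# Independent brute-force oracles -------------------------------------

oracle_sorensen <- function(x, y) {
  a <- names(which(x > 0)); b <- names(which(y > 0))
  if (is.null(names(x))) { a <- which(x > 0); b <- which(y > 0) }
  1 - 2 * length(intersect(a, b)) / (length(a) + length(b))
}

oracle_bray <- function(x, y) {
  s <- 0
  for (i in seq_along(x)) s <- s + min(x[i], y[i])
  1 - 2 * s / (sum(x) + sum(y))
}

oracle_chao1 <- function(x, bias_corrected = TRUE) {
  s <- sum(x > 0); f1 <- sum(x == 1); f2 <- sum(x == 2)
  if (bias_corrected) s + f1 * (f1 - 1) / (2 * (f2 + 1))
  else if (f2 > 0) s + f1^2 / (2 * f2)
  else s + f1 * (f1 - 1) / 2
}

oracle_shannon <- function(x, base = 2) {
  p <- x / sum(x); p <- p[p > 0]
  -sum(p * log(p)) / log(base)
}

# Kruskal-Wallis H with tie correction, from the definition.
oracle_kruskal_h <- function(values, groups) {
  n <- length(values)
  r <- rank(values)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, groups, function(ri) length(ri) * mean(ri)^2)) -
    3 * (n + 1)
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# All between-group distances by nested loops with membership tests.
oracle_between <- function(dm, labels, g1, g2) {
  out <- numeric()
  ids <- rownames(dm)
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (g1 == g2) {
      if (i < j && labels[ids[i]] == g1 && labels[ids[j]] == g1)
        out <- c(out, dm[i, j])
    } else if (labels[ids[i]] == g1 && labels[ids[j]] == g2) {
      out <- c(out, dm[i, j])
    }
  }
  out
}
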