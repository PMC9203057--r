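test_that("between_group_distances enumerates each pair exactly once", {
  set.seed(12)
  xy <- matrix(rnorm(18), 9, 2)
  dm <- euclid_dm(xy)
  meta <- make_meta(rownames(dm),
                    population = c(rep("g1", 2), rep("g2", 3), rep("g3", 4)))
  expect_length(between_group_distances(dm, meta, "g1", "g2"), 2 * 3)
  expect_length(between_group_distances(dm, meta, "g3", "g3"), choose(4, 2))
  labels <- setNames(meta$population, meta$sample_id)
  for (pair in list(c("g1", "g2"), c("g2", "g3"), c("g2", "g2"))) {
    got <- between_group_distances(dm, meta, pair[1], pair[2])
    expect_equal(sort(got), sort(oracle_between(dm, labels, pair[1],
                                                pair[2])))
  }
  expect_error(between_group_distances(dm, meta, "g1", "nope"), "nope")
})

test_that("identical distances give a zero statistic and p = 1", {
  n <- 8
  d <- matrix(0.5, n, n, dimnames = list(paste0("s", 1:n), paste0("s", 1:n)))
  diag(d) <- 0
  dm <- as_dist_matrix(d)
  meta <- make_meta(rownames(dm),
                    population = rep(c("u", "r", "h", "h"), each = 2))
  cmp <- mc_group_comparison(dm, meta, c("u", "h"), c("r", "h"),
                             n_perm = 99, seed = 4)
  expect_equal(cmp$stat_observed, 0)
  expect_equal(cmp$p_value, 1)
})

test_that("exact enumeration matches an independent brute-force null", {
  set.seed(99)
  xy <- matrix(rnorm(22), 11, 2)
  dm <- euclid_dm(xy)
  labels <- c(rep("A", 3), rep("B", 3), rep("H", 5))
  meta <- make_meta(rownames(dm), population = labels)
  got <- mc_group_comparison(dm, meta, c("A", "H"), c("B", "H"),
                             n_perm = "exact")
  # brute force: every way of assigning 3 of the 6 wildlife samples to A
  wild <- rownames(dm)[1:6]
  hum <- rownames(dm)[7:11]
  stat <- function(a_ids) {
    b_ids <- setdiff(wild, a_ids)
    mean(dm[a_ids, hum]) - mean(dm[b_ids, hum])
  }
  null <- combn(wild, 3, stat)
  expect_length(null, 20)
  obs <- stat(wild[1:3])
  expect_equal(got$stat_observed, obs)
  expect_equal(got$n_permutations, 20)
  expect_equal(got$p_value, mean(abs(null) >= abs(obs) - 1e-12))
  # one-tailed analogue
  got_lt <- mc_group_comparison(dm, meta, c("A", "H"), c("B", "H"),
                                n_perm = "exact", tail = "A_less")
  expect_equal(got_lt$p_value, mean(null <= obs + 1e-12))
})

test_that("Monte Carlo p converges to the exact p and is reproducible", {
  set.seed(5)
  xy <- matrix(rnorm(20), 10, 2)
  dm <- euclid_dm(xy)
  meta <- make_meta(rownames(dm),
                    population = c(rep("A", 3), rep("B", 3), rep("H", 4)))
  exact <- mc_group_comparison(dm, meta, c("A", "H"), c("B", "H"),
                               n_perm = "exact")$p_value
  mc1 <- mc_group_comparison(dm, meta, c("A", "H"), c("B", "H"),
                             n_perm = 1999, seed = 8)
  mc2 <- mc_group_comparison(dm, meta, c("A", "H"), c("B", "H"),
                             n_perm = 1999, seed = 8)
  expect_identical(mc1$p_value, mc2$p_value)   # bit-reproducible
  expect_lt(abs(mc1$p_value - exact), 0.08)
  expect_gte(mc1$p_value, 1 / 2000)            # +1 correction floor
})

test_that("PERMANOVA separates groups perfectly in the degenerate case", {
  dm <- euclid_dm(cbind(c(0, 0, 10, 10)))
  meta <- make_meta(rownames(dm), population = c("A", "A", "B", "B"))
  res <- adonis_dm(dm, meta, "population", n_perm = 0)
  expect_equal(res$r2[1], 1, tolerance = 1e-12)
  expect_equal(res$sum_sq[res$term == "Residual"], 0, tolerance = 1e-9)
})

test_that("PERMANOVA SS partition equals one-way ANOVA on scalar data", {
  set.seed(61)
  for (i in 1:5) {
    vals <- rnorm(12)
    g <- sample(rep(c("A", "B"), 6))
    ids <- sprintf("s%02d", 1:12)
    dm <- as_dist_matrix(`dimnames<-`(as.matrix(dist(vals)),
                                      list(ids, ids)))
    meta <- make_meta(ids, population = g)
    res <- adonis_dm(dm, meta, "population", n_perm = 0)
    an <- anova(lm(vals ~ g))
    expect_equal(res$sum_sq[1], an$`Sum Sq`[1], tolerance = 1e-9)
    expect_equal(res$sum_sq[res$term == "Residual"], an$`Sum Sq`[2],
                 tolerance = 1e-9)
    expect_equal(res$pseudo_f[1], an$`F value`[1], tolerance = 1e-9)
  }
})

test_that("PERMANOVA matches vegan::adonis2 sequential partitioning", {
  skip_if_not_installed("vegan")
  ft <- rarefy(random_table(n = 16, m = 20, seed = 44), 300, seed = 2)
  dm <- beta_matrix(ft, "bray_curtis")
  meta <- make_meta(sample_ids(ft),
                    host_species = rep(c("anole", "coyote"), 8),
                    population = rep(c("p1", "p2", "p3", "p4"), each = 4))
  res <- adonis_dm(dm, meta, c("host_species", "population"), n_perm = 99,
                   seed = 3)
  df <- data.frame(host_species = meta$host_species,
                   population = meta$population)
  ref <- vegan::adonis2(as.dist(unclass(dm)) ~ host_species + population,
                        data = df, by = "terms", permutations = 99)
  expect_equal(res$sum_sq[1:2], ref$SumOfSqs[1:2], tolerance = 1e-9)
  expect_equal(res$r2[1:2], ref$R2[1:2], tolerance = 1e-9)
  expect_equal(res$pseudo_f[1:2], ref$F[1:2], tolerance = 1e-9)
  expect_equal(sum(res$sum_sq[res$term != "Total"]),
               res$sum_sq[res$term == "Total"], tolerance = 1e-9)
  expect_equal(sum(res$r2[res$term != "Total"]), 1, tolerance = 1e-12)
})

test_that("PERMANOVA R2 is invariant to consistent sample reordering", {
  ft <- rarefy(random_table(n = 10, m = 15, seed = 9), 300, seed = 1)
  dm <- beta_matrix(ft, "sorensen_dice")
  meta <- make_meta(sample_ids(ft), population = rep(c("u", "r"), 5))
  base <- adonis_dm(dm, meta, "population", n_perm = 0)
  set.seed(2)
  perm <- sample(rownames(dm))
  dm2 <- as_dist_matrix(unclass(dm)[perm, perm])
  res <- adonis_dm(dm2, meta, "population", n_perm = 0)
  expect_equal(res$r2, base$r2, tolerance = 1e-12)
})

test_that("single-level terms and missing seeds are rejected", {
  dm <- euclid_dm(cbind(1:4))
  meta <- make_meta(rownames(dm))
  expect_error(adonis_dm(dm, meta, "population", n_perm = 99, seed = 1),
               "fewer than two levels")
  meta$population <- c("a", "a", "b", "b")
  expect_error(adonis_dm(dm, meta, "population", n_perm = 99), "seed")
})

test_that("PERMDISP contrasts dispersions and is label-symmetric", {
  set.seed(23)
  tight <- matrix(rnorm(10, sd = 1e-3), 5, 2)
  loose <- matrix(rnorm(10, sd = 2), 5, 2)
  dm <- euclid_dm(rbind(tight, loose))
  meta <- make_meta(rownames(dm), population = rep(c("t", "l"), each = 5))
  res <- permdisp(dm, meta, "population", n_perm = 199, seed = 6)
  expect_lt(res$dispersions[["t"]], 1e-2)
  expect_gt(res$dispersions[["l"]], 0.5)
  expect_lt(res$p_value, 0.05)
  # swapping group names leaves F unchanged
  meta2 <- meta
  meta2$population <- c(t = "l", l = "t")[meta$population]
  res2 <- permdisp(dm, meta2, "population", n_perm = 199, seed = 6)
  expect_equal(res2$f_statistic, res$f_statistic, tolerance = 1e-12)
  # singleton groups are refused
  meta$population[1] <- "solo"
  expect_error(permdisp(dm, meta, "population", n_perm = 9, seed = 1),
               "singleton")
})

test_that("PERMDISP centroid distances match vegan::betadisper", {
  skip_if_not_installed("vegan")
  set.seed(77)
  xy <- matrix(rnorm(24), 12, 2)
  dm <- euclid_dm(xy)
  g <- rep(c("a", "b"), 6)
  meta <- make_meta(rownames(dm), population = g)
  res <- permdisp(dm, meta, "population", n_perm = 0)
  ref <- vegan::betadisper(as.dist(unclass(dm)), g, type = "centroid")
  expect_equal(unname(res$dispersions[c("a", "b")]),
               unname(tapply(ref$distances, g, mean)), tolerance = 1e-8)
  expect_equal(res$f_statistic, anova(ref)$`F value`[1], tolerance = 1e-8)
})

test_that("Kruskal-Wallis wrapper matches the rank definition", {
  vals <- setNames(c(1, 2, 3, 10, 20, 30), paste0("s", 1:6))
  meta <- make_meta(names(vals), population = rep(c("a", "b"), each = 3))
  res <- kruskal_wallis(vals, meta, "population")
  expect_equal(res$h_statistic, 3.857142857, tolerance = 1e-8)
  expect_equal(res$df, 1)

  # identical groups: H = 0; all-tied: degenerate p = 1
  same <- setNames(c(5, 7, 9, 5, 7, 9), paste0("s", 1:6))
  expect_equal(kruskal_wallis(same, meta, "population")$h_statistic, 0)
  tied <- setNames(rep(4, 6), paste0("s", 1:6))
  expect_equal(kruskal_wallis(tied, meta, "population")$p_value, 1)

  # tie-corrected H equals the definitional oracle on random data
  set.seed(15)
  for (i in 1:20) {
    v <- setNames(sample(1:6, 9, replace = TRUE), paste0("s", 1:9))
    m <- make_meta(names(v), population = sample(c("a", "b", "c"), 9,
                                                 replace = TRUE))
    if (length(unique(m$population)) < 2 || length(unique(v)) == 1) next
    got <- kruskal_wallis(v, m, "population")
    expect_equal(got$h_statistic, oracle_kruskal_h(v, m$population),
                 tolerance = 1e-9)
  }
})
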