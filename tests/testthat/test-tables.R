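test_that("feature table construction enforces its invariants", {
  m <- matrix(c(3, 0, 1, 2), 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("a1", "a2")))
  ft <- feature_table(m)
  expect_identical(unname(ft$counts), unname(m * 1))
  expect_identical(sample_ids(ft), c("s1", "s2"))

  expect_error(feature_table(matrix(-1, 1, 1, dimnames = list("s", "a"))),
               "non-negative")
  expect_error(feature_table(matrix(1.5, 1, 1, dimnames = list("s", "a"))),
               "integral")
  dup <- matrix(1, 2, 1, dimnames = list(c("s1", "s1"), "a1"))
  expect_error(feature_table(dup), "duplicate sample")
})

test_that("TSV round-trip preserves random tables, both orientations", {
  for (seed in 1:5) {
    ft <- random_table(n = 5, m = 7, seed = seed)
    path <- withr::local_tempfile(fileext = ".tsv")
    write_feature_table(ft, path)
    back <- read_feature_table(path)
    expect_equal(back$counts, ft$counts)
  }
  # BIOM-style orientation: ASVs in rows, flagged by the header cell
  ft <- random_table(seed = 9)
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(`#ASV_ID` = asv_ids(ft), t(ft$counts),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_feature_table(path)
  expect_equal(back$counts, ft$counts)
})

test_that("malformed tables are rejected at read time", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\ta1\ta2", "s1\t3\t0", "s1\t1\t2"), path)
  expect_error(read_feature_table(path), "duplicate")
  writeLines(c("sample_id\ta1", "s1\t-3"), path)
  expect_error(read_feature_table(path), "negative")
  writeLines(c("sample_id\ta1", "s1\t2.5"), path)
  expect_error(read_feature_table(path), "integral")
  expect_equal(unname(read_feature_table(path, round = TRUE)$counts[1, 1]),
               2)
})

test_that("metadata reader validates the closed urban_status vocabulary", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_metadata(make_meta(c("s1", "s2"), urban_status = "urban"), path)
  md <- read_metadata(path)
  expect_identical(md$urban_status, c("urban", "urban"))
  write_metadata(transform(make_meta("s1"), urban_status = "suburbia"), path)
  expect_error(read_metadata(path), "urban_status")
})

test_that("low-depth filter removes per-group outliers below mean - 3 sd", {
  # hand-checkable group: 19 samples at depth 1000, one at depth 1
  counts <- matrix(0, 20, 2,
                   dimnames = list(sprintf("s%02d", 1:20), c("a1", "a2")))
  counts[, 1] <- c(rep(600, 19), 1)
  counts[, 2] <- c(rep(400, 19), 0)
  ft <- feature_table(counts)
  meta <- make_meta(sample_ids(ft))
  res <- filter_low_depth(ft, meta, grouping = "population")
  d <- c(rep(1000, 19), 1)
  thr <- mean(d) - 3 * sd(d)
  expect_gt(thr, 279); expect_lt(thr, 281)
  expect_identical(res$report$removed_low_depth$sample_id, "s20")
  expect_equal(res$report$removed_low_depth$group_threshold, thr)
  expect_identical(sort(c(removed_samples(res$report),
                          res$report$retained)),
                   sort(sample_ids(ft)))

  # equal depths: sd = 0, nobody removed
  eq <- feature_table(matrix(50, 4, 2, dimnames = list(paste0("e", 1:4),
                                                       c("a1", "a2"))))
  expect_length(removed_samples(
    filter_low_depth(eq, make_meta(sample_ids(eq)))$report), 0)
})

test_that("depth filter judges each group independently", {
  # s_lo is an outlier within group g1 only; group g2 spans wider depths
  depths <- c(rep(1000, 12), 150, round(seq(100, 2000, length.out = 10)))
  ids <- sprintf("x%02d", seq_along(depths))
  counts <- cbind(a1 = round(depths * 0.6), a2 = depths - round(depths * 0.6))
  rownames(counts) <- ids
  ft <- feature_table(counts)
  meta <- make_meta(ids, population = c(rep("g1", 13), rep("g2", 10)))
  res <- filter_low_depth(ft, meta, grouping = "population")
  # brute-force per-group thresholds
  expected <- unlist(lapply(split(ids, meta$population), function(s) {
    d <- sample_depths(ft)[s]
    s[d < mean(d) - 3 * sd(d)]
  }), use.names = FALSE)
  expect_setequal(res$report$removed_low_depth$sample_id, expected)
  expect_true("x13" %in% expected)   # the outlier relative to g1 only
  # a singleton group is retained with a warning (sd undefined)
  meta1 <- make_meta(ids, population = c("solo", rep("g", 22)))
  expect_warning(filter_low_depth(ft, meta1, grouping = "population"),
                 "single sample")
})

test_that("dominance filter uses a strict 75% boundary", {
  counts <- rbind(over = c(80, 10, 10),    # 0.80 -> removed
                  exact = c(75, 25, 0),    # exactly 0.75 -> retained
                  even = c(1, 1, 1),
                  empty = c(0, 0, 0))      # zero depth -> removed, flagged
  colnames(counts) <- c("a1", "a2", "a3")
  ft <- feature_table(counts)
  res <- filter_dominated(ft)
  expect_identical(res$report$removed_dominated$sample_id, "over")
  expect_equal(res$report$removed_dominated$max_asv_fraction, 0.8)
  expect_identical(res$report$removed_zero_depth, "empty")
  expect_setequal(res$report$retained, c("exact", "even"))
})

test_that("QC filters are idempotent", {
  ft <- random_table(n = 12, m = 6, seed = 3)
  ft$counts["s01", ] <- c(500, 1, 0, 0, 0, 0)  # dominated
  meta <- make_meta(sample_ids(ft))
  once <- qc_filter(ft, meta)
  twice <- qc_filter(once$table, meta)
  expect_identical(sample_ids(twice$table), sample_ids(once$table))
  expect_length(removed_samples(twice$report), 0)
})

test_that("rarefaction hits the target depth exactly and is bounded", {
  counts <- rbind(s1 = c(120, 0, 0), s2 = c(60, 40, 0), s3 = c(100, 50, 50))
  colnames(counts) <- c("a1", "a2", "a3")
  ft <- feature_table(counts)
  r <- rarefy(ft, "auto", seed = 11)
  expect_equal(attr(r, "rarefaction_depth"), floor(0.9 * 100))
  expect_true(all(sample_depths(r) == 90))
  expect_true(all(r$counts <= ft$counts))

  # single-ASV sample: only one possible outcome
  one <- feature_table(matrix(50, 1, 1, dimnames = list("s", "a")))
  expect_equal(unname(rarefy(one, 10, seed = 1)$counts[1, 1]), 10)

  # determinism and seed sensitivity
  expect_identical(rarefy(ft, 90, seed = 5)$counts,
                   rarefy(ft, 90, seed = 5)$counts)
  r2 <- rarefy(ft, 90, seed = 6)
  expect_true(all(sample_depths(r2) == 90))

  expect_error(rarefy(ft, 121, seed = 1), "s1")
  expect_error(rarefy(ft, 90), "seed")
})

test_that("empty ASV columns are kept by default, dropped on request", {
  counts <- rbind(s1 = c(10, 1, 0), s2 = c(12, 2, 0))
  colnames(counts) <- c("a1", "a2", "a3")
  ft <- feature_table(counts)
  r <- rarefy(ft, 5, seed = 2)
  expect_identical(asv_ids(r), c("a1", "a2", "a3"))
  r2 <- rarefy(ft, 5, seed = 2, drop_empty = TRUE)
  expect_false("a3" %in% asv_ids(r2))
})
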