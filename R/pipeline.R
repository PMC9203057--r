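#' Run the full convergence analysis on one study
#'
#' Orchestrates the standard stage order: sample QC (group-wise depth
#' filter, then single-ASV dominance filter); rarefaction; alpha
#' diversity with Kruskal-Wallis tests; beta-diversity matrices;
#' multi-term PERMANOVA and PERMDISP; the headline Monte Carlo
#' comparisons (urban-wildlife-to-human vs rural-wildlife-to-human mean
#' dissimilarity, per wildlife species); ANCOM urban-vs-rural contrasts
#' per host species; exclusive ASV sharing with equal-n subsampling; and
#' an optional outlier-exclusion/subsample consensus protocol.
#'
#' Rarefaction depth is recomputed for every analysis subset (each
#' species-plus-humans comparison rarefies its own samples to 90% of
#' their minimum depth) rather than inherited from the global table, so
#' that no subset is penalized by another subset's shallowest sample.
#'
#' @param table a `feature_table` of raw counts.
#' @param meta sample metadata covering the table.
#' @param config list of options: `seed` (required), `qc_group`
#'   (default `"source_dataset"`), `metric` for the headline tests
#'   (default `"sorensen_dice"`), `tail` (default `"A_less"`: the
#'   directional humanization hypothesis), `n_perm` (default 999),
#'   `sharing_reps` (default 10), `exclude` (sample ids for the
#'   sensitivity rerun, default none), `subsample` (list with `group`
#'   label, `k`, `n_reps` for the fixed-size subsample protocol,
#'   default none), `alpha` (significance level, default 0.05).
#' @param out_dir optional directory; when given, every stage artifact
#'   is written as TSV/JSON and listed in the manifest.
#' @return list of class `convergence_run`: `manifest` plus the stage
#'   outputs (`qc`, `rarefied`, `alpha`, `alpha_tests`, `beta`,
#'   `adonis`, `permdisp`, `headline`, `ancom`, `sharing`,
#'   `consensus`).
#' @export
run_convergence_analysis <- function(table, meta, config = list(),
                                     out_dir = NULL) {
  defaults <- list(qc_group = "source_dataset", metric = "sorensen_dice",
                   tail = "A_less", n_perm = 999, sharing_reps = 10,
                   exclude = character(), subsample = NULL, alpha = 0.05)
  config <- utils::modifyList(defaults, config)
  if (is.null(config$seed))
    stop("config$seed is required", call. = FALSE)
  seed <- as.integer(config$seed)
  meta <- validate_metadata(meta)

  manifest <- list(
    input = list(n_samples = nrow(table$counts), n_asvs = ncol(table$counts),
                 total_reads = sum(table$counts)),
    config = config[c("qc_group", "metric", "tail", "n_perm",
                      "sharing_reps", "alpha")],
    seeds = list(base = seed),
    stages = character())
  out <- list()
  stage <- function(name) manifest$stages <<- c(manifest$stages, name)

  # --- QC -------------------------------------------------------------
  stage("qc")
  qc <- qc_filter(table, meta, grouping = config$qc_group)
  out$qc <- qc$report
  tab <- qc$table
  meta_q <- meta[meta$sample_id %in% sample_ids(tab), , drop = FALSE]

  # --- global rarefaction (alpha, adonis, permdisp) --------------------
  stage("rarefy")
  manifest$seeds$rarefy <- seed + 1L
  rar <- rarefy(tab, "auto", seed = manifest$seeds$rarefy)
  manifest$rarefaction_depth <- attr(rar, "rarefaction_depth")
  out$rarefied <- rar

  # --- alpha diversity -------------------------------------------------
  stage("alpha")
  out$alpha <- alpha_diversity(rar)
  out$alpha_tests <- list()
  for (metric in c("chao1", "shannon")) {
    vals <- stats::setNames(out$alpha[[metric]], out$alpha$sample_id)
    out$alpha_tests[[metric]] <- lapply(
      split(names(vals), meta_q$host_species[match(names(vals),
                                                   meta_q$sample_id)]),
      function(ids) {
        m <- meta_q[meta_q$sample_id %in% ids, , drop = FALSE]
        if (length(unique(m$population)) < 2L) return(NULL)
        kruskal_wallis(vals[ids], m, "population")
      })
  }

  # --- beta diversity + PERMANOVA/PERMDISP -----------------------------
  stage("beta")
  out$beta <- list(sorensen_dice = beta_matrix(rar, "sorensen_dice"),
                   bray_curtis = beta_matrix(rar, "bray_curtis"))
  stage("adonis")
  manifest$seeds$adonis <- seed + 2L
  out$adonis <- lapply(out$beta, adonis_dm, meta = meta_q,
                       terms = c("host_species", "population",
                                 "urban_status"),
                       n_perm = config$n_perm,
                       seed = manifest$seeds$adonis)
  stage("permdisp")
  manifest$seeds$permdisp <- seed + 3L
  out$permdisp <- lapply(out$beta, permdisp, meta = meta_q,
                         group = "population", n_perm = config$n_perm,
                         seed = manifest$seeds$permdisp)

  # --- headline comparisons (per wildlife species, own rarefaction) ---
  stage("headline")
  wild <- setdiff(unique(meta_q$host_species), "human")
  human_ids <- meta_q$sample_id[meta_q$host_species == "human"]
  out$headline <- list()
  for (i in seq_along(wild)) {
    sp <- wild[i]
    sp_seed <- seed + 10L + i
    manifest$seeds[[paste0("headline_", sp)]] <- sp_seed
    out$headline[[sp]] <- headline_comparison(
      tab, meta_q, species = sp, human_ids = human_ids,
      metric = config$metric, tail = config$tail, n_perm = config$n_perm,
      seed = sp_seed)
  }

  # --- ANCOM urban vs rural, per host species --------------------------
  stage("ancom")
  out$ancom <- list()
  sp_all <- unique(meta_q$host_species)
  for (i in seq_along(sp_all)) {
    sp <- sp_all[i]
    m <- meta_q[meta_q$host_species == sp, , drop = FALSE]
    if (!all(c("urban", "rural") %in% m$urban_status)) next
    keep <- m$sample_id[m$urban_status %in% c("urban", "rural")]
    sub <- subset_samples(tab, keep, drop_empty = TRUE)
    sp_seed <- seed + 100L + i
    manifest$seeds[[paste0("ancom_", sp)]] <- sp_seed
    sub_r <- rarefy(sub, "auto", seed = sp_seed, drop_empty = TRUE)
    out$ancom[[sp]] <- ancom_w(sub_r, m, group = "urban_status",
                               levels = c("rural", "urban"),
                               alpha = config$alpha)
  }

  # --- exclusive sharing ----------------------------------------------
  stage("sharing")
  out$sharing <- list()
  for (i in seq_along(wild)) {
    sp <- wild[i]
    m <- meta_q[meta_q$host_species == sp, , drop = FALSE]
    upop <- unique(m$population[m$urban_status == "urban"])
    rpop <- unique(m$population[m$urban_status == "rural"])
    if (!length(upop) || !length(rpop)) next
    keep <- c(m$sample_id[m$population %in% c(upop[1], rpop[1])], human_ids)
    sp_seed <- seed + 200L + i
    manifest$seeds[[paste0("sharing_", sp)]] <- sp_seed
    sub_r <- rarefy(subset_samples(tab, keep), "auto", seed = sp_seed)
    out$sharing[[sp]] <- subsampled_sharing(
      sub_r, meta_q[meta_q$sample_id %in% keep, , drop = FALSE],
      human_samples = human_ids, urban_pop = upop[1], rural_pop = rpop[1],
      n_reps = config$sharing_reps, seed = sp_seed + 1L)
  }

  # --- consensus robustness protocol ----------------------------------
  stage("consensus")
  out$consensus <- list()
  for (i in seq_along(wild)) {
    sp <- wild[i]
    base <- out$headline[[sp]]
    if (is.null(base)) next
    runs <- list(total = base$comparison)
    analysis <- function(ids) {
      headline_comparison(tab, meta_q, species = sp, human_ids = human_ids,
                          metric = config$metric, tail = config$tail,
                          n_perm = config$n_perm,
                          seed = manifest$seeds[[paste0("headline_", sp)]],
                          restrict = ids)$comparison
    }
    sp_samples <- meta_q$sample_id[meta_q$host_species %in% c(sp, "human")]
    if (length(config$exclude) &&
        any(config$exclude %in% sp_samples))
      runs$excluded <- rerun_without(analysis, sp_samples,
                                     intersect(config$exclude, sp_samples))
    if (!is.null(config$subsample)) {
      ss <- config$subsample
      grp <- meta_q$sample_id[meta_q$population == ss$group &
                                meta_q$host_species == sp]
      if (length(grp) >= ss$k)
        runs$subsampled <- subsample_runs(
          analysis, sp_samples, grp, k = ss$k,
          n_reps = if (is.null(ss$n_reps)) 5L else ss$n_reps,
          seed = seed + 300L + i)
    }
    out$consensus[[sp]] <- consensus(runs, alpha = config$alpha)
  }

  out$manifest <- manifest
  class(out) <- "convergence_run"
  if (!is.null(out_dir)) write_run(out, meta_q, out_dir)
  out
}

# One species' headline test: subset to the species + humans, rarefy the
# subset to its own auto depth, and compare mean dissimilarity of
# (urban wildlife ~ human) against (rural wildlife ~ human).
headline_comparison <- function(table, meta, species, human_ids, metric,
                                tail, n_perm, seed, restrict = NULL) {
  m <- meta[meta$host_species %in% c(species, "human"), , drop = FALSE]
  ids <- c(m$sample_id[m$host_species == species &
                         m$urban_status %in% c("urban", "rural")],
           intersect(human_ids, m$sample_id))
  if (!is.null(restrict)) ids <- intersect(ids, restrict)
  m <- m[m$sample_id %in% ids, , drop = FALSE]
  m$analysis_group <- ifelse(m$host_species == "human", "human",
                             paste(species, m$urban_status, sep = "_"))
  groups <- unique(m$analysis_group)
  need <- c(paste(species, "urban", sep = "_"),
            paste(species, "rural", sep = "_"), "human")
  if (!all(need %in% groups))
    stop("headline comparison for '", species,
         "' needs urban and rural wildlife plus humans", call. = FALSE)
  sub <- rarefy(subset_samples(table, m$sample_id), "auto", seed = seed)
  dm <- beta_matrix(sub, metric)
  cmp <- mc_group_comparison(
    dm, m, pair_A = c(need[1], "human"), pair_B = c(need[2], "human"),
    grouping = "analysis_group", n_perm = n_perm, tail = tail, seed = seed)
  list(comparison = cmp, dm = dm,
       rarefaction_depth = attr(sub, "rarefaction_depth"),
       samples = m$sample_id)
}

#' @export
print.convergence_run <- function(x, ...) {
  cat("convergence_run:", length(x$manifest$stages), "stages on",
      x$manifest$input$n_samples, "samples\n")
  cat("  rarefaction depth:", x$manifest$rarefaction_depth, "\n")
  for (sp in names(x$headline)) {
    cmp <- x$headline[[sp]]$comparison
    cat(sprintf("  %s: d(urban~human) = %.3f, d(rural~human) = %.3f, p = %.4g\n",
                sp, cmp$mean_A, cmp$mean_B, cmp$p_value))
  }
  invisible(x)
}

# Write every stage artifact as plain text (TSV/JSON); byte-identical
# across reruns with the same inputs and seeds.
write_run <- function(run, meta, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  jsonlite::write_json(list(
    retained = run$qc$retained,
    removed_low_depth = run$qc$removed_low_depth,
    removed_dominated = run$qc$removed_dominated,
    removed_zero_depth = run$qc$removed_zero_depth),
    p("qc_report.json"), digits = NA)
  write_feature_table(run$rarefied, p("rarefied_table.tsv"))
  utils::write.table(run$alpha, p("alpha_diversity.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (metric in names(run$beta))
    write_dist_matrix(run$beta[[metric]], p(paste0("beta_", metric, ".tsv")))
  for (metric in names(run$adonis))
    utils::write.table(run$adonis[[metric]],
                       p(paste0("adonis_", metric, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  heads <- do.call(rbind, lapply(names(run$headline), function(sp) {
    cmp <- run$headline[[sp]]$comparison
    data.frame(species = sp,
               pair_A = paste(cmp$pair_A, collapse = "~"),
               pair_B = paste(cmp$pair_B, collapse = "~"),
               mean_A = cmp$mean_A, mean_B = cmp$mean_B,
               stat = cmp$stat_observed, p = cmp$p_value,
               n_perm = cmp$n_permutations, tail = cmp$tail,
               seed = cmp$seed)
  }))
  if (!is.null(heads))
    utils::write.table(heads, p("headline_comparisons.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  for (sp in names(run$ancom))
    utils::write.table(run$ancom[[sp]], p(paste0("ancom_", sp, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(run$sharing))
    jsonlite::write_json(lapply(run$sharing, function(s)
      list(n_urban_exclusive = s$n_urban_exclusive,
           n_rural_exclusive = s$n_rural_exclusive,
           unsubsampled = as.list(s$unsubsampled),
           replicates = s$replicates,
           urban_exclusive_asvs = s$urban_exclusive_asvs,
           rural_exclusive_asvs = s$rural_exclusive_asvs)),
      p("sharing.json"), digits = NA)
  if (length(run$consensus))
    jsonlite::write_json(lapply(run$consensus, function(cn)
      list(runs = cn$runs, alpha = cn$alpha,
           consensus_significant = cn$consensus_significant)),
      p("consensus.json"), digits = NA)
  jsonlite::write_json(run$manifest, p("manifest.json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(out_dir)
}
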