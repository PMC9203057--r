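#' Configuration of a synthetic urbanization study
#'
#' Parameterizes a multi-host-species, urban-gradient ASV study with
#' known ground truth. Each host species owns a set of core ASVs; a
#' shared human-associated ASV pool (led by a dominant Bacteroides-like
#' focal ASV) penetrates wildlife gut communities with a weight that
#' grows with each population's humanization parameter h in `[0, 1]`.
#' Sample compositions are Dirichlet draws around the population's
#' expected profile, and counts are multinomial at lognormal sequencing
#' depths, so rarefaction to 90% of the minimum depth is non-trivial.
#'
#' @param species named list; each element has a `populations`
#'   data.frame with columns `name`, `n`, `urban_status`, `h`.
#' @param humans list with a `populations` data.frame (columns `name`,
#'   `n`, `urban_status`); humans always carry the full human pool.
#' @param m_core core ASVs per host species (humans included).
#' @param m_human_pool size of the human-associated pool.
#' @param focal_asv_abundance expected relative abundance of the focal
#'   pool ASV in urban humans (default 0.15).
#' @param rural_focal_fraction the rural-human focal share as a fraction
#'   of the urban share (default 0.2, i.e. 3% when urban is 15%).
#' @param pool_other_share total expected share of the non-focal pool
#'   ASVs in humans (default 0.25).
#' @param base_mix humanization weight floor shared by all wildlife
#'   (default 0.02): background exposure that gives rural animals a
#'   small, symmetric overlap with the human pool.
#' @param human_mix_max additional pool weight at h = 1 (default 0.3);
#'   a population's pool weight is `base_mix + h * human_mix_max`, so
#'   host-species identity stays the dominant signal even when h = 1.
#' @param depth_meanlog,depth_sdlog lognormal read-depth parameters
#'   (defaults log(5000) and 0.15).
#' @param dirichlet_concentration Dirichlet precision around the
#'   expected profile (default 50; smaller = noisier communities).
#' @param qc_fault_rates named numeric: per-sample probabilities of the
#'   injected faults `low_depth` (depth cut to 1%), `dominated` (90% of
#'   reads moved to one ASV) and `outlier` (a wildlife sample generated
#'   at h = 1). Default all 0.
#' @param seed default RNG seed used by [generate_study()].
#' @return a validated list of class `study_config`.
#' @export
study_config <- function(
    species = list(
      coyote = list(populations = data.frame(
        name = c("Edmonton", "Leduc"),
        n = c(15L, 25L),
        urban_status = c("urban", "rural"),
        h = c(0.8, 0)))),
    humans = list(populations = data.frame(
      name = c("USA", "Malawi"),
      n = c(20L, 15L),
      urban_status = c("urban", "rural"))),
    m_core = 60L, m_human_pool = 40L,
    focal_asv_abundance = 0.15, rural_focal_fraction = 0.2,
    pool_other_share = 0.25,
    base_mix = 0.02, human_mix_max = 0.3,
    depth_meanlog = log(5000), depth_sdlog = 0.15,
    dirichlet_concentration = 50,
    qc_fault_rates = c(low_depth = 0, dominated = 0, outlier = 0),
    seed = NULL) {
  cfg <- list(species = species, humans = humans, m_core = as.integer(m_core),
              m_human_pool = as.integer(m_human_pool),
              focal_asv_abundance = focal_asv_abundance,
              rural_focal_fraction = rural_focal_fraction,
              pool_other_share = pool_other_share,
              base_mix = base_mix, human_mix_max = human_mix_max,
              depth_meanlog = depth_meanlog, depth_sdlog = depth_sdlog,
              dirichlet_concentration = dirichlet_concentration,
              qc_fault_rates = qc_fault_rates, seed = seed)
  validate_study_config(cfg)
}

validate_study_config <- function(cfg) {
  if (!length(cfg$species)) stop("config needs >= 1 species", call. = FALSE)
  if (is.null(names(cfg$species)) || any(names(cfg$species) == ""))
    stop("species list must be named", call. = FALSE)
  for (sp in names(cfg$species)) {
    pops <- cfg$species[[sp]]$populations
    if (!all(c("name", "n", "urban_status", "h") %in% names(pops)))
      stop("populations of '", sp,
           "' need columns name, n, urban_status, h", call. = FALSE)
    if (any(pops$h < 0 | pops$h > 1))
      stop("h must lie in [0, 1]", call. = FALSE)
    if (any(pops$n <= 0)) stop("population sizes must be positive",
                               call. = FALSE)
    bad <- setdiff(pops$urban_status, c("urban", "semiurban", "rural"))
    if (length(bad)) stop("invalid urban_status: ",
                          paste(bad, collapse = ", "), call. = FALSE)
  }
  if (cfg$m_core < 2L || cfg$m_human_pool < 2L)
    stop("m_core and m_human_pool must be >= 2", call. = FALSE)
  stopifnot(cfg$focal_asv_abundance > 0,
            cfg$focal_asv_abundance + cfg$pool_other_share < 1,
            cfg$base_mix >= 0, cfg$base_mix + cfg$human_mix_max <= 1,
            cfg$dirichlet_concentration > 0)
  rates <- cfg$qc_fault_rates
  if (any(rates < 0) || sum(rates) > 1)
    stop("qc_fault_rates must be probabilities summing to <= 1",
         call. = FALSE)
  structure(cfg, class = "study_config")
}

#' Read/write a study configuration as YAML
#' @param path YAML file path.
#' @return a `study_config`.
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$species <- lapply(raw$species, function(sp) {
    sp$populations <- as.data.frame(sp$populations)
    sp
  })
  raw$humans$populations <- as.data.frame(raw$humans$populations)
  raw$qc_fault_rates <- unlist(raw$qc_fault_rates)
  do.call(study_config, raw)
}

#' @rdname read_study_config
#' @param cfg a `study_config`.
#' @export
write_study_config <- function(cfg, path) {
  out <- unclass(cfg)
  out$species <- lapply(out$species, function(sp) {
    sp$populations <- as.list(sp$populations)
    sp
  })
  out$humans$populations <- as.list(out$humans$populations)
  out$qc_fault_rates <- as.list(out$qc_fault_rates)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Generate a synthetic urbanization study with ground truth
#'
#' @param config a [study_config()].
#' @param seed RNG seed (defaults to `config$seed`); the whole study is
#'   a deterministic function of (config, seed).
#' @return list with `table` (a `feature_table`), `meta` (sample
#'   metadata data.frame) and `truth` (class `study_truth`): the human
#'   pool and focal ASV ids, per-population h, expected per-population
#'   ASV profiles, and the ids of injected fault samples.
#' @export
generate_study <- function(config, seed = config$seed) {
  config <- validate_study_config(config)
  if (is.null(seed)) stop("generate_study requires a seed", call. = FALSE)

  pool_ids <- sprintf("human_pool_%03d", seq_len(config$m_human_pool))
  focal_id <- pool_ids[1]
  core_ids <- lapply(names(config$species), function(sp)
    sprintf("%s_core_%03d", sp, seq_len(config$m_core)))
  names(core_ids) <- names(config$species)
  human_core_ids <- sprintf("human_core_%03d", seq_len(config$m_core))
  all_ids <- c(unlist(core_ids, use.names = FALSE), human_core_ids, pool_ids)

  # Rank-abundance shapes: geometric core profile, harmonic pool tail.
  core_shape <- 0.93^seq_len(config$m_core)
  core_shape <- core_shape / sum(core_shape)
  other_w <- 1 / seq_len(config$m_human_pool - 1L)
  other_w <- other_w / sum(other_w)

  human_profile <- function(status) {
    f <- config$focal_asv_abundance *
      if (status == "urban") 1
      else if (status == "rural") config$rural_focal_fraction
      else (1 + config$rural_focal_fraction) / 2
    p <- stats::setNames(numeric(length(all_ids)), all_ids)
    p[focal_id] <- f
    p[pool_ids[-1]] <- config$pool_other_share * other_w
    p[human_core_ids] <- (1 - f - config$pool_other_share) * core_shape
    p
  }
  # Pool composition wildlife converge toward: the urban-human pool.
  pool_profile <- stats::setNames(numeric(length(all_ids)), all_ids)
  pool_profile[focal_id] <- config$focal_asv_abundance
  pool_profile[pool_ids[-1]] <- config$pool_other_share * other_w
  pool_profile <- pool_profile / sum(pool_profile)

  wildlife_profile <- function(sp, h) {
    w <- config$base_mix + h * config$human_mix_max
    p <- stats::setNames(numeric(length(all_ids)), all_ids)
    p[core_ids[[sp]]] <- (1 - w) * core_shape
    p + w * pool_profile
  }

  plan <- list()
  for (sp in names(config$species)) {
    pops <- config$species[[sp]]$populations
    for (r in seq_len(nrow(pops)))
      plan[[length(plan) + 1L]] <- list(
        species = sp, pop = pops$name[r], status = pops$urban_status[r],
        h = pops$h[r], n = pops$n[r],
        profile = wildlife_profile(sp, pops$h[r]),
        outlier_profile = wildlife_profile(sp, 1),
        dataset = paste0(sp, "_study"))
  }
  hpops <- config$humans$populations
  for (r in seq_len(nrow(hpops)))
    plan[[length(plan) + 1L]] <- list(
      species = "human", pop = hpops$name[r], status = hpops$urban_status[r],
      h = NA_real_, n = hpops$n[r],
      profile = human_profile(hpops$urban_status[r]),
      outlier_profile = NULL,
      dataset = paste0("human_", hpops$name[r]))

  rates <- config$qc_fault_rates[c("low_depth", "dominated", "outlier")]
  rates[is.na(rates)] <- 0
  names(rates) <- c("low_depth", "dominated", "outlier")
  res <- with_seed(seed, {
    counts <- matrix(0, nrow = sum(vapply(plan, `[[`, 0L, "n")),
                     ncol = length(all_ids),
                     dimnames = list(NULL, all_ids))
    meta <- vector("list", length(plan))
    faults <- list(low_depth = character(), dominated = character(),
                   outlier = character())
    row <- 0L
    rn <- character(nrow(counts))
    for (pl in plan) {
      for (i in seq_len(pl$n)) {
        row <- row + 1L
        sid <- sprintf("%s_%s_%02d", pl$species, pl$pop, i)
        rn[row] <- sid
        fault <- "none"
        if (sum(rates) > 0) {
          u <- stats::runif(1)
          cuts <- cumsum(rates)
          fault <- if (u < cuts[1]) "low_depth"
          else if (u < cuts[2]) "dominated"
          else if (u < cuts[3] && !is.null(pl$outlier_profile)) "outlier"
          else "none"
        }
        profile <- if (fault == "outlier") pl$outlier_profile else pl$profile
        depth <- round(stats::rlnorm(1, config$depth_meanlog,
                                     config$depth_sdlog))
        if (fault == "low_depth") depth <- max(10L, round(depth * 0.01))
        pos <- profile > 0
        alpha <- config$dirichlet_concentration * profile[pos]
        gam <- stats::rgamma(sum(pos), shape = alpha)
        if (sum(gam) == 0) gam[] <- 1
        x <- stats::rmultinom(1, depth, prob = gam / sum(gam))[, 1]
        full <- numeric(length(all_ids))
        full[pos] <- x
        if (fault == "dominated") {
          dom <- which.max(full)
          n_dom <- ceiling(0.9 * depth)
          rest <- full
          rest[dom] <- 0
          redist <- if (depth - n_dom > 0 && sum(rest) > 0)
            stats::rmultinom(1, depth - n_dom, prob = rest / sum(rest))[, 1]
          else numeric(length(full))
          full <- redist
          full[dom] <- n_dom
        }
        counts[row, ] <- full
        if (fault != "none") faults[[fault]] <- c(faults[[fault]], sid)
        meta[[row]] <- data.frame(
          sample_id = sid, host_species = pl$species, population = pl$pop,
          urban_status = pl$status, source_dataset = pl$dataset)
      }
    }
    rownames(counts) <- rn
    list(counts = counts, meta = do.call(rbind, meta), faults = faults)
  })

  expected <- do.call(rbind, lapply(plan, `[[`, "profile"))
  rownames(expected) <- vapply(plan, `[[`, "", "pop")
  truth <- structure(list(
    human_pool_asv_ids = pool_ids,
    focal_asv_id = focal_id,
    populations = do.call(rbind, lapply(plan, function(pl)
      data.frame(species = pl$species, population = pl$pop,
                 urban_status = pl$status, h = pl$h, n = pl$n))),
    expected_profiles = expected,
    fault_samples = res$faults,
    seed = seed), class = "study_truth")

  taxonomy <- stats::setNames(
    c("d__Bacteria; g__Bacteroides",
      rep("d__Bacteria; human-associated", config$m_human_pool - 1L)),
    pool_ids)
  list(table = feature_table(res$counts, taxonomy = taxonomy),
       meta = res$meta, truth = truth)
}

#' Generate a single-species study along an ordered humanization gradient
#'
#' One wildlife population per h level (plus the configured humans),
#' emulating an urban-to-rural transect: downstream, the population-mean
#' Sorensen-Dice dissimilarity to humans should be monotone decreasing
#' in h.
#'
#' @param config a [study_config()]; its species list is replaced.
#' @param levels ordered humanization values, >= 3 of them (e.g.
#'   `c(0.8, 0.5, 0.3, 0)`); duplicates or unordered values are allowed
#'   with a warning.
#' @param n_per_pop samples per gradient population (default 20).
#' @param species_name name for the gradient species.
#' @param seed RNG seed.
#' @return as [generate_study()]; `truth$gradient_levels` records the
#'   per-population h in gradient order.
#' @export
gradient_study <- function(config = study_config(), levels, n_per_pop = 20L,
                           species_name = "gradient_sp",
                           seed = config$seed) {
  if (length(levels) < 3L) stop("need >= 3 gradient levels", call. = FALSE)
  if (anyDuplicated(levels) || is.unsorted(rev(levels)))
    warning("gradient levels are unordered or duplicated", call. = FALSE)
  status <- rep("semiurban", length(levels))
  status[which.max(levels)] <- "urban"
  status[which.min(levels)] <- "rural"
  pops <- data.frame(
    name = sprintf("site%02d_h%s", seq_along(levels), gsub("\\.", "p",
                                                           format(levels))),
    n = n_per_pop, urban_status = status, h = levels)
  config$species <- stats::setNames(list(list(populations = pops)),
                                    species_name)
  out <- generate_study(validate_study_config(config), seed = seed)
  out$truth$gradient_levels <- stats::setNames(levels, pops$name)
  out
}

#' @export
print.study_truth <- function(x, ...) {
  cat("study_truth:", nrow(x$populations), "populations;",
      length(x$human_pool_asv_ids), "human-pool ASVs; focal =",
      x$focal_asv_id, "\n")
  print(x$populations, row.names = FALSE)
  nf <- lengths(x$fault_samples)
  if (any(nf > 0))
    cat("  injected faults:",
        paste(sprintf("%s=%d", names(nf), nf), collapse = ", "), "\n")
  invisible(x)
}
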