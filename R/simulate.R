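#' Configuration for the quasi-clonal lineage simulator
#'
#' Defaults describe the stated world the package is validated against: a
#' selfing lineage founded around 1600 by a colonization bottleneck, ~100
#' samples collected 1863-2006 (herbarium + modern), a substitution rate of
#' 2.11e-9 site^-1 year^-1 over a 1.08e8 bp accessible genome, and a
#' seed-bank-delayed mean generation time of 1.3 years.
#'
#' @param seed integer RNG seed
#' @param founder_year calendar year CE of the lineage founder
#' @param sample_years named list with numeric vectors `herbarium` and
#'   `modern` of collection years; `NULL` gives the default design of 27
#'   herbarium samples spread evenly over 1863-1993 (at least one per
#'   decade) and 73 modern samples over 1993-2006
#' @param mu_per_site_year substitution rate, site^-1 year^-1
#' @param accessible_length named numeric of callable bp per annotation class
#'   (a `total` element is added automatically)
#' @param genealogy `"star"` (independent branches from the founder; the
#'   post-bottleneck expansion limit), `"coalescent"` (random genealogy
#'   rescaled so the root sits at the founder) or `"forward_wf"` (small
#'   selfing Wright-Fisher population with seed-bank generation intervals)
#' @param selection_coding retention probability in (0,1] for coding
#'   mutations; 1 = neutral.  Models purifying selection as thinning.
#' @param growth_beta expansion strength of the coalescent mode: node depths
#'   are compressed rootward as `rel^beta`, so 1 = constant size and larger
#'   values give the star-like, singleton-rich genealogies of a
#'   bottleneck-then-expansion; the default reproduces the strongly negative
#'   Tajima's D and the few-percent common-variant fraction the package is
#'   validated against
#' @param generation_time_years mean generation interval (seed-bank delayed)
#' @param missing_rate_herbarium,missing_rate_modern per-cell missingness
#' @param founder_n effective founder population size (forward_wf only)
#' @param n_causal,target_h2,n_replicates phenotype generation parameters
#' @param max_mutations guard against runaway simulations
#' @return a `sim_config` list
#' @export
sim_config <- function(seed = 1L,
                       founder_year = 1600,
                       sample_years = NULL,
                       mu_per_site_year = 2.11e-9,
                       accessible_length = c(coding = 3.3e7, intronic = 1.8e7,
                                             intergenic = 4.6e7,
                                             transposon = 1.1e7),
                       genealogy = c("star", "coalescent", "forward_wf"),
                       selection_coding = 1,
                       growth_beta = 80,
                       generation_time_years = 1.3,
                       missing_rate_herbarium = 0.05,
                       missing_rate_modern = 0.01,
                       founder_n = 10L,
                       n_causal = 10L,
                       target_h2 = 0.64,
                       n_replicates = 3L,
                       max_mutations = 2e6) {
  genealogy <- match.arg(genealogy)
  if (is.null(sample_years))
    sample_years <- list(
      herbarium = round(seq(1863, 1993, length.out = 27)),
      modern = round(seq(1993, 2006, length.out = 73)))
  stopifnot(mu_per_site_year >= 0, all(accessible_length >= 0),
            selection_coding > 0, selection_coding <= 1,
            generation_time_years > 0,
            missing_rate_herbarium >= 0, missing_rate_herbarium < 1,
            missing_rate_modern >= 0, missing_rate_modern < 1,
            target_h2 >= 0, target_h2 < 1)
  accessible_length <- accessible_length[setdiff(names(accessible_length),
                                                 "total")]
  if (any(!names(accessible_length) %in% ANNOTATION_CLASSES))
    stop("accessible_length classes must be annotation classes")
  yrs <- unlist(sample_years)
  if (founder_year >= min(yrs))
    stop("founder_year must precede all sample years")
  structure(list(seed = as.integer(seed), founder_year = founder_year,
                 sample_years = sample_years,
                 mu_per_site_year = mu_per_site_year,
                 accessible_length = accessible_length,
                 genealogy = genealogy, selection_coding = selection_coding,
                 growth_beta = growth_beta,
                 generation_time_years = generation_time_years,
                 missing_rate_herbarium = missing_rate_herbarium,
                 missing_rate_modern = missing_rate_modern,
                 founder_n = as.integer(founder_n),
                 n_causal = as.integer(n_causal), target_h2 = target_h2,
                 n_replicates = as.integer(n_replicates),
                 max_mutations = max_mutations),
            class = "sim_config")
}

## genome layout: one contiguous block per annotation class laid end to end
## on synthetic chromosomes, so classified positions can be drawn uniformly
## within their class and an annotation_map can be emitted for round trips.
sim_genome_layout <- function(config) {
  L <- config$accessible_length
  L <- L[L > 0]
  start <- cumsum(c(1, utils::head(L, -1)))
  data.frame(class = names(L), chrom = "chr1", start = start,
             end = start + L - 1, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Annotation map matching the simulated genome layout
#' @param config a [sim_config()]
#' @export
sim_annotation_map <- function(config) {
  lay <- sim_genome_layout(config)
  gr <- GenomicRanges::GRanges(lay$chrom,
                               IRanges::IRanges(lay$start, lay$end))
  gr$class <- lay$class
  annotation_map(gr)
}

## draw k distinct positions for mutations, each assigned a class with
## probability proportional to class length (infinite-sites: collisions are
## redrawn, vanishingly rare at genomic L)
sim_draw_positions <- function(k, layout, occupied = integer(0)) {
  if (k == 0)
    return(data.frame(chrom = character(0), pos = integer(0),
                      class = character(0)))
  w <- layout$end - layout$start + 1
  repeat {
    cls_i <- sample.int(nrow(layout), k, replace = TRUE, prob = w)
    pos <- layout$start[cls_i] +
      floor(runif(k) * (layout$end[cls_i] - layout$start[cls_i] + 1))
    if (!anyDuplicated(pos) && !any(pos %in% occupied)) break
  }
  data.frame(chrom = layout$chrom[cls_i], pos = as.integer(pos),
             class = layout$class[cls_i], stringsAsFactors = FALSE)
}

BASES <- c("A", "C", "G", "T")

#' Simulate a dated quasi-clonal lineage
#'
#' Generates a genealogy for the configured samples, drops mutations on
#' branches as a Poisson process with intensity `mu * branch_years * L`,
#' places them uniformly within annotation classes (proportional to class
#' accessible length), thins coding mutations by the retention probability to
#' mimic purifying selection, and applies era-specific missingness.  The
#' founder allele is recorded as truth so orientation estimators can be
#' scored.
#'
#' @param config a [sim_config()]
#' @return list with elements `variants` (a [variant_table()]), `meta`
#'   (a `sample_meta`), and `truth` (true rate, branch years per sample,
#'   per-class pre/post-thinning mutation counts, genealogy mode)
#' @export
simulate_lineage <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  yrs <- c(config$sample_years$herbarium, config$sample_years$modern)
  era <- rep(c("herbarium", "modern"),
             c(length(config$sample_years$herbarium),
               length(config$sample_years$modern)))
  n <- length(yrs)
  ids <- sprintf("%s_%03d", ifelse(era == "herbarium", "H", "M"), seq_len(n))
  meta <- sample_meta(data.frame(
    sample_id = ids, year = yrs,
    latitude = round(runif(n, 38, 46), 4),
    longitude = round(runif(n, -95, -70), 4),
    era = era, stringsAsFactors = FALSE))

  layout <- sim_genome_layout(config)
  L_tot <- sum(config$accessible_length)
  mu <- config$mu_per_site_year

  ## genealogy -> per-branch (years, carrier tip sets)
  branches <- switch(config$genealogy,
    star = {
      by <- yrs - config$founder_year
      list(years = by, carriers = lapply(seq_len(n), identity),
           branch_years_per_sample = by)
    },
    coalescent = sim_coalescent_branches(n, yrs, config$founder_year,
                                         config$growth_beta),
    forward_wf = NULL)

  if (config$genealogy == "forward_wf") {
    out <- sim_forward_wf(config, meta, layout, L_tot)
    calls <- out$calls; sitedf <- out$sites
    truth_counts <- out$truth_counts
    branch_years_per_sample <- out$branch_years
  } else {
    exp_tot <- mu * L_tot * sum(branches$years)
    if (exp_tot > config$max_mutations)
      stop("expected mutation count ", round(exp_tot),
           " exceeds max_mutations cap")
    k_per_branch <- rpois(length(branches$years), mu * L_tot * branches$years)
    k <- sum(k_per_branch)
    sitedf <- sim_draw_positions(k, layout)
    branch_of <- rep(seq_along(k_per_branch), k_per_branch)
    ## purifying selection as thinning of coding mutations
    pre_counts <- table(factor(sitedf$class, levels = layout$class))
    keep <- rep(TRUE, k)
    if (config$selection_coding < 1 && k) {
      is_cod <- sitedf$class == "coding"
      keep[is_cod] <- runif(sum(is_cod)) < config$selection_coding
    }
    sitedf <- sitedf[keep, , drop = FALSE]
    branch_of <- branch_of[keep]
    calls <- matrix(0L, nrow(sitedf), n, dimnames = list(NULL, ids))
    for (i in seq_along(branch_of)) {
      calls[i, branches$carriers[[branch_of[i]]]] <- 1L
    }
    truth_counts <- list(pre_thinning = as.list(pre_counts),
                         post_thinning = as.list(table(
                           factor(sitedf$class, levels = layout$class))))
    branch_years_per_sample <- branches$branch_years_per_sample
  }

  ## alleles: founder (ancestral) base and a distinct derived base
  ns <- nrow(sitedf)
  anc <- sample(BASES, ns, replace = TRUE)
  der <- vapply(anc, function(b) sample(setdiff(BASES, b), 1), character(1))
  sitedf$ancestral <- anc
  sitedf$derived <- unname(der)

  ## era-specific missingness
  if (ns) {
    miss_rate <- ifelse(era == "herbarium", config$missing_rate_herbarium,
                        config$missing_rate_modern)
    miss <- matrix(runif(ns * n) < rep(miss_rate, each = ns), ns, n)
    calls[miss] <- NA_integer_
  }

  acc <- c(config$accessible_length, total = L_tot)
  v <- variant_table(sitedf[, c("chrom", "pos", "ancestral", "derived",
                                "class")],
                     calls, acc)
  truth <- list(mu_per_site_year = mu, genealogy = config$genealogy,
                founder_year = config$founder_year,
                branch_years_per_sample = setNames(branch_years_per_sample,
                                                   ids),
                class_counts = truth_counts,
                selection_coding = config$selection_coding)
  list(variants = v, meta = meta, truth = truth)
}

## Kingman-style random genealogy from ape::rcoal, rescaled so the root sits
## at the founder year, with a power transform on node depths that pushes
## coalescences toward the root (the bottleneck-then-expansion regime:
## star-like trees, singleton excess, strongly negative Tajima's D).
## beta = 1 is the plain constant-size coalescent; larger beta = stronger
## expansion.  Terminal branches are then stretched/shrunk so each tip ends
## at its collection year.
sim_coalescent_branches <- function(n, yrs, founder_year, beta = 80) {
  tr <- ape::rcoal(n)
  depth_node <- ape::node.depth.edgelength(tr)   # distance from root
  depth <- max(depth_node)
  span <- max(yrs) - founder_year
  ## depths relative to the root, compressed rootward by the power transform
  rel <- (depth_node / depth)^beta
  tr$edge.length <- span * (rel[tr$edge[, 2]] - rel[tr$edge[, 1]])
  ## tip heights then equal max(yrs); shorten tip i by (max - yrs[i])
  tip_edge <- match(seq_len(n), tr$edge[, 2])
  adj <- tr$edge.length[tip_edge] - (max(yrs) - yrs)
  if (any(adj < 0)) {
    ## a tip older than its subtending node: clamp (rare for dense designs)
    adj[adj < 0] <- 0.1
  }
  tr$edge.length[tip_edge] <- adj
  desc <- phylo_edge_tips(tr)
  per_sample <- vapply(seq_len(n), function(i)
    sum(tr$edge.length[vapply(desc, function(d) i %in% d, logical(1))]),
    numeric(1))
  list(years = tr$edge.length, carriers = desc,
       branch_years_per_sample = per_sample)
}

## tips descending from each edge of a phylo
phylo_edge_tips <- function(tr) {
  n <- length(tr$tip.label)
  children <- split(seq_len(nrow(tr$edge)), tr$edge[, 1])
  res <- vector("list", nrow(tr$edge))
  rec <- function(edge_idx) {
    node <- tr$edge[edge_idx, 2]
    if (node <= n) res[[edge_idx]] <<- node
    else res[[edge_idx]] <<- unlist(lapply(children[[as.character(node)]],
                                           rec))
    res[[edge_idx]]
  }
  root_edges <- children[[as.character(n + 1L)]]
  for (e in root_edges) rec(e)
  res
}

## Small selfing Wright-Fisher population with synchronous generations whose
## calendar duration is drawn from a shifted geometric (seed-bank delay) with
## mean generation_time_years.  Coding mutations carry a fitness cost
## 1 - selection_coding, lowering their frequencies in addition to thinning.
sim_forward_wf <- function(config, meta, layout, L_tot) {
  N <- config$founder_n
  g <- config$generation_time_years
  p_geom <- 1 / g  # interval = 1 + rgeom(p), mean = 1/p ... shifted: mean g
  t <- config$founder_year
  genomes <- replicate(N, integer(0), simplify = FALSE)
  mut_class <- character(0); mut_pos <- integer(0); mut_chrom <- character(0)
  snapshots <- list()
  want <- split(seq_len(nrow(meta)), meta$year)
  years_sorted <- sort(unique(meta$year))
  mu <- config$mu_per_site_year
  s_cost <- 1 - config$selection_coding
  while (t < max(meta$year)) {
    dt <- 1 + rgeom(1, prob = min(1, p_geom))
    t_next <- t + dt
    ## fitness-weighted selfing reproduction
    w <- vapply(genomes, function(gn)
      (1 - s_cost) ^ sum(mut_class[gn] == "coding"), numeric(1))
    parents <- sample.int(N, N, replace = TRUE, prob = w)
    k <- rpois(N, mu * L_tot * dt)
    new_genomes <- vector("list", N)
    for (i in seq_len(N)) {
      gn <- genomes[[parents[i]]]
      if (k[i] > 0) {
        pts <- sim_draw_positions(k[i], layout, occupied = mut_pos)
        idx <- length(mut_pos) + seq_len(k[i])
        mut_pos <- c(mut_pos, pts$pos)
        mut_chrom <- c(mut_chrom, pts$chrom)
        mut_class <- c(mut_class, pts$class)
        gn <- c(gn, idx)
      }
      new_genomes[[i]] <- gn
    }
    genomes <- new_genomes
    for (y in years_sorted[years_sorted > t & years_sorted <= t_next]) {
      snapshots[[as.character(y)]] <- genomes
    }
    t <- t_next
    if (length(mut_pos) > config$max_mutations)
      stop("mutation count exceeded max_mutations cap")
  }
  n <- nrow(meta)
  sample_genomes <- vector("list", n)
  for (y in names(want)) {
    pool <- snapshots[[y]]
    if (is.null(pool)) pool <- genomes
    for (i in want[[y]]) sample_genomes[[i]] <- pool[[sample.int(N, 1)]]
  }
  seg <- sort(unique(unlist(sample_genomes)))
  calls <- matrix(0L, length(seg), n, dimnames = list(NULL, meta$sample_id))
  for (i in seq_len(n))
    calls[match(sample_genomes[[i]], seg), i] <- 1L
  ## drop monomorphic (fixed in all samples) -- keep segregating only
  poly <- rowSums(calls) < n & rowSums(calls) > 0
  seg <- seg[poly]; calls <- calls[poly, , drop = FALSE]
  sites <- data.frame(chrom = mut_chrom[seg], pos = mut_pos[seg],
                      class = mut_class[seg], stringsAsFactors = FALSE)
  list(calls = calls, sites = sites,
       truth_counts = list(post_thinning = as.list(
         table(factor(sites$class, levels = layout$class)))),
       branch_years = meta$year - config$founder_year)
}

#' Simulate mutation-accumulation line mutation counts
#'
#' Single-seed-descent laboratory lines accumulate mutations with minimal
#' selection; per-line counts are independent Poisson draws with mean
#' `mu_per_site_gen * generations * callable_bp`.
#'
#' @param n_lines number of MA lines
#' @param generations generations of single-seed descent (scalar or per line)
#' @param mu_per_site_gen mutation rate, site^-1 generation^-1
#' @param callable_bp callable genome size per line (scalar or per line)
#' @param seed RNG seed
#' @return data.frame with columns `line`, `generations`, `callable_bp`,
#'   `count`
#' @export
simulate_ma_lines <- function(n_lines, generations, mu_per_site_gen,
                              callable_bp, seed = 1L) {
  stopifnot(n_lines >= 1, all(generations > 0), mu_per_site_gen >= 0,
            all(callable_bp > 0))
  set.seed(seed)
  generations <- rep_len(generations, n_lines)
  callable_bp <- rep_len(callable_bp, n_lines)
  data.frame(line = sprintf("MA_%02d", seq_len(n_lines)),
             generations = generations, callable_bp = callable_bp,
             count = rpois(n_lines,
                           mu_per_site_gen * generations * callable_bp))
}

#' Simulate phenotypes with a target chip heritability
#'
#' Draws `n_causal` causal sites among those with minor allele frequency at
#' least 5%, assigns Gaussian effects, and tunes the environmental variance
#' so the expected fraction of accession-level variance explained by genotype
#' equals `target_h2`.  Replicates add within-line noise.
#'
#' @param v a [variant_table()]
#' @param config a [sim_config()]; uses `n_causal`, `target_h2`,
#'   `n_replicates`, `seed`
#' @param trait trait name for the output table
#' @param maf_min causal sites must exceed this minor allele frequency
#' @return list with `phenotypes` (sample_id, trait, replicate, value) and
#'   `truth` (causal site indices, effects, realized h2)
#' @export
simulate_phenotypes <- function(v, config, trait = "sim_trait",
                                maf_min = 0.05) {
  set.seed(config$seed + 1L)
  f <- site_frequencies(v)
  common <- which(pmin(f, 1 - f) >= maf_min)
  if (length(common) < config$n_causal)
    stop("only ", length(common), " sites with MAF >= ", maf_min,
         " but n_causal = ", config$n_causal,
         "; simulate more samples or lower n_causal")
  causal <- sort(sample(common, config$n_causal))
  X <- t(v$calls[causal, , drop = FALSE])
  X[is.na(X)] <- rep(colMeans(X, na.rm = TRUE),
                     each = nrow(X))[is.na(X)]
  beta <- rnorm(config$n_causal)
  g <- drop(X %*% beta)
  h2 <- config$target_h2
  if (h2 == 0 || var(g) == 0) {
    g <- g * 0
    sd_e <- 1
  } else {
    sd_e <- sqrt(var(g) * (1 - h2) / h2)
  }
  n <- n_samples(v)
  acc_mean <- g + rnorm(n, 0, sd_e)
  reps <- config$n_replicates
  tot_sd <- sd(acc_mean)
  if (!is.finite(tot_sd) || tot_sd == 0) tot_sd <- 1
  ph <- data.frame(
    sample_id = rep(colnames(v$calls), each = reps),
    trait = trait,
    replicate = rep(seq_len(reps), times = n),
    value = rep(acc_mean, each = reps) +
      rnorm(n * reps, 0, 0.25 * tot_sd),
    stringsAsFactors = FALSE)
  realized <- if (var(acc_mean) > 0) var(g) / var(acc_mean) else 0
  list(phenotypes = ph,
       truth = list(causal_sites = causal, beta = beta,
                    realized_h2 = realized, target_h2 = h2))
}

#' Simulate a climate covariate coupled to genotype and geography
#'
#' The covariate is a mixture of an allele signal at one common driver SNP
#' and a smooth latitude/longitude gradient, plus noise; latitude and
#' longitude are retained as confounders so spatial correction can be
#' exercised.
#'
#' @param meta `sample_meta`
#' @param v [variant_table()]
#' @param coupling in `[0,1]`: 0 = purely spatial, 1 = purely genetic
#' @param seed RNG seed
#' @param noise_sd standard deviation of the residual noise
#' @return list with `covariates` (sample_id, climate, latitude, longitude)
#'   and `driver_site` (index of the driving SNP, NA if coupling = 0)
#' @export
simulate_climate <- function(meta, v, coupling = 0.5, seed = 1L,
                             noise_sd = 0.1) {
  stopifnot(coupling >= 0, coupling <= 1)
  set.seed(seed)
  n <- nrow(meta)
  grad <- scale(meta$latitude + meta$longitude)[, 1]
  f <- site_frequencies(v)
  common <- which(pmin(f, 1 - f) >= 0.05)
  driver <- NA_integer_
  sig <- numeric(n)
  if (coupling > 0 && length(common)) {
    driver <- common[sample.int(length(common), 1)]
    x <- v$calls[driver, ]
    x[is.na(x)] <- mean(x, na.rm = TRUE)
    sig <- scale(x)[, 1]
  }
  clim <- coupling * sig + (1 - coupling) * grad + rnorm(n, 0, noise_sd)
  list(covariates = data.frame(sample_id = meta$sample_id, climate = clim,
                               latitude = meta$latitude,
                               longitude = meta$longitude,
                               stringsAsFactors = FALSE),
       driver_site = driver)
}
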