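#' Run the full lineage analysis end to end
#'
#' Orchestrates simulate (or load) -> QC -> rates -> diversity -> selection
#' -> association from a single configuration, writing TSV tables plus a
#' versioned JSON report to the output directory.  The run is bit-for-bit
#' reproducible for a fixed seed.
#'
#' @param config list with components:
#'   * `sim`: a [sim_config()] (simulate inputs), or `vcf`/`meta` paths plus
#'     `accessible_length` to load real data;
#'   * `stages`: character subset of `c("qc","rates","diversity",
#'     "selection","association")` (default all);
#'   * `n_boot`, `n_perm`, `maf_min`, `freq_cutoff`, `generation_time`:
#'     thresholds with the package defaults;
#'   * `seed`: global seed (overrides `sim$seed`).
#' @param outdir output directory (created); `NULL` for no files
#' @return the report list, invisibly written as `report.json`
#' @export
run_full_analysis <- function(config, outdir = NULL) {
  stages <- config$stages %||% c("qc", "rates", "diversity", "selection",
                                 "association")
  n_boot <- config$n_boot %||% 1000L
  n_perm <- config$n_perm %||% 1000L
  maf_min <- config$maf_min %||% 0.05
  cutoff <- config$freq_cutoff %||% 0.05
  gtime <- config$generation_time %||% 1.3
  seed <- config$seed %||% 1L

  report <- list(schema = "clonalclock-report/1",
                 parameters = list(seed = seed, n_boot = n_boot,
                                   n_perm = n_perm, maf_min = maf_min,
                                   freq_cutoff = cutoff,
                                   generation_time_years = gtime))

  if (!is.null(config$sim)) {
    sim <- config$sim
    sim$seed <- as.integer(seed)
    message("stage simulate: genealogy=", sim$genealogy)
    ds <- simulate_lineage(sim)
    v <- ds$variants; meta <- ds$meta
    report$simulate <- list(n_sites = n_sites(v), n_samples = n_samples(v),
                            true_rate = ds$truth$mu_per_site_year)
  } else {
    if (is.null(config$vcf) || is.null(config$meta))
      stop("config needs either a 'sim' block or 'vcf' + 'meta' paths")
    meta <- read_sample_meta(config$meta)
    v <- read_vcf(config$vcf, meta, config$accessible_length)
    if (!is.null(config$annotations))
      v <- classify_sites(v, read_annotations(config$annotations,
                                              config$dialect %||% "gff3"))
  }
  if (n_samples(v) == 0 || nrow(meta) == 0) stop("empty sample set")
  acc_total <- v$accessible_length[["total"]]

  pd <- NULL
  if ("qc" %in% stages) {
    message("stage qc")
    pd <- pairwise_distance_matrix(v, meta)
    fg <- four_gamete_screen(v)
    report$qc <- list(
      min_identity_pct = identity_summary(pd, acc_total),
      max_pairwise_snps = suppressWarnings(max(pd$d, na.rm = TRUE)),
      incompatible_pairs = fg$incompatible_pairs,
      flagged_recombinants = fg$flagged)
  }

  if ("rates" %in% stages) {
    message("stage rates")
    pairs <- net_distance_pairs(v, meta)
    est <- fit_rate(pairs, acc_total, n_boot = n_boot, seed = seed)
    gen <- per_generation_rate(est, gtime)
    if (is.null(pd)) pd <- pairwise_distance_matrix(v, meta)
    d_site <- mean_pairwise_distance(pd, acc_total)
    tm <- if (est$rate > 0)
      estimate_tmrca(d_site, est$rate, mean(meta$year))
    else list(L_years = NA, root_year = NA,
              note = "rate estimate not positive; TMRCA undefined")
    report$rates <- list(
      per_year = unclass(est), per_generation = unclass(gen),
      per_class = lapply(stratify_rates(v, meta, n_boot = n_boot,
                                        seed = seed), unclass),
      tmrca = tm)
  }

  sfs <- NULL
  if ("diversity" %in% stages) {
    message("stage diversity")
    S <- n_sites(v); n <- n_samples(v)
    sfs <- unfolded_sfs(v, meta)
    report$diversity <- list(
      segregating_sites = S,
      theta_w_per_site = watterson_theta(S, n, acc_total),
      pi_per_site = nucleotide_diversity(v, acc_total),
      tajimas_d = tajimas_d(v),
      sfs_reference_fallbacks = sum(sfs$sites$orientation ==
                                      "reference_fallback"))
  }

  if ("selection" %in% stages) {
    message("stage selection")
    if (is.null(sfs)) sfs <- unfolded_sfs(v, meta)
    non_coding <- c("intergenic", "intronic", "utr5", "utr3", "transposon",
                    "pseudogene")
    dep <- annotation_depletion_test(v, "coding", intersect(
      non_coding, names(v$accessible_length)[v$accessible_length > 0]))
    frq <- tryCatch(
      frequency_class_test(sfs, "coding", "intergenic", cutoff = cutoff),
      error = function(e) NULL)
    ks <- sfs_ks_test(sfs$sites$frequency[sfs$sites$class == "coding"],
                      sfs$sites$frequency[sfs$sites$class != "coding"],
                      n_boot = min(n_boot * 10L, 10000L), seed = seed)
    report$selection <- list(
      depletion_coding_vs_noncoding = unclass(dep)[c("odds_ratio",
                                                     "p_value")],
      frequency_coding_vs_intergenic = if (!is.null(frq))
        unclass(frq)[c("odds_ratio", "p_value")],
      ks_coding_vs_noncoding = ks)
  }

  if ("association" %in% stages) {
    message("stage association")
    if (!is.null(config$sim)) {
      ph <- simulate_phenotypes(v, sim)
      pheno <- ph$phenotypes
    } else if (!is.null(config$phenotypes)) {
      pheno <- read_phenotypes(config$phenotypes, meta)
    } else pheno <- NULL
    if (!is.null(pheno)) {
      acc_means <- tapply(pheno$value, pheno$sample_id, mean)
      y <- as.numeric(acc_means[colnames(v$calls)])
      names(y) <- colnames(v$calls)
      K <- kinship_matrix(v, maf_min)
      h2 <- chip_heritability(y, K)
      scan <- gwa_scan(y, v, maf_min = maf_min)
      thr <- permutation_threshold(y, v, n_perm = n_perm, seed = seed,
                                   maf_min = maf_min)
      db <- double_bonferroni(0.05, nrow(scan),
                              length(unique(pheno$trait)))
      hits <- scan[scan$p < thr$threshold, , drop = FALSE]
      ld_part <- rep(0L, nrow(hits))
      if (nrow(hits) > 1) {
        ld <- ld_statistics(v, hits$site)
        ld_part <- ld$partners_high_ld
      }
      report$association <- list(
        h2 = unclass(h2), kinship_sites = attr(K, "n_sites"),
        permutation_threshold = thr$threshold,
        double_bonferroni = db,
        hits = cbind(hits,
                     empirical_significant = TRUE,
                     double_bonferroni_significant = hits$p < db,
                     ld_partners = ld_part))
    }
  }

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_dataset(v, meta, outdir)
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE)
  }
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
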