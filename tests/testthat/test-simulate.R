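## one herbarium + one modern sample, no missingness: minimal valid design
tiny_cfg <- function(seed, mu = 1e-8, L = 1e7, acc = NULL, ...) {
  if (is.null(acc)) acc <- c(intergenic = L)
  sim_config(seed = seed, founder_year = 1900,
             sample_years = list(herbarium = 1950, modern = 2000),
             mu_per_site_year = mu,
             accessible_length = acc,
             missing_rate_herbarium = 0, missing_rate_modern = 0, ...)
}

test_that("mu = 0 gives zero segregating sites", {
  ds <- simulate_lineage(tiny_cfg(1, mu = 0))
  expect_equal(n_sites(ds$variants), 0)
})

test_that("star-branch mutation counts are Poisson(mu * years * L)", {
  ## herbarium tip 50y from founder, modern 100y: lambda = 5 and 10
  counts <- vapply(1:1000, function(s) {
    ds <- simulate_lineage(tiny_cfg(s))
    unname(colSums(ds$variants$calls == 1L, na.rm = TRUE)[2])
  }, numeric(1))
  ## modern branch: lambda = 1e-8 * 100 * 1e7 = 10
  expect_gt(mean(counts), 10 - 3 * sqrt(10 / 1000))
  expect_lt(mean(counts), 10 + 3 * sqrt(10 / 1000))
  qs <- qpois(c(0.005, 0.995), 10)
  expect_gt(mean(counts >= qs[1] & counts <= qs[2]), 0.97)
  expect_gt(var(counts) / mean(counts), 0.8)  # Poisson dispersion
  expect_lt(var(counts) / mean(counts), 1.2)
})

test_that("same seed is bit-identical, different seeds differ", {
  a <- simulate_lineage(sim_config(seed = 7))
  b <- simulate_lineage(sim_config(seed = 7))
  c <- simulate_lineage(sim_config(seed = 8))
  expect_identical(a$variants, b$variants)
  expect_identical(a$meta, b$meta)
  expect_false(identical(a$variants$sites$pos, c$variants$sites$pos))
})

test_that("per-class mutation counts track class lengths when neutral", {
  acc <- c(coding = 4e6, intronic = 2e6, intergenic = 3e6, transposon = 1e6)
  pv <- vapply(1:20, function(s) {
    ds <- simulate_lineage(tiny_cfg(s, mu = 2e-7, acc = acc))
    tab <- table(factor(ds$variants$sites$class, levels = names(acc)))
    suppressWarnings(chisq.test(tab, p = acc / sum(acc))$p.value)
  }, numeric(1))
  expect_gt(min(pv), 0.001)
})

test_that("coding thinning depletes coding SNPs below bp expectation", {
  cfg <- sim_config(seed = 11, selection_coding = 0.5)
  ds <- simulate_lineage(cfg)
  r <- annotation_depletion_test(ds$variants, "coding", "intergenic")
  expect_lt(r$odds_ratio, 1)
  expect_lt(r$p_value, 0.05)
})

test_that("simulate_ma_lines draws independent Poisson counts", {
  z <- simulate_ma_lines(5, 30, 0, 1e8, seed = 1)
  expect_true(all(z$count == 0))
  z1 <- simulate_ma_lines(1, 1, 0.4, 1, seed = 2)
  expect_true(z1$count %in% 0:3)
  m <- replicate(200, mean(simulate_ma_lines(
    12, 30, 7.1e-9, 1e8, seed = sample.int(1e6, 1))$count))
  lam <- 7.1e-9 * 30 * 1e8           # 21.3 per line
  expect_lt(abs(mean(m) - lam), 4 * sqrt(lam / (12 * 200)))
})

test_that("phenotypes: h2 = 0 is genotype-independent; causal site is hot", {
  cfg <- sim_config(seed = 5, genealogy = "coalescent", target_h2 = 0,
                    n_causal = 2)
  ds <- simulate_lineage(cfg)
  ph <- simulate_phenotypes(ds$variants, cfg)
  expect_equal(ph$truth$realized_h2, 0)

  cfg2 <- sim_config(seed = 5, genealogy = "coalescent", target_h2 = 0.95,
                     n_causal = 1)
  ph2 <- simulate_phenotypes(ds$variants, cfg2)
  acc <- tapply(ph2$phenotypes$value, ph2$phenotypes$sample_id, mean)
  y <- as.numeric(acc[colnames(ds$variants$calls)])
  scan <- gwa_scan(y, ds$variants)
  best <- scan$site[which.min(scan$p)]
  ## top hit is the causal site or a perfect LD partner of it
  ld <- ld_statistics(ds$variants, unique(c(best, ph2$truth$causal_sites)))
  i <- match(best, ld$sites); j <- match(ph2$truth$causal_sites[1], ld$sites)
  expect_true(best == ph2$truth$causal_sites[1] || ld$r2[i, j] > 0.8)
})

test_that("too few common sites for the requested causal count is fatal", {
  cfg <- tiny_cfg(3, mu = 1e-8)   # star, n = 2: no common polymorphism
  ds <- simulate_lineage(cfg)
  cfg$n_causal <- 50L
  expect_error(simulate_phenotypes(ds$variants, cfg), "n_causal")
})

test_that("climate covariate decouples from genotype at coupling 0", {
  cfg <- sim_config(seed = 9, genealogy = "coalescent")
  ds <- simulate_lineage(cfg)
  cl <- simulate_climate(ds$meta, ds$variants, coupling = 0, seed = 9)
  expect_true(is.na(cl$driver_site))
  ## at coupling 1 and low noise the driver SNP is recoverable
  cl2 <- simulate_climate(ds$meta, ds$variants, coupling = 1, seed = 9,
                          noise_sd = 0.01)
  scan <- gwa_scan(cl2$covariates$climate, ds$variants)
  best <- scan$site[which.min(scan$p)]
  ld <- ld_statistics(ds$variants, unique(c(best, cl2$driver_site)))
  expect_true(best == cl2$driver_site ||
                ld$r2[match(best, ld$sites),
                      match(cl2$driver_site, ld$sites)] > 0.8)
})

test_that("runaway-memory guard trips", {
  expect_error(simulate_lineage(tiny_cfg(1, mu = 1)), "max_mutations")
})

test_that("forward-WF mode produces a selfing population with variation", {
  cfg <- sim_config(seed = 2, genealogy = "forward_wf", founder_n = 8,
                    mu_per_site_year = 2e-8,
                    accessible_length = c(coding = 5e6, intergenic = 5e6),
                    sample_years = list(
                      herbarium = round(seq(1863, 1993, length.out = 8)),
                      modern = round(seq(1994, 2006, length.out = 12))),
                    missing_rate_herbarium = 0, missing_rate_modern = 0)
  ds <- simulate_lineage(cfg)
  expect_gt(n_sites(ds$variants), 0)
  f <- rowMeans(ds$variants$calls == 1L)
  expect_true(all(f > 0 & f < 1))    # segregating only
})
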