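## small coalescent-world dataset reused across association tests
assoc_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 41, genealogy = "coalescent")
      cache <<- list(cfg = cfg, ds = simulate_lineage(cfg))
    }
    cache
  }
})

test_that("kinship: identical genotypes and orthogonal blocks", {
  calls <- matrix(rep(c(1L, 0L, 1L, 0L, 1L, 1L), 4), 6, 4,
                  dimnames = list(NULL, letters[1:4]))
  K <- kinship_matrix(toy_variants(calls), maf_min = 0)
  expect_true(all(abs(K - K[1, 1]) < 1e-12))

  ## two clean genotype groups: within-block kinship high, between low
  blk <- cbind(g1 = c(1L, 1L, 1L, 0L, 0L, 0L), g2 = c(1L, 1L, 1L, 0L, 0L, 0L),
               g3 = c(0L, 0L, 0L, 1L, 1L, 1L), g4 = c(0L, 0L, 0L, 1L, 1L, 1L))
  K2 <- kinship_matrix(toy_variants(blk), maf_min = 0.05)
  expect_gt(K2["g1", "g2"], 0.9)
  expect_lt(K2["g1", "g3"], -0.9)
  expect_error(kinship_matrix(toy_variants(blk), maf_min = 0.6), "MAF")
})

test_that("chip heritability: null trait gives small h2, non-sig LRT", {
  w <- assoc_world()
  K <- kinship_matrix(w$ds$variants)
  set.seed(1)
  hs <- replicate(10, {
    y <- rnorm(nrow(K))
    names(y) <- rownames(K)
    h <- chip_heritability(y, K)
    c(h$h2, h$p_value)
  })
  expect_lt(median(hs[1, ]), 0.25)
  expect_gt(mean(hs[2, ] > 0.05), 0.5)
})

test_that("chip heritability recovers a strong simulated signal", {
  w <- assoc_world()
  ph <- simulate_phenotypes(w$ds$variants, w$cfg)   # target 0.64
  acc <- tapply(ph$phenotypes$value, ph$phenotypes$sample_id, mean)
  y <- as.numeric(acc[colnames(w$ds$variants$calls)])
  names(y) <- colnames(w$ds$variants$calls)
  K <- kinship_matrix(w$ds$variants)
  h <- chip_heritability(y, K)
  expect_gt(h$h2, 0.3)
  expect_lt(h$p_value, 0.05)
})

test_that("gwa_scan: null p uniform, planted effect found", {
  w <- assoc_world()
  v <- w$ds$variants
  ## sites are heavily tied/correlated within one genealogy, so check
  ## marginal uniformity of p averaged over several null traits
  set.seed(2)
  fr <- replicate(8, {
    y <- rnorm(n_samples(v))
    p <- gwa_scan(y, v)$p
    c(mean(p < 0.1), mean(p < 0.5))
  })
  expect_lt(abs(mean(fr[1, ]) - 0.1), 0.08)
  expect_lt(abs(mean(fr[2, ]) - 0.5), 0.15)

  cfg2 <- w$cfg; cfg2$n_causal <- 1L; cfg2$target_h2 <- 0.9
  ph <- simulate_phenotypes(v, cfg2)
  acc <- tapply(ph$phenotypes$value, ph$phenotypes$sample_id, mean)
  y2 <- as.numeric(acc[colnames(v$calls)])
  scan2 <- gwa_scan(y2, v)
  best <- scan2$site[which.min(scan2$p)]
  causal <- ph$truth$causal_sites[1]
  ld <- ld_statistics(v, unique(c(best, causal)))
  expect_true(best == causal ||
                ld$r2[match(best, ld$sites), match(causal, ld$sites)] > 0.8)
})

test_that("covariate correction removes a spatial gradient signal", {
  w <- assoc_world()
  v <- w$ds$variants; meta <- w$ds$meta
  cl <- simulate_climate(meta, v, coupling = 0, seed = 3, noise_sd = 0.05)
  y <- cl$covariates$climate
  cov <- as.matrix(cl$covariates[, c("latitude", "longitude")])
  scan_cor <- gwa_scan(y, v, covariates = cov)
  ## negative control: a purely spatial trait yields no strong hit once
  ## latitude/longitude are projected out
  expect_gt(min(scan_cor$p), 1e-5)
  expect_equal(nrow(scan_cor), nrow(gwa_scan(y, v)))
})

test_that("permutation threshold: validation and pooled calibration", {
  w <- assoc_world()
  v <- w$ds$variants
  set.seed(4)
  y <- rnorm(n_samples(v))
  expect_error(permutation_threshold(y, v, n_perm = 10), "at least 100")
  ## pooled null: ~alpha of null-site p fall under the threshold, averaged
  ## over traits (a single trait is noisy because sites are correlated)
  hit <- vapply(1:8, function(s) {
    set.seed(s + 50)
    yy <- rnorm(n_samples(v))
    thr <- permutation_threshold(yy, v, n_perm = 150, seed = s,
                                 mode = "pooled")
    mean(gwa_scan(yy, v)$p < thr$threshold)
  }, numeric(1))
  expect_lt(abs(mean(hit) - 0.05), 0.04)
  thr <- permutation_threshold(y, v, n_perm = 150, seed = 1, mode = "pooled")
  thr2 <- permutation_threshold(y, v, n_perm = 150, seed = 1, mode = "minp")
  expect_lt(thr2$threshold, thr$threshold)
})

test_that("double Bonferroni arithmetic", {
  expect_equal(double_bonferroni(0.05, 391, 109), 1e-4)
  expect_equal(double_bonferroni(0.05, 100, 0), 5e-4)
  expect_equal(double_bonferroni(0.05, 1, 0), 0.05)
})

test_that("LD statistics match brute-force haplotype counting", {
  ## worked 8-haplotype fixture over two sites
  h <- rbind(s1 = c(1L, 1L, 1L, 0L, 0L, 0L, 1L, 0L),
             s2 = c(1L, 1L, 0L, 0L, 0L, 1L, 1L, 0L))
  v <- toy_variants(h)
  ld <- ld_statistics(v)
  pA <- mean(h[1, ]); pB <- mean(h[2, ])
  pAB <- mean(h[1, ] == 1 & h[2, ] == 1)
  D <- pAB - pA * pB
  expect_equal(ld$D[1, 2], D, tolerance = 1e-12)
  expect_equal(ld$r2[1, 2], D^2 / (pA * (1 - pA) * pB * (1 - pB)),
               tolerance = 1e-12)
  Dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB) else
    min(pA * pB, (1 - pA) * (1 - pB))
  expect_equal(ld$Dprime[1, 2], D / Dmax, tolerance = 1e-12)

  ## perfectly co-inherited pair
  cc <- rbind(a = c(1L, 1L, 0L, 0L), b = c(1L, 1L, 0L, 0L))
  ld2 <- ld_statistics(toy_variants(cc))
  expect_equal(ld2$r2[1, 2], 1)
  expect_equal(ld2$Dprime[1, 2], 1)
  expect_equal(unname(ld2$partners_high_ld), c(1, 1))

  ## monomorphic site flagged undefined
  mm <- rbind(a = c(1L, 1L, 1L, 1L), b = c(1L, 0L, 1L, 0L))
  ld3 <- ld_statistics(toy_variants(mm))
  expect_false(ld3$defined[1, 2])
  expect_true(is.na(ld3$r2[1, 2]))
})

test_that("LD invariants: bounds, and r2 = Dprime^2 at p = 0.5", {
  set.seed(6)
  X <- matrix(rbinom(5 * 60, 1, 0.5), 5, 60)
  X <- X[apply(X, 1, function(z) var(z) > 0), , drop = FALSE]
  colnames(X) <- sprintf("s%d", seq_len(ncol(X)))
  ld <- ld_statistics(toy_variants(X))
  ut <- upper.tri(ld$r2)
  ok <- ld$defined[ut] & !is.na(ld$r2[ut])
  expect_true(all(ld$r2[ut][ok] >= -1e-12 & ld$r2[ut][ok] <= 1 + 1e-12))
  expect_true(all(abs(ld$Dprime[ut][ok]) <= 1 + 1e-12))
  ## exact-0.5 frequency pair
  p5 <- rbind(a = c(1L, 1L, 0L, 0L, 1L, 0L), b = c(1L, 0L, 1L, 0L, 1L, 0L))
  ld5 <- ld_statistics(toy_variants(p5))
  expect_equal(ld5$r2[1, 2], ld5$Dprime[1, 2]^2, tolerance = 1e-12)
})

test_that("hit overlap enrichment", {
  r <- hit_overlap_enrichment(1:10, 1:10, 100)
  expect_gt(r$odds_ratio, 50)
  expect_lt(r$p_value, 1e-6)
  ## independent random sets: overlap near chance, not significant
  set.seed(8)
  r2 <- hit_overlap_enrichment(sample(300, 50), sample(300, 50), 300)
  expect_gt(r2$p_value, 0.05)
  expect_error(hit_overlap_enrichment(1, 2, 0), "universe")
})
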