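test_that("net-distance pairs match hand counts", {
  ## modern 'm' carries 10 derived alleles, herbarium 'h' carries 4
  calls <- cbind(m = c(rep(1L, 10), rep(0L, 2)),
                 h = c(rep(1L, 4), rep(0L, 8)))
  v <- toy_variants(calls)
  meta <- toy_meta(c("m", "h"), c(2000, 1900), c("modern", "herbarium"))
  pr <- net_distance_pairs(v, meta)
  expect_equal(nrow(pr), 1)
  expect_equal(pr$Dprime, 6)
  expect_equal(pr$Tprime, 100)
  expect_equal(pr$D_ic, 10)
  expect_equal(pr$D_jc, 4)

  ## identical genotypes give zero net distance
  calls2 <- cbind(m = c(1L, 0L, 1L), h = c(1L, 0L, 1L))
  pr2 <- net_distance_pairs(toy_variants(calls2),
                            toy_meta(c("m", "h"), c(2000, 1900),
                                     c("modern", "herbarium")))
  expect_equal(pr2$Dprime, 0)
})

test_that("fit_rate reproduces exact OLS and degenerate cases", {
  pr <- data.frame(modern = "m", herbarium = c("h1", "h2", "h3"),
                   D_ic = 0, D_jc = 0,
                   Dprime = c(100, 200, 300), Tprime = c(50, 100, 150),
                   callable_i = 1, callable_j = 1)
  est <- fit_rate(pr, 1e6, n_boot = 200, seed = 1)
  expect_equal(est$slope, 2)
  expect_equal(est$intercept, 0)
  expect_equal(est$rate, 2e-6)

  pr0 <- transform(pr, Dprime = 0)
  est0 <- fit_rate(pr0, 1e6, n_boot = 200, seed = 1)
  expect_equal(est0$rate, 0)
  expect_equal(c(est0$ci_low, est0$ci_high), c(0, 0))

  prT <- transform(pr, Tprime = 100)
  expect_error(fit_rate(prT, 1e6), "variance in time")
  expect_error(net_distance_pairs(
    toy_variants(cbind(a = 1L, b = 0L)),
    toy_meta(c("a", "b"), c(2000, 2001), c("modern", "modern"))),
    "herbarium")
})

test_that("rate is scale-equivariant in accessible length", {
  pr <- data.frame(Dprime = c(10, 30, 50), Tprime = c(10, 30, 50),
                   modern = "m", herbarium = c("h1", "h2", "h3"))
  e1 <- fit_rate(pr, 1e6, n_boot = 100, seed = 3)
  e2 <- fit_rate(pr, 2e6, n_boot = 100, seed = 3)
  expect_equal(e2$rate, e1$rate / 2)
  expect_equal(e2$ci_low, e1$ci_low / 2)
})

test_that("per-generation rescaling is linear and matches the arithmetic", {
  r <- clonalclock:::rate_estimate(rate = 2.11e-9,
                                   ci = c(1.88e-9, 2.33e-9),
                                   method = "net_distance",
                                   unit = "site^-1 year^-1")
  g <- per_generation_rate(r, 1.3)
  expect_equal(signif(g$rate, 2), 2.7e-9)
  expect_equal(signif(g$ci_low, 2), 2.4e-9)
  expect_equal(signif(g$ci_high, 2), 3.0e-9)
  expect_identical(per_generation_rate(r, 1)$rate, r$rate)
  ## composition: rescaling by g1*g2 equals two-step rescaling
  expect_equal(per_generation_rate(r, 6)$rate,
               per_generation_rate(per_generation_rate(r, 2), 3)$rate)
})

test_that("TMRCA solves d = 2 L mu", {
  z <- estimate_tmrca(1.53186e-6, 2.11e-9, 1978)
  expect_equal(z$L_years, 363, tolerance = 1e-3)
  expect_equal(z$root_year, 1615, tolerance = 1e-3)
  expect_equal(estimate_tmrca(0, 1e-9, 1990)$root_year, 1990)
  expect_error(estimate_tmrca(1e-6, 0, 1990), "positive")
})

test_that("MA-line estimator: arithmetic, zero and single-line cases", {
  e <- ma_mutation_rate(c(10, 14), 30, 1e8, n_boot = 200, seed = 1)
  expect_equal(e$rate, 24 / 6e9)
  e0 <- ma_mutation_rate(c(0, 0, 0), 10, 1e7, n_boot = 100, seed = 1)
  expect_equal(e0$rate, 0)
  e1 <- ma_mutation_rate(20, 30, 1e8, seed = 1)
  expect_true(e1$ci_low < e1$rate && e1$rate < e1$ci_high)
  expect_equal(e1$n_boot, 0L)
})

test_that("stratified rates scale with per-class thinning", {
  ## wide herbarium series keeps per-class slopes precise enough to compare
  cfg <- sim_config(seed = 21, genealogy = "star", selection_coding = 0.5,
                    sample_years = list(
                      herbarium = round(seq(1700, 1990, length.out = 40)),
                      modern = round(seq(2000, 2006, length.out = 10))),
                    missing_rate_herbarium = 0, missing_rate_modern = 0)
  ds <- simulate_lineage(cfg)
  strat <- stratify_rates(ds$variants, ds$meta, n_boot = 100, seed = 1)
  expect_named(strat, names(cfg$accessible_length), ignore.order = TRUE)
  ## coding retention 0.5 halves the coding rate relative to intergenic
  expect_equal(strat$coding$rate / strat$intergenic$rate, 0.5,
               tolerance = 0.25)
  ## zero-SNP class yields rate 0
  vv <- ds$variants
  keep <- vv$sites$class != "transposon"
  vv$sites <- vv$sites[keep, , drop = FALSE]
  vv$calls <- vv$calls[keep, , drop = FALSE]
  s2 <- stratify_rates(vv, ds$meta, classes = "transposon",
                       n_boot = 100, seed = 1)
  expect_equal(s2$transposon$rate, 0)
})

test_that("net-distance estimator is unbiased (informative design)", {
  ## wide, dense herbarium series so each replicate is precise; 40 seeds
  cfg <- function(s) sim_config(
    seed = s, founder_year = 1600,
    sample_years = list(herbarium = round(seq(1700, 1990, length.out = 40)),
                        modern = round(seq(2000, 2006, length.out = 10))),
    missing_rate_herbarium = 0, missing_rate_modern = 0)
  ests <- vapply(1:40, function(s) {
    ds <- simulate_lineage(cfg(s))
    pr <- net_distance_pairs(ds$variants, ds$meta)
    fit_rate(pr, 1.08e8, n_boot = 100, seed = s)$rate
  }, numeric(1))
  expect_lt(abs(mean(ests) / 2.11e-9 - 1), 0.03)
})
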