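# clonalclock

Substitution rates, founding dates and selection inference for **dated
samples of a quasi-clonal selfing lineage** — the situation that arises when
a plant colonizes a new range from one (or very few) founders and is then
re-sampled over a century and a half, partly from herbarium specimens,
partly from living populations.

In such a lineage there is effectively no observable recombination, every
segregating variant is a *de novo* mutation that arose after the founding,
and the known collection year of each specimen turns the sample set into a
natural mutation-accumulation experiment. `clonalclock` implements the
analysis chain for exactly this setting:

* **Tip-dated substitution rate** by net-distance regression.  For a modern
  sample *i* and a herbarium sample *j*, both called against the lineage
  pseudo-reference *c*,

  `D'_ij = D_ic − D_jc`,  `T'_ij = year_i − year_j`,

  and the OLS fit `D' = a + b·T'` gives the genome-wide substitution rate
  `μ = b / L` (L = accessible genome length), with bootstrap confidence
  intervals (pair-level or sample-level resampling).
* **Founding date (TMRCA)** from `d = 2·L·μ` where *d* is the mean pairwise
  per-site distance, subtracted from the mean collection year.
* **Generation-time rescaling** (`×1.3 yr/generation` by default — seed
  banks delay the effective generation even in an annual plant) and a
  **mutation-accumulation-line estimator** (`Σcounts / Σ(generations × bp)`,
  line-level bootstrap-t CI) for lab-rate comparisons.
* **Diversity and the unfolded SFS**: Watterson's θ, π, Tajima's D, and a
  site frequency spectrum oriented by *order of appearance*: the ancestral
  allele at each site is the one carried by the earliest-dated herbarium
  sample with a non-missing call.
* **Purifying-selection tests**: one-tailed Fisher contingency tests of
  SNPs-vs-accessible-bp between annotation classes, frequency-class tests at
  the 5% cutoff, and a pooled-bootstrap two-sample Kolmogorov–Smirnov test.
* **Mutation-driven association**: frequency-standardized kinship from
  common (MAF > 5%) SNPs, chip heritability `h² = σ²_g/(σ²_g+σ²_e)` by
  1-D REML (`y = Zu + ε`), per-SNP GWA (`y = Xb + ε`) with a
  1,000-permutation empirical null, double-Bonferroni threshold
  `α/(n_SNPs + n_phenotypes)`, LD statistics (r², D, D′), and the embedded
  Grantham (1974) amino-acid distance matrix for scoring nonsynonymous
  hits.
* **QC for clonality**: pairwise SNP distances, NJ tree, percent identity,
  and a four-gamete screen that flags recombinant genomes.
* **A lineage simulator** (`simulate_lineage()` + phenotype/climate
  generators) producing dated genotype datasets with the statistical
  structure above — star, growth-transformed coalescent, or forward
  Wright–Fisher genealogies — so every estimator can be validated against
  known truth without any external data.

## Worked example

```r
library(clonalclock)

## a dated lineage: 27 herbarium samples 1863-1993, 73 modern 1993-2006,
## founded ~1600, mu = 2.11e-9 /site/year over a 108 Mb accessible genome
cfg <- sim_config(seed = 42, genealogy = "star")
ds  <- simulate_lineage(cfg)
ds$variants
#> variant_table: 8607 sites x 100 samples
#> accessible length (total): 1.08e+08 bp
#> sites per class: coding=2625, intronic=1427, transposon=870, intergenic=3685

pairs <- net_distance_pairs(ds$variants, ds$meta)
est <- fit_rate(pairs, ds$variants$accessible_length[["total"]],
                n_boot = 1000, seed = 42, boot_unit = "sample")
est
#> net_distance rate: 2.46e-09 site^-1 year^-1 (95% CI 1.75e-09-3.15e-09, 1000 bootstraps)
per_generation_rate(est, 1.3)
#> net_distance rate: 3.2e-09 site^-1 generation^-1 (95% CI 2.27e-09-4.1e-09, 1000 bootstraps)

pd <- pairwise_distance_matrix(ds$variants, ds$meta)
identity_summary(pd, 1.08e8)   # 99.99980 -- quasi-identical genomes
tajimas_d(ds$variants)         # -3.06    -- bottleneck + expansion
tm <- estimate_tmrca(mean_pairwise_distance(pd, 1.08e8),
                     est$rate, mean(ds$meta$year))
tm$root_year                   # 1659, true founder year 1600
```

The point estimate (2.46e-9 against a true 2.11e-9) and the recovered root
year (1659 vs 1600) illustrate the honest precision of a dated-tip clock at
this scale: the estimator is unbiased, but a single century-deep lineage
carries ~20% counting noise in the slope (see the methods vignette).

Purifying selection shows up as a *count* deficit of coding SNPs per
accessible bp; frequency shifts additionally require selection acting after
the mutations arose (forward-WF mode):

```r
cfg2 <- sim_config(seed = 7, genealogy = "coalescent", selection_coding = 0.5)
ds2 <- simulate_lineage(cfg2)
annotation_depletion_test(ds2$variants, "coding", "intergenic")
#> Fisher exact (coding vs intergenic, tail=less): OR = 0.522, p = 2.14e-63
grantham_score("C", "W")       # 215 -- the most radical substitution
```

## Command line

`inst/cli/clonalclock.R` exposes `simulate | qc | rate | diversity |
selection | gwas | all` subcommands over a JSON config, with a global
`--seed`; `all` writes a versioned JSON report plus the dataset as
VCF + TSV.
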