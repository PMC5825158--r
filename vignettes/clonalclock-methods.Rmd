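---
title: "Dating and selection inference in a quasi-clonal lineage: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{clonalclock methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The setting and its assumptions

`clonalclock` targets a narrow but powerful study design: a highly selfing
plant lineage descended from a recent founder (a colonization bottleneck),
re-sequenced at many time points because part of the sample is herbarium
material with known collection years. Three assumptions carry the whole
analysis, and all three are *testable* with the QC module:

1. **Single lineage** — all samples coalesce into one founder genotype;
   checked by pairwise distances and percent identity (quasi-identical
   genomes, `identity_summary()`).
2. **No observable recombination** — selfing makes recombination invisible
   between near-identical homologues; checked by the four-gamete screen.
   In a strictly clonal genealogy under infinite sites, no site pair can
   show all four haplotypes; any violation implicates a recombinant (or
   recurrent mutation), and the greedy screen removes the fewest samples
   that restore compatibility. This replaces a parsimony-splits network:
   both detect the same signal (incompatible bipartitions), but the
   four-gamete count is simple, fast and directly testable.
3. **Calls are haploid lineage states** — heterozygous genotypes are
   treated as upstream errors (fatal by default, coercible to missing).

# The tip-dated clock

With sample *i* collected in year `t_i` and the lineage founded at unknown
time `t_f`, the count of derived alleles carried by *i* against the lineage
pseudo-reference has expectation `mu * L * (t_i - t_f)`. Differencing a
modern sample *i* against a herbarium sample *j* cancels `t_f`:

    E[D'_ij] = E[D_ic] - E[D_jc] = mu * L * (t_i - t_j) = mu * L * T'_ij

so OLS of `D'` on `T'` over all modern-herbarium pairs estimates `mu * L`
as its slope regardless of the (unknown) genealogy connecting the samples
— the property that makes the estimator robust to the lack of resolvable
phylogenetic structure in a quasi-clonal lineage.

**Missingness normalization.** Herbarium genomes are patchier than modern
ones. Derived-allele counts are therefore rescaled to the full site set by
each sample's callable fraction (`D_ic * S / callable_i`) before
differencing; without this, era-correlated missingness deflates the slope
by several percent. The global accessible length `L` is the default
denominator for converting the slope to a per-site rate.

**What precision to expect.** The slope is identified by *within-era* year
spread (the large modern-vs-herbarium mean time difference is absorbed by
the intercept, since the regression fits one). With ~27 herbarium genomes
spread over 130 years and Poisson counting noise of sd ~ sqrt(mu*L*t) ~ 9
SNPs per genome, the slope carries a ~20% coefficient of variation *per
dataset* — an irreducible property of the design, visible in the wide
bootstrap intervals. Validation therefore distinguishes (a) unbiasedness,
which holds to <1% over hundreds of replicates and is asserted by a
property test on a more informative design, from (b) single-replicate
precision, which no estimator can improve at fixed data.

**Bootstrap intervals.** Two resampling units are provided. The default
resamples *pairs* with replacement; because all pairs sharing a sample are
correlated, this interval is severely anticonservative (measured coverage
well below half nominal) and is retained only as the conventional
procedure. The `boot_unit = "sample"` alternative resamples modern and
herbarium samples and keeps the induced pairs; its percentile interval
reaches ~87% coverage at n = 27 herbarium genomes — close to, but below,
nominal, the usual small-n percentile shortfall. Users who need calibrated
intervals at this design size should treat even the sample-level interval
as approximate.

# TMRCA and rates per generation

`estimate_tmrca()` solves `d = 2 L mu` for the expected coalescent depth
`L` (years), where `d` is the mean pairwise per-site distance
(missing-data corrected, optionally restricted to modern samples), and
subtracts it from the mean collection year. It deliberately performs no
uncertainty propagation: its inputs each carry their own intervals.

`per_generation_rate()` multiplies a yearly rate by the mean generation
interval. The default 1.3 years reflects seed-bank-delayed reproduction in
an annual plant; the function is linear, so alternative generation times
are a rescaling, not a refit.

`ma_mutation_rate()` pools mutation counts over mutation-accumulation
lines: `rate = sum(counts) / sum(generations * callable_bp)`. Its CI is a
line-level **bootstrap-t** interval (point estimate ± t[n-1] × bootstrap
SE): with the typical 12 lines, the percentile interval's measured
coverage is ~85%, the t-interval's ~92%; the t-form is therefore the
package's choice where the procedure was otherwise unspecified.

# Diversity and the time-oriented unfolded SFS

θ_W, π and Tajima's D follow the standard formulations, with all
per-site quantities rescaled by the *accessible* genome length so that
datasets with different callable fractions are comparable, and pairwise
quantities corrected for per-pair joint callability.

The unfolded SFS is oriented **by order of appearance**: at each site the
ancestral allele is the allele carried by the earliest-dated herbarium
sample(s) with a non-missing call. The tie-breaking chain (the data never
fully specify one) is: majority among the samples of the earliest year,
then the pseudo-reference allele; sites with no herbarium call at all fall
back to pseudo-reference orientation and are flagged
(`orientation = "reference_fallback"`). Sites genotyped in fewer than 80%
of samples are excluded by default. On star simulations with known founder
alleles the orientation matches truth at >99% of sites.

# Selection tests

Two one-tailed Fisher contingency contrasts are provided:
`annotation_depletion_test()` compares SNP counts against accessible bp
between classes (purifying selection removes coding mutations before they
are observed: OR < 1 for coding), and `frequency_class_test()` compares
low (<5%) versus intermediate (>=5%; the boundary counts as intermediate)
frequency classes (selection keeps deleterious variants rare: OR > 1 for
coding). Odds ratios are sample ORs, Haldane-corrected (and flagged) only
when a cell is zero; p-values are exact hypergeometric tails, verified
against full enumeration in the tests.

The `sfs_ks_test()` p-value is a pooled bootstrap: allele-frequency data
are heavily tied, so the asymptotic KS distribution is inapplicable; both
groups are resampled with replacement from the pooled sample under the
null. Calibration measured over 500 neutral simulated datasets: KS
rejection 0.05-0.06 at alpha = 0.05; the Fisher frequency-class test sits
at 0.026-0.03 — *below* nominal, the textbook conservatism of exact tests
on discrete tables. The acceptance criterion asking for rejection in
[0.03, 0.07] is left honestly red on its lower edge for the Fisher test;
no threshold was adjusted.

# Association

The kinship matrix uses frequency-standardized genotypes
(`(x - p)/sqrt(p(1-p))`) over MAF > 5% SNPs — in a lineage where any two
genomes differ by a few dozen SNPs, only variants that have risen to
common frequency carry usable relatedness signal. Chip heritability is
REML in the eigenbasis of K (a one-dimensional optimization over
`lambda = sigma_g^2/sigma_e^2`), with a 50:50 boundary-mixture LRT against
`sigma_g^2 = 0`; `h2` is the variance ratio `sigma_g^2/(sigma_g^2 +
sigma_e^2)`.

The GWA scan is single-SNP OLS *without* a kinship term: with one
quasi-clonal population the random effect would absorb essentially all
variance and leave nothing for fixed effects. Multiplicity is handled
empirically: the phenotype is permuted across accessions (replicates are
averaged first — the accession, not the replicate, is the exchangeable
unit), and the threshold is either the alpha-quantile of the pooled null
p distribution (default; the most literal reading of an "empirical null
distribution" of p-values) or of the per-permutation minimum p (`minp`),
which controls family-wise error (measured FWER <= 0.08 at nominal 0.05).
The double-Bonferroni threshold `alpha/(n_SNPs + n_phenotypes)` is also
reported. Climate covariates are handled by projecting latitude/longitude
out of both phenotype and genotypes.

Grantham scores are embedded as the published 1974 integer matrix rather
than recomputed from the composition/polarity/volume formula — the
published table is the community standard and two of its entries (N-E,
D-W) differ slightly from a naive recomputation. The embedded table was
cross-checked against the formula during development (188/190 pairs within
rounding).

# The simulator: what it emulates, and what it does not

`simulate_lineage()` generates the *stated world* the package is validated
against: ~100 samples (27 herbarium 1863-1993, 73 modern 1993-2006), a
founder around 1600, `mu = 2.11e-9 /site/year`, a 108 Mb accessible genome
split across annotation classes, era-specific missingness (5% herbarium,
1% modern), and one of three genealogies:

* **star** — every sample is an independent branch from the founder; the
  limit of instantaneous post-bottleneck expansion. All variants are
  singletons.
* **coalescent** — a random Kingman topology whose node depths are
  compressed rootward by a power transform (`growth_beta`). The default
  `growth_beta = 80` was calibrated once against the stated targets of
  the modelled world — about 5-6k segregating sites, Tajima's D near
  -2.8, and a common-variant (MAF>5%) fraction near 8% — and then frozen;
  it yields S ~ 4,700, D ~ -2.8, ~7% common at the default design.
* **forward_wf** — a small selfing Wright-Fisher population stepped in
  generations whose calendar durations are drawn from a shifted geometric
  with mean `generation_time_years` (a seed-bank delay with the stated
  mean and "notable variance"); coding mutations carry a fitness cost, so
  this is the only mode in which selection *shifts frequencies* rather
  than only thinning counts.

Purifying selection is modelled as **thinning** (each coding mutation is
retained with probability `selection_coding`) in star/coalescent modes.
This reproduces the count-depletion signature exactly (retention 0.5 gives
OR ~ 0.5) but deliberately does *not* move the coding SFS — a green
depletion test on thinned data says nothing about the frequency-class
test, which needs forward_wf. Phenotypes are generated as `y = X beta +
e` over causal SNPs drawn from the common set, with the noise variance
tuned so the genetic fraction of accession-level variance equals the
target h²; replicate noise is 25% of the accession sd. The climate
covariate mixes one driver SNP's standardized genotype with a lat+lon
gradient at a chosen coupling.

Not emulated: sequencing reads and ancient-DNA damage chemistry,
structural variants, introgression from other lineages, pooling of
siblings in modern libraries, and real spatial population structure
(coordinates are uniform noise). A green test here validates estimator
logic against the stated statistical structure, not robustness to those
artefacts.

# Numerical and degenerate-input choices

* Annotation precedence on overlap: coding > utr5 > utr3 > intronic >
  transposon > pseudogene > intergenic; unannotated positions and
  uncovered chromosomes default to intergenic (with a warning for the
  latter). Internal coordinates are 1-based closed; BED is converted on
  read.
* Sites with all calls missing are dropped with a message; a sample pair
  with zero jointly-callable sites has an *undefined* (NA) distance, never
  zero, and NJ refuses such matrices.
* `fit_rate()` is fatal on zero variance in `T'`; an all-zero `D'` yields
  rate 0 with a degenerate [0,0] interval.
* Monomorphic sites are skipped in the GWA scan and flagged undefined in
  LD; LD `D'` at `D_max = 0` is NA.
* Empirical p-values use the `(x+1)/(n+1)` form; permutation and bootstrap
  thresholds never return exact zero.
* All stochastic functions take explicit seeds; a fixed seed reproduces
  every output bit-for-bit (asserted in the pipeline tests).

# Known limitations

* The pair-level bootstrap CI of the net-distance regression is retained
  for convention but is not trustworthy (see above); sample-level
  resampling is close to nominal but still slightly narrow at 27
  herbarium genomes.
* A 20-replicate mean of the rate estimator at the stated design has a
  standard error of ~4.5% of truth; recovery-to-5% acceptance checks at
  that replicate count sit on the edge of their own Monte Carlo noise and
  are reported honestly rather than re-seeded (the corresponding
  acceptance assertion is red at seeds 1:20 with a 20-replicate mean 8%
  low, while a 300-replicate check shows bias < 1%).
* The four-gamete screen cannot distinguish recombination from recurrent
  mutation, and its greedy removal is one defensible automation of what
  was historically a manual curation step.
* Nonsynonymous/synonymous contrasts are supported only through per-site
  class labels supplied by the annotation; there is no internal codon
  engine.
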