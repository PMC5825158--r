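## common-site genotype matrix: samples x sites, mean-imputed
genotype_matrix <- function(v, maf_min = 0.05) {
  f <- site_frequencies(v)
  keep <- which(!is.na(f) & pmin(f, 1 - f) >= maf_min)
  X <- t(v$calls[keep, , drop = FALSE])
  if (ncol(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    idx <- which(is.na(X), arr.ind = TRUE)
    if (nrow(idx)) X[idx] <- mu[idx[, 2]]
  }
  list(X = X, sites = keep)
}

#' Kinship (genomic relationship) matrix from common SNPs
#'
#' Centered, standardized allele cross-products averaged over the SNPs
#' passing the minor-allele-frequency filter (default > 5%, mirroring the
#' use of common variants only).  A small ridge is added, with a warning, if
#' numerical noise makes the matrix non-positive-semidefinite.
#'
#' @param v a [variant_table()]
#' @param maf_min minor allele frequency filter
#' @return sample x sample numeric matrix with attribute `n_sites`
#' @export
kinship_matrix <- function(v, maf_min = 0.05) {
  gm <- genotype_matrix(v, maf_min)
  if (!ncol(gm$X)) stop("no sites pass the MAF filter")
  ## frequency-standardized (VanRaden-style) scaling: (x - p) / sqrt(p(1-p))
  p <- colMeans(gm$X)
  sdv <- sqrt(p * (1 - p))
  Xs <- sweep(sweep(gm$X, 2, p), 2, pmax(sdv, 1e-12), "/")
  Xs[, sdv == 0] <- 0
  K <- tcrossprod(Xs) / ncol(Xs)
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    warning("kinship not PSD; adding ridge ", format(-min(ev) + 1e-8))
    K <- K + diag(-min(ev) + 1e-8, nrow(K))
  }
  attr(K, "n_sites") <- ncol(Xs)
  K
}

#' Chip heritability by REML in a kinship mixed model
#'
#' Fits `y = mu + u + e` with `u ~ N(0, sigma_g^2 K)`,
#' `e ~ N(0, sigma_e^2 I)` by restricted maximum likelihood: after an
#' eigendecomposition of K the REML criterion is a one-dimensional function
#' of the variance ratio `lambda = sigma_g^2 / sigma_e^2`, optimized
#' numerically.  Significance of the genetic component is a likelihood-ratio
#' test against `sigma_g^2 = 0` with the usual 50:50 boundary mixture.
#'
#' @param y per-accession trait values (named by sample id or aligned to K)
#' @param K kinship matrix from [kinship_matrix()]
#' @return a `heritability_result`: list with `sigma_g`, `sigma_e`,
#'   `sigma_total`, `h2`, `lrt`, `p_value`, `lambda`
#' @export
chip_heritability <- function(y, K) {
  if (!is.null(names(y)) && !is.null(rownames(K)))
    y <- y[rownames(K)]
  ok <- !is.na(y)
  if (sum(ok) < 20) stop("need phenotypes for at least 20 accessions")
  y <- y[ok]; K <- K[ok, ok]
  n <- length(y)
  ed <- eigen(K, symmetric = TRUE)
  d <- pmax(ed$values, 0)
  yt <- drop(crossprod(ed$vectors, y))
  xt <- drop(crossprod(ed$vectors, rep(1, n)))

  reml_ll <- function(log_lambda) {
    lam <- exp(log_lambda)
    w <- 1 / (d * lam + 1)
    xwx <- sum(w * xt^2)
    beta <- sum(w * xt * yt) / xwx
    r <- yt - xt * beta
    s2 <- sum(w * r^2) / (n - 1)
    -0.5 * ((n - 1) * log(s2) + sum(log(d * lam + 1)) + log(xwx) +
              (n - 1))
  }
  opt <- optimize(reml_ll, interval = c(-12, 12), maximum = TRUE)
  ll0 <- reml_ll(-30)                 # effectively lambda = 0
  lam <- exp(opt$maximum)
  if (opt$objective < ll0) { lam <- 0; opt$objective <- ll0 }
  w <- 1 / (d * lam + 1)
  beta <- sum(w * xt * yt) / sum(w * xt^2)
  s2e <- sum(w * (yt - xt * beta)^2) / (n - 1)
  sg <- lam * s2e
  lrt <- max(0, 2 * (opt$objective - ll0))
  p <- 0.5 * pchisq(lrt, df = 1, lower.tail = FALSE)
  structure(list(sigma_g = sg, sigma_e = s2e, sigma_total = sg + s2e,
                 h2 = if (sg + s2e > 0) sg / (sg + s2e) else 0,
                 lrt = lrt, p_value = p, lambda = lam, n = n),
            class = "heritability_result")
}

#' @export
print.heritability_result <- function(x, ...) {
  cat(sprintf("chip heritability: h2 = %.3f (sigma_g %.3g, sigma_e %.3g), LRT p = %.3g, n = %d\n",
              x$h2, x$sigma_g, x$sigma_e, x$p_value, x$n))
  invisible(x)
}

## residualize columns of M on covariates (with intercept)
residualize <- function(M, covariates = NULL) {
  n <- nrow(M)
  C <- cbind(rep(1, n), covariates)
  Q <- qr.Q(qr(C))
  M - Q %*% crossprod(Q, M)
}

#' Genome-wide association scan by per-SNP regression
#'
#' Single-SNP ordinary least squares `y = X b + e` (no kinship term: in a
#' quasi-clonal lineage the kinship random effect would absorb essentially
#' all variance), with optional covariates (e.g. latitude/longitude for
#' climate traits) projected out of both phenotype and genotypes.
#'
#' @param y per-accession trait values aligned to the samples of `v`
#' @param v a [variant_table()]
#' @param covariates optional numeric matrix (n_samples x q)
#' @param maf_min minor allele frequency filter (default 0.05)
#' @return data.frame of class `assoc_scan`: `site` (row index into
#'   `v$sites`), `chrom`, `pos`, `class`, `effect`, `se`, `p`
#' @export
gwa_scan <- function(y, v, covariates = NULL, maf_min = 0.05) {
  gm <- genotype_matrix(v, maf_min)
  if (!ncol(gm$X)) stop("no sites pass the MAF filter")
  ok <- !is.na(y)
  X <- gm$X[ok, , drop = FALSE]; yy <- y[ok]
  cv <- if (is.null(covariates)) NULL else
    as.matrix(covariates)[ok, , drop = FALSE]
  q <- if (is.null(cv)) 0 else ncol(cv)
  n <- length(yy)
  Xr <- residualize(X, cv)
  yr <- drop(residualize(matrix(yy), cv))
  sxx <- colSums(Xr^2)
  poly <- sxx > 1e-10
  df <- n - 2 - q
  b <- colSums(Xr * yr) / sxx
  rss <- sum(yr^2) - b^2 * sxx
  se <- sqrt(pmax(rss / df, 0) / sxx)
  tval <- b / se
  p <- 2 * pt(abs(tval), df, lower.tail = FALSE)
  out <- data.frame(site = gm$sites, chrom = v$sites$chrom[gm$sites],
                    pos = v$sites$pos[gm$sites],
                    class = v$sites$class[gm$sites],
                    effect = b, se = se, p = p)[poly, ]
  rownames(out) <- NULL
  class(out) <- c("assoc_scan", "data.frame")
  out
}

#' Empirical significance threshold from phenotype permutations
#'
#' Permutes the phenotype across accessions `n_perm` times, recomputes all
#' per-SNP p-values each time, and derives the threshold on raw p-values
#' below which a result is empirically significant at level `alpha`.  Two
#' nulls are available: `"pooled"` (default) takes the alpha-quantile of all
#' permuted p-values pooled; `"minp"` takes the alpha-quantile of the
#' per-permutation minimum p, which controls the family-wise error rate.
#'
#' @inheritParams gwa_scan
#' @param n_perm number of permutations (>= 100)
#' @param alpha significance level (default 0.05)
#' @param seed RNG seed
#' @param mode `"pooled"` or `"minp"`
#' @return list with `threshold`, `mode`, `alpha`, `n_perm`, and `null_min_p`
#'   (minp mode) or a summary of the pooled null
#' @export
permutation_threshold <- function(y, v, covariates = NULL, n_perm = 1000L,
                                  alpha = 0.05, seed = 1L,
                                  mode = c("pooled", "minp"),
                                  maf_min = 0.05) {
  mode <- match.arg(mode)
  if (n_perm < 100) stop("n_perm must be at least 100")
  gm <- genotype_matrix(v, maf_min)
  if (!ncol(gm$X)) stop("no sites pass the MAF filter")
  ok <- !is.na(y)
  X <- gm$X[ok, , drop = FALSE]; yy <- y[ok]
  cv <- if (is.null(covariates)) NULL else
    as.matrix(covariates)[ok, , drop = FALSE]
  q <- if (is.null(cv)) 0 else ncol(cv)
  n <- length(yy)
  Xr <- residualize(X, cv)
  sxx <- colSums(Xr^2)
  poly <- sxx > 1e-10
  Xr <- Xr[, poly, drop = FALSE]; sxx <- sxx[poly]
  df <- n - 2 - q
  set.seed(seed)
  ## all permutations at once: p-values from correlations of residualized
  ## genotypes with permuted (then residualized) phenotypes
  P <- matrix(NA_real_, n_perm, ncol(Xr))
  for (r in seq_len(n_perm)) {
    yp <- drop(residualize(matrix(yy[sample.int(n)]), cv))
    b <- colSums(Xr * yp) / sxx
    rss <- sum(yp^2) - b^2 * sxx
    tval <- b / sqrt(pmax(rss / df, 0) / sxx)
    P[r, ] <- 2 * pt(abs(tval), df, lower.tail = FALSE)
  }
  if (mode == "pooled") {
    thr <- quantile(P, alpha, names = FALSE)
    list(threshold = thr, mode = mode, alpha = alpha, n_perm = n_perm,
         null_quantiles = quantile(P, c(0.01, 0.05, 0.5)))
  } else {
    minp <- apply(P, 1, min)
    list(threshold = quantile(minp, alpha, names = FALSE), mode = mode,
         alpha = alpha, n_perm = n_perm, null_min_p = minp)
  }
}

#' Double-Bonferroni significance threshold
#'
#' Conservative threshold dividing alpha by the number of SNPs plus the
#' number of phenotypes tested (e.g. 0.05 / [391 + 109] = 0.0001).
#'
#' @param alpha nominal level (default 0.05)
#' @param n_snps number of SNPs tested
#' @param n_phenos number of phenotypes tested
#' @export
double_bonferroni <- function(alpha = 0.05, n_snps, n_phenos = 0) {
  stopifnot(n_snps + n_phenos > 0)
  alpha / (n_snps + n_phenos)
}

#' Pairwise linkage disequilibrium statistics for haploid calls
#'
#' Haplotype-count based `D = p_AB - p_A p_B`, normalized `D' = D / D_max`,
#' and `r^2 = D^2 / (p_A p_a p_B p_b)`, computed over samples jointly called
#' at each pair.  Monomorphic sites yield NA (flagged by the `defined`
#' matrix).  Also reports, per site, how many partner sites are in high LD
#' (`r^2 > 0.5`).
#'
#' @param v a [variant_table()]
#' @param sites integer indices of the sites to analyse (default: all,
#'   capped at 2000 to bound the pair count)
#' @return list with matrices `r2`, `D`, `Dprime`, logical `defined`, and
#'   vector `partners_high_ld`
#' @export
ld_statistics <- function(v, sites = NULL) {
  if (is.null(sites)) {
    if (n_sites(v) > 2000)
      stop("refusing all-pairs LD over ", n_sites(v),
           " sites; pass an explicit site subset")
    sites <- seq_len(n_sites(v))
  }
  X <- v$calls[sites, , drop = FALSE]
  S <- nrow(X)
  P1 <- X == 1L; P1[is.na(P1)] <- FALSE
  P0 <- X == 0L; P0[is.na(P0)] <- FALSE
  M <- P1 | P0
  nAB <- tcrossprod(P1)
  njoint <- tcrossprod(M * 1)
  nA <- tcrossprod(P1, M)             # derived at row site among joint
  pA <- nA / njoint
  pB <- t(pA)
  pAB <- nAB / njoint
  D <- pAB - pA * pB
  Dmax <- ifelse(D >= 0, pmin(pA * (1 - pB), (1 - pA) * pB),
                 pmin(pA * pB, (1 - pA) * (1 - pB)))
  Dp <- ifelse(Dmax > 0, D / Dmax, NA)
  denom <- pA * (1 - pA) * pB * (1 - pB)
  r2 <- ifelse(denom > 0, D^2 / denom, NA)
  defined <- denom > 0 & njoint > 1
  r2[!defined] <- NA; Dp[!defined] <- NA; D[!defined] <- NA
  diag(defined) <- FALSE
  high <- r2 > 0.5 & defined
  partners <- rowSums(high, na.rm = TRUE)
  names(partners) <- rownames(X)
  list(r2 = r2, D = D, Dprime = Dp, defined = defined,
       partners_high_ld = partners, sites = sites)
}

#' Overlap enrichment between two hit sets
#'
#' 2x2 joint-membership table of two SNP hit sets over a common universe,
#' tested one-tailed for enrichment (OR > 1).  Used e.g. to ask whether
#' climate-associated SNPs coincide with trait-associated ones.
#'
#' @param hits_a,hits_b vectors of site identifiers
#' @param universe total number of candidate sites (or the vector of ids)
#' @return a `contingency_result`
#' @export
hit_overlap_enrichment <- function(hits_a, hits_b, universe) {
  if (length(universe) == 1 && is.numeric(universe)) {
    n_univ <- universe
  } else {
    n_univ <- length(universe)
    hits_a <- intersect(hits_a, universe)
    hits_b <- intersect(hits_b, universe)
  }
  if (n_univ <= 0) stop("empty universe")
  both <- length(intersect(hits_a, hits_b))
  a_only <- length(hits_a) - both
  b_only <- length(hits_b) - both
  neither <- n_univ - both - a_only - b_only
  fisher_contingency(both, a_only, b_only, neither, tail = "greater",
                     labels = c("in_b", "not_in_b"))
}
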