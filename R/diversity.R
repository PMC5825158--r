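#' Watterson's theta per site
#'
#' `theta_W = S / (a_n * L)` with `a_n = sum(1/i, i = 1..n-1)`: the number of
#' segregating sites rescaled by sample size and by the accessible genome
#' length, so estimates from differently-sized callable genomes are
#' comparable.
#'
#' @param S number of segregating sites
#' @param n number of sequences sampled
#' @param L accessible genome length in bp
#' @export
watterson_theta <- function(S, n, L) {
  stopifnot(S >= 0, L > 0)
  if (n < 2) stop("need at least 2 sequences")
  S / (sum(1 / seq_len(n - 1)) * L)
}

## mean pairwise difference count, corrected for per-pair missingness by
## rescaling each pair's count to the full site set
mean_pairwise_diff <- function(v) {
  pd <- pairwise_distance_matrix(v)
  ut <- upper.tri(pd$d)
  S <- n_sites(v)
  corr <- pd$d[ut] * ifelse(pd$callable[ut] > 0, S / pd$callable[ut],
                            NA_real_)
  mean(corr, na.rm = TRUE)
}

#' Nucleotide diversity per site
#'
#' Average pairwise per-site difference: each pair's SNP distance over its
#' jointly-callable sites, rescaled to the full site set and divided by the
#' accessible genome length.
#'
#' @param v a [variant_table()]
#' @param L accessible genome length in bp
#' @export
nucleotide_diversity <- function(v, L) {
  stopifnot(L > 0)
  if (n_samples(v) < 2) stop("need at least 2 samples")
  if (n_sites(v) == 0) return(0)
  mean_pairwise_diff(v) / L
}

#' Tajima's D
#'
#' The normalized difference between nucleotide diversity and Watterson's
#' theta (both in count units), using the standard constants
#' a1, a2, b1, b2, c1, c2, e1, e2 of the 1989 formulation.  Strongly negative
#' values indicate an excess of rare variants, as expected after a recent
#' bottleneck followed by expansion.
#'
#' @param v a [variant_table()]
#' @return Tajima's D (NA with a warning if no segregating sites)
#' @export
tajimas_d <- function(v) {
  n <- n_samples(v)
  if (n < 4) stop("need at least 4 samples")
  S <- n_sites(v)
  if (S < 1) {
    warning("no segregating sites; Tajima's D undefined")
    return(NA_real_)
  }
  k <- mean_pairwise_diff(v)
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (k - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Unfolded site frequency spectrum oriented by first appearance
#'
#' Uses the temporal structure of the sampling to orient alleles: at each
#' site the ancestral allele is taken to be the one carried by the
#' earliest-dated herbarium sample(s) with a non-missing call (majority among
#' ties on the earliest year, then the pseudo-reference allele).  Sites with
#' no herbarium call fall back to pseudo-reference orientation and are
#' flagged.  Derived counts are then computed over all samples with
#' non-missing calls.
#'
#' @param v a [variant_table()]
#' @param meta `sample_meta` with herbarium samples dated
#' @param min_called_frac sites genotyped in less than this fraction of
#'   samples are excluded (default 0.8)
#' @return an `sfs_bundle`: list with `sites` (data.frame: class,
#'   derived_count, n_called, frequency, flipped, orientation),
#'   `spectra` (per-class tables of derived counts), `n_excluded`
#' @export
unfolded_sfs <- function(v, meta, min_called_frac = 0.8) {
  m <- meta[match(colnames(v$calls), meta$sample_id), ]
  herb <- which(m$era == "herbarium" & !is.na(m$year))
  if (!length(herb)) stop("no dated herbarium samples for orientation")
  n_called <- rowSums(!is.na(v$calls))
  keep <- n_called >= min_called_frac * n_samples(v)
  n_excluded <- sum(!keep)
  calls <- v$calls[keep, , drop = FALSE]
  cls <- v$sites$class[keep]
  nc <- n_called[keep]

  H <- calls[, herb, drop = FALSE]
  hy <- m$year[herb]
  ns <- nrow(calls)
  anc_state <- integer(ns)            # 0 = reference allele ancestral
  orientation <- rep("herbarium", ns)
  for (s in seq_len(ns)) {
    obs <- which(!is.na(H[s, ]))
    if (!length(obs)) {
      orientation[s] <- "reference_fallback"
      anc_state[s] <- 0L
      next
    }
    first <- obs[hy[obs] == min(hy[obs])]
    tab <- c(`0` = sum(H[s, first] == 0L), `1` = sum(H[s, first] == 1L))
    anc_state[s] <- if (tab["1"] > tab["0"]) 1L else 0L  # tie -> reference
  }
  der <- rowSums(calls == 1L, na.rm = TRUE)
  derived_count <- ifelse(anc_state == 1L, nc - der, der)
  out <- data.frame(chrom = v$sites$chrom[keep], pos = v$sites$pos[keep],
                    class = cls, derived_count = derived_count,
                    n_called = nc,
                    frequency = ifelse(nc > 0, derived_count / nc, NA),
                    flipped = anc_state == 1L, orientation = orientation,
                    stringsAsFactors = FALSE)
  spectra <- lapply(split(out$derived_count, out$class), function(x)
    table(factor(x, levels = 0:max(1, max(x)))))
  structure(list(sites = out, spectra = spectra, n_excluded = n_excluded),
            class = "sfs_bundle")
}

#' @export
print.sfs_bundle <- function(x, ...) {
  cat("sfs_bundle:", nrow(x$sites), "oriented sites (",
      sum(x$sites$orientation == "reference_fallback"),
      "reference fallbacks,", x$n_excluded, "excluded for missingness)\n")
  invisible(x)
}
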