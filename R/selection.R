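#' One-tailed Fisher's exact test on a 2x2 table
#'
#' Exact hypergeometric p-value (via [stats::fisher.test]) with the sample
#' odds ratio `OR = (a/b) / (c/d)`; a Haldane 0.5 correction is applied to
#' the OR (and flagged) only when a cell is zero.  `tail = "less"` tests
#' OR < 1, `"greater"` tests OR > 1.
#'
#' @param a,b,c,d nonnegative integer cell counts, rows = categories
#'   contrasted, columns = outcome
#' @param tail `"less"`, `"greater"` or `"two"`
#' @param labels optional character(2) naming the contrasted categories
#' @return a `contingency_result`: list with `table`, `odds_ratio`,
#'   `p_value`, `tail`, `labels`, `corrected`
#' @export
fisher_contingency <- function(a, b, c, d, tail = c("less", "greater", "two"),
                               labels = c("a", "b")) {
  tail <- match.arg(tail)
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be nonnegative integers")
  tab <- matrix(round(cells), 2, byrow = TRUE,
                dimnames = list(labels, c("x", "y")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("a margin of the contingency table is zero")
  alt <- if (tail == "two") "two.sided" else tail
  p <- fisher.test(tab, alternative = alt)$p.value
  corrected <- any(tab == 0)
  t2 <- if (corrected) tab + 0.5 else tab
  or <- (t2[1, 1] / t2[1, 2]) / (t2[2, 1] / t2[2, 2])
  structure(list(table = tab, odds_ratio = unname(or), p_value = p,
                 tail = tail, labels = labels, corrected = corrected),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("Fisher exact (%s vs %s, tail=%s): OR = %.3g, p = %.3g%s\n",
              x$labels[1], x$labels[2], x$tail, x$odds_ratio, x$p_value,
              if (x$corrected) " [Haldane-corrected OR]" else ""))
  invisible(x)
}

#' Test for depletion of SNPs in one annotation class
#'
#' Contrasts SNP density against accessible base pairs between two
#' annotation classes: the table is
#' `[SNPs_a, bp_a - SNPs_a; SNPs_b, bp_b - SNPs_b]`, tested one-tailed
#' toward depletion of `class_a` (OR < 1).  Under purifying selection coding
#' regions show fewer variants per accessible bp than neutral ones.
#'
#' @param v a [variant_table()] with per-class accessible lengths
#' @param class_a,class_b annotation classes to contrast (a = putatively
#'   selected, e.g. `"coding"`); either may be a vector of classes, pooled
#' @return a `contingency_result`
#' @export
annotation_depletion_test <- function(v, class_a = "coding",
                                      class_b = "intergenic") {
  acc <- v$accessible_length
  bp_a <- sum(acc[class_a], na.rm = TRUE)
  bp_b <- sum(acc[class_b], na.rm = TRUE)
  if (is.na(bp_a) || is.na(bp_b) || bp_a <= 0 || bp_b <= 0)
    stop("both classes need accessible lengths in the variant table")
  snp_a <- sum(v$sites$class %in% class_a)
  snp_b <- sum(v$sites$class %in% class_b)
  fisher_contingency(snp_a, bp_a - snp_a, snp_b, bp_b - snp_b,
                     tail = "less",
                     labels = c(paste(class_a, collapse = "+"),
                                paste(class_b, collapse = "+")))
}

#' Frequency-class contingency test at the 5% cutoff
#'
#' Splits derived-allele frequencies into low (< cutoff) and intermediate
#' (>= cutoff; the boundary counts as intermediate) and contrasts the two
#' classes with a one-tailed Fisher test toward low-frequency enrichment of
#' `class_a` (OR > 1).  Purifying selection keeps deleterious variants rarer
#' than neutral ones.
#'
#' @param sfs an `sfs_bundle` from [unfolded_sfs()]
#' @param class_a,class_b annotation classes (vectors pooled)
#' @param cutoff low/intermediate frequency boundary (default 0.05)
#' @return a `contingency_result`
#' @export
frequency_class_test <- function(sfs, class_a = "coding",
                                 class_b = "intergenic", cutoff = 0.05) {
  s <- sfs$sites
  fa <- s$frequency[s$class %in% class_a]
  fb <- s$frequency[s$class %in% class_b]
  if (!length(fa) || !length(fb))
    stop("no sites in one of the contrasted classes (",
         paste(class_a, collapse = "+"), " n=", length(fa), "; ",
         paste(class_b, collapse = "+"), " n=", length(fb), ")")
  fisher_contingency(sum(fa < cutoff), sum(fa >= cutoff),
                     sum(fb < cutoff), sum(fb >= cutoff),
                     tail = "greater",
                     labels = c(paste(class_a, collapse = "+"),
                                paste(class_b, collapse = "+")))
}

#' Two-sample Kolmogorov-Smirnov test with a pooled bootstrap null
#'
#' Compares two frequency distributions by the KS statistic D (maximum
#' absolute difference of the empirical CDFs).  Because allele-frequency data
#' are heavily tied, the p-value comes from resampling both groups with
#' replacement from the pooled sample under the null rather than from the
#' asymptotic distribution.
#'
#' @param freqs_a,freqs_b numeric vectors
#' @param n_boot bootstrap replicates (default 10000; < 100 warns)
#' @param seed RNG seed
#' @return list with `D` and `p_value`
#' @export
sfs_ks_test <- function(freqs_a, freqs_b, n_boot = 10000L, seed = 1L) {
  stopifnot(length(freqs_a) > 0, length(freqs_b) > 0)
  if (n_boot < 100) warning("n_boot < 100 gives a very coarse p-value")
  na <- length(freqs_a); nb <- length(freqs_b)
  pool <- c(freqs_a, freqs_b)
  g <- sort(unique(pool))          # tie-aware support of both samples
  code <- match(pool, g)
  nu <- length(g)
  ks_from_codes <- function(ca, cb) {
    Fx <- cumsum(tabulate(ca, nu)) / length(ca)
    Fy <- cumsum(tabulate(cb, nu)) / length(cb)
    max(abs(Fx - Fy))
  }
  D <- ks_from_codes(code[seq_len(na)], code[na + seq_len(nb)])
  set.seed(seed)
  exceed <- 0L
  ntot <- na + nb
  for (r in seq_len(n_boot)) {
    ca <- code[sample.int(ntot, na, replace = TRUE)]
    cb <- code[sample.int(ntot, nb, replace = TRUE)]
    if (ks_from_codes(ca, cb) >= D - 1e-12) exceed <- exceed + 1L
  }
  list(D = D, p_value = (exceed + 1) / (n_boot + 1))
}
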