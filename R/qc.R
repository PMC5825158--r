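#' Pairwise SNP distances between samples
#'
#' Distance between two samples is the number of sites where both calls are
#' non-missing and differ; the number of jointly-callable sites is recorded
#' alongside.  A pair with zero jointly-callable sites gets an `NA` distance
#' (undefined, not zero) and is flagged.
#'
#' @param v a [variant_table()]
#' @param meta optional `sample_meta`; when given, each pair is categorised
#'   as herbarium-herbarium, herbarium-modern or modern-modern
#' @return object of class `pairwise_distances`: list with `d` (symmetric
#'   integer matrix, NA where undefined), `callable` (jointly-callable site
#'   counts), `category` (character matrix or NULL), `undefined_pairs`
#' @export
pairwise_distance_matrix <- function(v, meta = NULL) {
  if (n_samples(v) < 2) stop("need at least 2 samples")
  A <- v$calls == 1L; A[is.na(A)] <- FALSE
  B <- v$calls == 0L; B[is.na(B)] <- FALSE
  M <- !is.na(v$calls)
  d <- crossprod(A, B) + crossprod(B, A)
  callable <- crossprod(M)
  d[callable == 0] <- NA
  diag(d) <- ifelse(diag(callable) == 0, NA, 0)
  undef <- which(is.na(d) & upper.tri(d), arr.ind = TRUE)
  category <- NULL
  if (!is.null(meta)) {
    era <- meta$era[match(colnames(v$calls), meta$sample_id)]
    category <- outer(era, era, function(a, b)
      paste(pmin(a, b), pmax(a, b), sep = "-"))
    dimnames(category) <- dimnames(d)
  }
  structure(list(d = d, callable = callable, category = category,
                 undefined_pairs = undef),
            class = "pairwise_distances")
}

#' @export
print.pairwise_distances <- function(x, ...) {
  ut <- x$d[upper.tri(x$d)]
  cat("pairwise_distances over", ncol(x$d), "samples; SNP differences",
      "range", suppressWarnings(min(ut, na.rm = TRUE)), "-",
      suppressWarnings(max(ut, na.rm = TRUE)), "\n")
  if (nrow(x$undefined_pairs))
    cat(nrow(x$undefined_pairs), "pair(s) undefined (no joint coverage)\n")
  invisible(x)
}

#' Neighbor-joining tree from pairwise distances
#'
#' Standard NJ agglomeration (via [ape::nj]); deterministic for a given
#' input order.  Intended as an unrooted visual check that the samples form
#' a single quasi-clonal lineage: star-like data yield short internal and
#' long terminal branches.
#'
#' @param d a `pairwise_distances` object (or a symmetric numeric matrix)
#' @return an [ape::phylo] tree
#' @export
nj_tree <- function(d) {
  m <- if (inherits(d, "pairwise_distances")) d$d else as.matrix(d)
  if (any(is.na(m)))
    stop("distance matrix has undefined entries; cannot build NJ tree")
  ape::nj(stats::as.dist(m))
}

#' Four-gamete screen for recombinant genomes
#'
#' In a strictly clonal (non-recombining, infinite-sites) lineage no pair of
#' sites can show all four haplotypes 00/01/10/11.  This screen counts
#' incompatible site pairs and greedily flags samples: at each step the
#' sample whose removal most reduces the incompatible-pair count is removed
#' (ties broken by column order), until no incompatibility remains or
#' `max_removals` is hit.  Used in place of a parsimony-splits network:
#' reticulation and four-gamete violations flag the same signal.
#'
#' @param v a [variant_table()]
#' @param min_count minimum derived-allele count for a site to enter the
#'   screen; the default 2 excludes singletons, which cannot by themselves
#'   create a violation but inflate the pair count
#' @param max_removals cap on greedy sample removals
#' @return list with `incompatible_pairs` (count over all retained sites),
#'   `flagged` (sample ids removed, possibly empty),
#'   `residual_pairs` (count after removals)
#' @export
four_gamete_screen <- function(v, min_count = 2L, max_removals = 5L) {
  dac <- rowSums(v$calls == 1L, na.rm = TRUE)
  n_called <- rowSums(!is.na(v$calls))
  keep <- dac >= min_count & (n_called - dac) >= min_count
  X <- v$calls[keep, , drop = FALSE]
  samples <- colnames(v$calls)
  count_pairs <- function(X) {
    if (nrow(X) < 2) return(0L)
    ## collapse identical site patterns: clonal data have few distinct ones
    key <- apply(X, 1, paste, collapse = ",")
    mult <- as.vector(table(key)[unique(key)])
    U <- X[!duplicated(key), , drop = FALSE]
    P1 <- U == 1L; P1[is.na(P1)] <- FALSE
    P0 <- U == 0L; P0[is.na(P0)] <- FALSE
    n11 <- tcrossprod(P1)
    n00 <- tcrossprod(P0)
    n10 <- tcrossprod(P1, P0)
    n01 <- tcrossprod(P0, P1)
    bad <- n11 > 0 & n00 > 0 & n10 > 0 & n01 > 0
    diag(bad) <- FALSE
    ## expand pattern pairs back to site pairs
    sum(tcrossprod(mult)[bad]) / 2
  }
  total <- count_pairs(X)
  flagged <- character(0)
  res <- total
  Xc <- X
  while (res > 0 && length(flagged) < max_removals && ncol(Xc) > 2) {
    per <- vapply(seq_len(ncol(Xc)), function(j)
      count_pairs(Xc[, -j, drop = FALSE]), numeric(1))
    j <- which.min(per)
    flagged <- c(flagged, colnames(Xc)[j])
    Xc <- Xc[, -j, drop = FALSE]
    res <- per[j]
  }
  list(incompatible_pairs = total, flagged = flagged, residual_pairs = res)
}

#' Minimum percent identity across all sample pairs
#'
#' `100 * (1 - max pairwise SNP distance / accessible_bp)`: how identical the
#' two most different genomes in the set are, over the callable genome.
#'
#' @param d a `pairwise_distances` object
#' @param accessible_bp callable genome size in bp
#' @return minimum pairwise percent identity (scalar)
#' @export
identity_summary <- function(d, accessible_bp) {
  stopifnot(accessible_bp > 0)
  mx <- suppressWarnings(max(d$d, na.rm = TRUE))
  if (!is.finite(mx)) stop("all pairwise distances undefined")
  100 * (1 - mx / accessible_bp)
}
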