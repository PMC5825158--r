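## fixtures are built in code; nothing is stored on disk

## tiny variant table: calls is a sites x samples matrix (0/1/NA)
toy_variants <- function(calls, classes = NULL, accessible = NULL,
                         pos = NULL) {
  calls <- as.matrix(calls)
  ns <- nrow(calls)
  if (is.null(colnames(calls)))
    colnames(calls) <- sprintf("S%02d", seq_len(ncol(calls)))
  if (is.null(classes)) classes <- rep("intergenic", ns)
  if (is.null(pos)) pos <- seq_len(ns) * 10L
  if (is.null(accessible)) accessible <- c(total = 1e6)
  sites <- data.frame(chrom = rep("chr1", ns), pos = pos,
                      ancestral = rep("A", ns), derived = rep("T", ns),
                      class = classes, stringsAsFactors = FALSE)
  variant_table(sites, calls, accessible)
}

toy_meta <- function(ids, years, eras) {
  sample_meta(data.frame(sample_id = ids, year = years,
                         latitude = seq(40, 41, length.out = length(ids)),
                         longitude = seq(-90, -89,
                                         length.out = length(ids)),
                         era = eras, stringsAsFactors = FALSE))
}

## write a small VCF by hand (independent of write_vcf) for reader tests
write_toy_vcf <- function(path, gt, pos = NULL, ann = NULL,
                          ref = "A", alt = "T") {
  gt <- as.matrix(gt)
  ns <- nrow(gt)
  if (is.null(pos)) pos <- seq_len(ns) * 100L
  if (is.null(ann)) ann <- rep("other", ns)
  samples <- colnames(gt)
  lines <- c("##fileformat=VCFv4.2",
             "##contig=<ID=chr1>",
             "##INFO=<ID=ANN,Number=1,Type=String,Description=\"class\">",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"))
  for (i in seq_len(ns))
    lines <- c(lines, paste(c("chr1", pos[i], ".", ref, alt, ".", "PASS",
                              paste0("ANN=", ann[i]), "GT", gt[i, ]),
                            collapse = "\t"))
  writeLines(lines, path)
  path
}

## planted-recombinant fixture: two diverged clonal parent haplotypes plus
## one child carrying parent A's alleles left of a random breakpoint and
## parent B's right of it; site order is shuffled so the breakpoint is not
## positional, and sprinkled singletons mimic private mutations
recombinant_fixture <- function(n_sites = 60, n_clone = 4, seed = 1) {
  set.seed(seed)
  bp <- sample(seq(n_sites %/% 3, 2 * n_sites %/% 3), 1)
  a <- c(rep(1L, bp), rep(0L, n_sites - bp))
  b <- 1L - a
  child <- rep(1L, n_sites)            # A-left + B-right = all derived
  calls <- cbind(matrix(a, n_sites, n_clone), matrix(b, n_sites, n_clone),
                 matrix(0L, n_sites, 2), child)
  colnames(calls) <- c(sprintf("A%d", 1:n_clone), sprintf("B%d", 1:n_clone),
                       "R1", "R2", "REC")
  calls <- calls[sample.int(n_sites), , drop = FALSE]
  ## private singleton mutations (excluded by the screen's MAF filter)
  extra <- matrix(0L, 5, ncol(calls))
  extra[cbind(1:5, sample.int(ncol(calls), 5))] <- 1L
  colnames(extra) <- colnames(calls)
  toy_variants(rbind(calls, extra))
}
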