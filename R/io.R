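## Annotation classes recognised throughout the package, in precedence order
## (highest first).  Precedence resolves overlapping annotation intervals and
## matches the coding-centric contrasts used by the selection tests.
ANNOTATION_CLASSES <- c("coding", "utr5", "utr3", "intronic", "transposon",
                        "pseudogene", "intergenic", "other")

#' Construct a variant table
#'
#' A `variant_table` is the central container of the package: a set of
#' biallelic sites called against a lineage pseudo-reference, together with a
#' sites x samples matrix of haploid (or homozygous, collapsed) calls.  The
#' lineage is assumed selfing, so no heterozygous state exists in the matrix:
#' `0` = reference/ancestral allele, `1` = alternate/derived allele, `NA` =
#' missing.
#'
#' @param sites data.frame with columns `chrom`, `pos` (1-based), `ancestral`,
#'   `derived` (single bases) and `class` (one of
#'   `r paste(ANNOTATION_CLASSES, collapse = ", ")`).
#' @param calls integer matrix, `nrow(sites)` x n_samples, values 0/1/NA, with
#'   sample ids as column names.
#' @param accessible_length named numeric vector of callable base pairs; must
#'   contain an element `total`, optionally one per annotation class.
#' @param drop_all_missing drop sites where every call is missing (logged).
#' @return an object of class `variant_table`.
#' @export
variant_table <- function(sites, calls, accessible_length,
                          drop_all_missing = TRUE) {
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "ancestral", "derived", "class") %in%
                  names(sites)))
  calls <- as.matrix(calls)
  if (nrow(sites) != nrow(calls))
    stop("sites and calls disagree on the number of sites")
  if (is.null(colnames(calls)))
    stop("calls must carry sample ids as column names")
  if (!"total" %in% names(accessible_length))
    stop("accessible_length must contain a 'total' element")
  bad <- setdiff(unique(sites$class), ANNOTATION_CLASSES)
  if (length(bad))
    stop("unknown annotation class(es): ", paste(bad, collapse = ", "))
  vals <- calls[!is.na(calls)]
  if (length(vals) && !all(vals %in% c(0L, 1L)))
    stop("calls must be 0, 1 or NA (haploid/homozygous lineage states)")

  ## sort by chromosome then position
  o <- order(sites$chrom, sites$pos)
  sites <- sites[o, , drop = FALSE]
  calls <- calls[o, , drop = FALSE]
  dup <- stats::ave(sites$pos, sites$chrom, FUN = function(p)
    as.integer(duplicated(p)))
  if (any(dup == 1L))
    stop("duplicated positions within a chromosome")

  if (drop_all_missing && nrow(calls)) {
    all_na <- rowSums(!is.na(calls)) == 0L
    if (any(all_na)) {
      message("dropping ", sum(all_na), " site(s) with all calls missing")
      sites <- sites[!all_na, , drop = FALSE]
      calls <- calls[!all_na, , drop = FALSE]
    }
  }
  rownames(sites) <- NULL
  structure(list(sites = sites, calls = calls,
                 accessible_length = accessible_length),
            class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat("variant_table: ", nrow(x$sites), " sites x ", ncol(x$calls),
      " samples\n", sep = "")
  cat("accessible length (total): ",
      format(x$accessible_length[["total"]], big.mark = ","), " bp\n", sep = "")
  tab <- table(factor(x$sites$class, levels = ANNOTATION_CLASSES))
  tab <- tab[tab > 0]
  if (length(tab))
    cat("sites per class: ",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Number of samples / sites of a variant table
#' @param v a `variant_table`
#' @export
n_samples <- function(v) ncol(v$calls)

#' @rdname n_samples
#' @export
n_sites <- function(v) nrow(v$sites)

#' Read a sample metadata table
#'
#' Tab-separated file with columns `sample_id`, `year`, `latitude`,
#' `longitude`, `era` (one of `herbarium`, `modern`).  Collection years are
#' calendar years CE and are the tip dates used throughout.
#'
#' @param path file path
#' @return data.frame of class `sample_meta`
#' @export
read_sample_meta <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  sample_meta(m)
}

#' Validate a sample metadata data.frame
#' @param m data.frame with columns sample_id, year, latitude, longitude, era
#' @export
sample_meta <- function(m) {
  need <- c("sample_id", "year", "latitude", "longitude", "era")
  if (!all(need %in% names(m)))
    stop("sample metadata must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(m$sample_id))
    stop("duplicated sample_id in metadata")
  if (!all(m$era %in% c("herbarium", "modern")))
    stop("era must be 'herbarium' or 'modern'")
  if (any(m$year < 1500 | m$year > 2100, na.rm = TRUE))
    stop("collection years outside [1500, 2100]")
  if (any(m$era == "herbarium") && any(m$era == "modern") &&
      max(m$year[m$era == "herbarium"]) > max(m$year[m$era == "modern"]))
    warning("some herbarium samples postdate the newest modern sample")
  class(m) <- c("sample_meta", "data.frame")
  m
}

#' Read a phenotype table
#'
#' Tab-separated columns `sample_id`, `trait`, `replicate`, `value`.  Every
#' sample id must be present in the metadata.
#'
#' @param path file path
#' @param meta optional `sample_meta` used to validate ids
#' @export
read_phenotypes <- function(path, meta = NULL) {
  p <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "trait", "replicate", "value")
  if (!all(need %in% names(p)))
    stop("phenotype table must have columns: ", paste(need, collapse = ", "))
  if (!is.null(meta)) {
    unknown <- setdiff(unique(p$sample_id), meta$sample_id)
    if (length(unknown))
      stop("phenotyped sample(s) absent from metadata: ",
           paste(utils::head(unknown, 5), collapse = ", "))
  }
  p
}

#' Read haploid/homozygous genotype calls from a VCF
#'
#' Parses a VCF 4.x file (via [VariantAnnotation::readVcf]) holding haploid or
#' homozygous-diploid genotypes of a selfing lineage against its
#' pseudo-reference.  The REF allele is stored as the provisional ancestral
#' allele (the unfolded SFS may later re-orient it), ALT as derived.
#'
#' @param path VCF file path
#' @param meta `sample_meta`; every VCF sample must appear here
#' @param accessible_length named numeric with at least `total`; callable
#'   genome size(s) in bp used for all per-site rescaling downstream
#' @param het how to treat heterozygous genotypes: `"fail"` (default: the
#'   lineage is selfing and heterozygotes indicate an upstream problem) or
#'   `"missing"`
#' @return a [variant_table()]
#' @export
read_vcf <- function(path, meta, accessible_length, het = c("fail", "missing")) {
  het <- match.arg(het)
  vcf <- VariantAnnotation::readVcf(path)
  samp <- colnames(vcf)
  unknown <- setdiff(samp, meta$sample_id)
  if (length(unknown))
    stop("VCF sample(s) not in metadata: ", paste(unknown, collapse = ", "))

  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field")
  code <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  code[gt %in% c("0", "0/0", "0|0")] <- 0L
  code[gt %in% c("1", "1/1", "1|1")] <- 1L
  is_het <- gt %in% c("0/1", "1/0", "0|1", "1|0")
  if (any(is_het)) {
    if (het == "fail") {
      idx <- which(matrix(is_het, nrow(gt)), arr.ind = TRUE)
      stop("heterozygous call(s) in a selfing lineage, e.g. at record ",
           idx[1, 1], " sample ", colnames(gt)[idx[1, 2]],
           "; use het = 'missing' to coerce")
    }
    code[matrix(is_het, nrow(gt))] <- NA_integer_
  }

  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- as.character(unlist(VariantAnnotation::alt(vcf)))
  info <- VariantAnnotation::info(vcf)
  cls <- if ("ANN" %in% names(info)) as.character(info$ANN) else
    rep("other", nrow(gt))
  cls[is.na(cls) | !cls %in% ANNOTATION_CLASSES] <- "other"
  sites <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ancestral = as.character(VariantAnnotation::ref(vcf)),
    derived = alt,
    class = cls,
    stringsAsFactors = FALSE)
  variant_table(sites, code, accessible_length)
}

#' Write a variant table to VCF
#'
#' Emits a minimal VCF 4.2 with haploid GT calls and the per-site annotation
#' class in `INFO/ANN`.  Round-trips bit-exactly through [read_vcf()].
#'
#' @param v a `variant_table`
#' @param path output path
#' @export
write_vcf <- function(v, path) {
  s <- v$sites
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=clonalclock",
    paste0("##contig=<ID=", unique(s$chrom), ">"),
    "##INFO=<ID=ANN,Number=1,Type=String,Description=\"Annotation class\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(v$calls)), collapse = "\t")), con)
  if (nrow(s)) {
    gt <- matrix(as.character(v$calls), nrow(s))
    gt[is.na(gt)] <- "."
    body <- paste(s$chrom, s$pos, ".", s$ancestral, s$derived, ".", "PASS",
                  paste0("ANN=", s$class), "GT",
                  apply(gt, 1, paste, collapse = "\t"), sep = "\t")
    writeLines(body, con)
  }
  invisible(path)
}

#' Write a variant table, metadata and truth bundle to a directory
#' @param v variant_table
#' @param meta sample_meta
#' @param dir output directory
#' @param truth optional simulation truth list, serialized to JSON
#' @export
write_dataset <- function(v, meta, dir, truth = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_vcf(v, file.path(dir, "calls.vcf"))
  utils::write.table(meta, file.path(dir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(truth))
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

## derived-allele count per sample over non-missing calls
derived_counts <- function(v) colSums(v$calls == 1L, na.rm = TRUE)

## non-missing call count per sample
callable_counts <- function(v) colSums(!is.na(v$calls))

## derived-allele frequency per site over non-missing calls
site_frequencies <- function(v) {
  n <- rowSums(!is.na(v$calls))
  k <- rowSums(v$calls == 1L, na.rm = TRUE)
  ifelse(n > 0, k / n, NA_real_)
}
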