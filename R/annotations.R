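#' Read genome annotation intervals
#'
#' Loads annotation intervals from GFF3 (1-based, closed) or BED (0-based,
#' half-open; converted on read) and resolves them into one non-overlapping
#' interval set per annotation class.  Overlaps between classes are resolved
#' by a fixed precedence, coding first:
#' coding > utr5 > utr3 > intronic > transposon > pseudogene > intergenic.
#'
#' GFF3 feature types are mapped to classes as follows: `CDS` and `exon` to
#' `coding`; `five_prime_UTR`/`three_prime_UTR` to `utr5`/`utr3`; `intron` to
#' `intronic`; `transposable_element`, `transposon` and
#' `transposable_element_gene` to `transposon`; `pseudogene` to `pseudogene`.
#' `gene`/`mRNA` records are not classes themselves: the part of a gene not
#' covered by exon/CDS/UTR intervals is derived as `intronic`.  Unknown
#' feature types (or BED name labels) become `other` with a warning.  For BED
#' input the 4th (name) column is the class label.
#'
#' @param path file path
#' @param dialect `"gff3"` or `"bed"`
#' @return an `annotation_map`: list with `intervals` (a
#'   [GenomicRanges::GRanges] with a `class` metadata column, disjoint after
#'   precedence) and `class_lengths` (named numeric, union bp per class)
#' @export
read_annotations <- function(path, dialect = c("gff3", "bed")) {
  dialect <- match.arg(dialect)
  empty <- !file.exists(path) || file.size(path) == 0 ||
    !length(grep("^[^#]", readLines(path, warn = FALSE), value = TRUE))
  if (empty) {
    return(annotation_map(GenomicRanges::GRanges(class = character(0))))
  }
  gr <- rtracklayer::import(path,
                            format = if (dialect == "gff3") "gff3" else "bed")
  if (any(GenomicRanges::end(gr) < GenomicRanges::start(gr)))
    stop("annotation interval with end < start")

  if (dialect == "bed") {
    lab <- gr$name
    if (is.null(lab)) lab <- rep("other", length(gr))
  } else {
    type <- as.character(gr$type)
    map <- c(CDS = "coding", exon = "coding",
             five_prime_UTR = "utr5", three_prime_UTR = "utr3",
             intron = "intronic",
             transposable_element = "transposon",
             transposable_element_gene = "transposon",
             transposon = "transposon",
             pseudogene = "pseudogene", intergenic = "intergenic")
    lab <- unname(map[type])
    ## genes minus their exonic/UTR parts are introns
    is_gene <- type %in% c("gene", "mRNA")
    if (any(is_gene)) {
      covered <- GenomicRanges::reduce(
        gr[!is.na(lab) & lab %in% c("coding", "utr5", "utr3")])
      introns <- GenomicRanges::setdiff(
        GenomicRanges::reduce(gr[is_gene]), covered)
    } else introns <- GenomicRanges::GRanges()
    unknown <- is.na(lab) & !is_gene
    if (any(unknown)) {
      warning("unknown feature type(s) classified as 'other': ",
              paste(unique(type[unknown]), collapse = ", "))
      lab[unknown] <- "other"
    }
    lab[is_gene] <- NA  # container records, dropped below
    keep <- !is.na(lab)
    base <- GenomicRanges::granges(gr[keep], use.mcols = FALSE)
    labs <- lab[keep]
    if (length(introns)) {
      base <- c(base, GenomicRanges::granges(introns, use.mcols = FALSE))
      labs <- c(labs, rep("intronic", length(introns)))
    }
    base$class <- labs
    return(annotation_map(base))
  }
  bad <- !lab %in% ANNOTATION_CLASSES
  if (any(bad)) {
    warning("unknown class label(s) mapped to 'other': ",
            paste(unique(lab[bad]), collapse = ", "))
    lab[bad] <- "other"
  }
  gr2 <- GenomicRanges::granges(gr, use.mcols = FALSE)
  gr2$class <- lab
  annotation_map(gr2)
}

#' Build an annotation map from a GRanges with a `class` column
#'
#' Applies the class precedence (see [read_annotations()]) so that the stored
#' intervals are disjoint, and computes union lengths per class.
#' @param gr GRanges with metadata column `class`
#' @export
annotation_map <- function(gr) {
  prec <- setdiff(ANNOTATION_CLASSES, "other")
  prec <- c(prec, "other")
  out <- GenomicRanges::GRanges(class = character(0))
  taken <- GenomicRanges::GRanges()
  lens <- setNames(numeric(length(ANNOTATION_CLASSES)), ANNOTATION_CLASSES)
  for (cl in prec) {
    g <- GenomicRanges::reduce(gr[!is.na(gr$class) & gr$class == cl])
    g <- GenomicRanges::setdiff(g, taken)
    if (length(g)) {
      g$class <- cl
      out <- c(out, g)
      taken <- GenomicRanges::reduce(c(taken, GenomicRanges::granges(g)))
      lens[[cl]] <- sum(GenomicRanges::width(g))
    }
  }
  structure(list(intervals = sort(out), class_lengths = lens),
            class = "annotation_map")
}

#' @export
print.annotation_map <- function(x, ...) {
  cat("annotation_map:", length(x$intervals), "disjoint intervals\n")
  nz <- x$class_lengths[x$class_lengths > 0]
  if (length(nz))
    cat(paste(names(nz), format(nz, big.mark = ","), sep = ": ",
              collapse = "; "), "\n")
  invisible(x)
}

#' Assign an annotation class to every variant site
#'
#' Each site receives exactly one class by interval lookup in the
#' precedence-resolved map.  Sites outside any interval, or on chromosomes the
#' map does not cover, default to `intergenic` (the non-coding complement).
#'
#' @param v a [variant_table()]
#' @param a an `annotation_map`
#' @return the variant table with `sites$class` replaced
#' @export
classify_sites <- function(v, a) {
  if (!n_sites(v)) return(v)
  iv <- a$intervals
  covered_chr <- unique(as.character(GenomicRanges::seqnames(iv)))
  missing_chr <- setdiff(unique(v$sites$chrom), covered_chr)
  if (length(missing_chr))
    warning("chromosome(s) absent from annotation, sites set intergenic: ",
            paste(missing_chr, collapse = ", "))
  pos <- GenomicRanges::GRanges(v$sites$chrom,
                                IRanges::IRanges(v$sites$pos, v$sites$pos))
  cls <- rep("intergenic", n_sites(v))
  if (length(iv)) {
    ## seqlevel mismatch is handled above (intergenic default), so the
    ## GenomicRanges no-common-levels warning is redundant here
    hit <- suppressWarnings(
      GenomicRanges::findOverlaps(pos, iv, select = "first"))
    ok <- !is.na(hit)
    cls[ok] <- iv$class[hit[ok]]
  }
  v$sites$class <- cls
  v
}
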