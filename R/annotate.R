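# Candidate-region annotation: gene/QTL interval intersection, gene-desert
# flagging and variant-origin classification against outgroup panels.

#' Intersect candidate regions with gene and QTL interval sets
#'
#' A feature annotates a region iff the two intervals share at least 1 bp
#' (end-exclusive convention: a gene starting exactly at a region's end does
#' not overlap).  Regions overlapping no gene are flagged gene deserts.
#'
#' @param regions a \code{\link{genomic_regions}} data frame.
#' @param genes,qtls \code{\link{interval_set}} data frames.
#' @return data frame with one row per region: comma-separated
#'   \code{genes} and \code{qtls} labels and a \code{gene_desert} flag.
#' @export
intersect_annotations <- function(regions, genes, qtls = interval_set()) {
  if (nrow(regions) && nrow(genes) &&
      !length(intersect(unique(regions$chrom), unique(genes$chrom)))) {
    stop(sprintf("no chromosome label shared between regions (%s) and annotations (%s); check naming",
                 paste(unique(regions$chrom), collapse = ","),
                 paste(unique(genes$chrom), collapse = ",")))
  }
  overlap_labels <- function(iv) {
    labs <- vector("list", nrow(regions))
    for (ch in intersect(unique(regions$chrom), unique(iv$chrom))) {
      ri <- which(regions$chrom == ch); fi <- which(iv$chrom == ch)
      rr <- IRanges::IRanges(regions$start[ri], regions$end[ri] - 1)
      rf <- IRanges::IRanges(iv$start[fi], iv$end[fi] - 1)
      hits <- IRanges::findOverlaps(rr, rf)
      for (h in seq_along(hits)) {
        i <- ri[S4Vectors::queryHits(hits)[h]]
        labs[[i]] <- c(labs[[i]], iv$label[fi[S4Vectors::subjectHits(hits)[h]]])
      }
    }
    labs
  }
  g <- overlap_labels(genes)
  q <- overlap_labels(qtls)
  data.frame(chrom = regions$chrom, start = regions$start, end = regions$end,
             genes = vapply(g, function(x) paste(x, collapse = ","), ""),
             qtls = vapply(q, function(x) paste(x, collapse = ","), ""),
             gene_desert = vapply(g, length, 0L) == 0L,
             stringsAsFactors = FALSE)
}

#' Classify the ancestral origin of variants in an admixed population
#'
#' A variant observed in the admixed population is classified
#' \code{"zebu"} if absent from both taurine outgroup panels,
#' \code{"taurine"} if present in both, and \code{"undefined"} if present in
#' exactly one.  The three classes partition all admixed-set variants.
#'
#' @param p a \code{\link{variant_presence}} table.
#' @return character vector (one class per row of \code{p}); rows absent
#'   from the admixed set raise an error, since origin is only defined for
#'   observed variants.
#' @export
classify_variant_origin <- function(p) {
  if (any(!p$admixed)) {
    stop(sprintf("%d variant(s) absent from the admixed set: origin classification undefined",
                 sum(!p$admixed)))
  }
  ifelse(!p$taurine1 & !p$taurine2, "zebu",
         ifelse(p$taurine1 & p$taurine2, "taurine", "undefined"))
}
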