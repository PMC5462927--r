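# Excess/deficiency of zebu local ancestry (dAZ) at candidate regions.
#
# dAZ at a SNP is the deviation of its mean zebu-ancestry dosage (across
# individuals) from the genome-wide mean over all SNPs; by construction the
# mean dAZ over all SNPs is exactly 0.  Regions whose significant SNPs have
# a median dAZ more than one SD away from 0 are classified as carrying an
# excess or deficiency of zebu ancestry.

#' Per-SNP zebu-ancestry deviation track (dAZ)
#'
#' @param L a \code{\link{local_ancestry_matrix}} of per-SNP, per-individual
#'   zebu-ancestry dosages in [0, 1].
#' @return data frame of class \code{daz_track} with columns \code{chrom},
#'   \code{pos}, \code{mean_dosage}, \code{daz}; the genome-wide grand mean
#'   and the SD of \code{daz} are attached as attributes \code{"grand_mean"}
#'   and \code{"sd_daz"}.
#' @export
delta_az <- function(L) {
  snp_mean <- rowMeans(L$dosage)
  grand <- mean(snp_mean)
  daz <- snp_mean - grand
  out <- data.frame(chrom = L$chrom, pos = L$pos, mean_dosage = snp_mean,
                    daz = daz, stringsAsFactors = FALSE)
  attr(out, "grand_mean") <- grand
  attr(out, "sd_daz") <- pop_sd(daz)
  class(out) <- c("daz_track", "data.frame")
  out
}

#' Median dAZ of a region's significant SNPs
#'
#' @param region single-row region (\code{chrom}, \code{start}, \code{end}).
#' @param track a \code{daz_track} from \code{\link{delta_az}}.
#' @param significant_snps positions (on the region's chromosome) of the
#'   SNPs significant in the meta-analysis; only these contribute.
#' @return the median dAZ (even counts use the mean of the two middle
#'   values), or \code{NA} with a warning when no significant SNP lies in
#'   the region.
#' @export
region_daz <- function(region, track, significant_snps) {
  stopifnot(nrow(region) == 1L)
  inside <- track$chrom == region$chrom &
    track$pos %in% significant_snps &
    track$pos >= region$start & track$pos <= region$end
  if (!any(inside)) {
    warning(sprintf("no significant SNP inside %s:%s-%s; region dAZ undefined",
                    region$chrom, region$start, region$end))
    return(NA_real_)
  }
  stats::median(track$daz[inside])
}

#' Classify a region's ancestry deviation
#'
#' \code{"excess"} if the median dAZ exceeds +1 SD of the per-SNP dAZ
#' distribution, \code{"deficiency"} below -1 SD, otherwise
#' \code{"typical"}.  Boundaries are exclusive: a median of exactly one SD
#' is typical.
#'
#' @param median_daz region median dAZ (from \code{\link{region_daz}}).
#' @param sd_daz genome-wide SD of per-SNP dAZ (attribute of the track).
#' @return one of \code{"excess"}, \code{"deficiency"}, \code{"typical"}.
#' @export
classify_daz <- function(median_daz, sd_daz) {
  stopifnot(sd_daz > 0)
  ifelse(is.na(median_daz), NA_character_,
         ifelse(median_daz > sd_daz, "excess",
                ifelse(median_daz < -sd_daz, "deficiency", "typical")))
}
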