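#' Domain containers
#'
#' Lightweight S3 containers shared by every stage of the scan pipeline.
#' Coordinates are 1-based throughout; a region's \code{size} is defined as
#' \code{end - start}, so \code{end} behaves as an exclusive bound in all
#' interval arithmetic (two regions overlap iff \code{max(starts) <
#' min(ends)}).  BED input/output converts explicitly (see
#' \code{\link{write_regions}}).
#'
#' @name admixscan-datamodel
NULL

#' Construct a diploid genotype matrix
#'
#' Holds per-SNP diploid calls coded as copies of the non-reference (ALT)
#' allele: 0, 1, 2 or \code{NA} for missing.  SNPs are rows, samples columns.
#'
#' @param chrom character vector of per-SNP chromosome labels.
#' @param pos integer vector of 1-based physical positions (bp); must be
#'   strictly increasing within each chromosome.
#' @param geno numeric matrix, SNPs x samples, values in \{0, 1, 2, NA\}.
#' @param samples character vector of unique sample identifiers.
#' @param ref,alt per-SNP allele labels (single nucleotides).
#' @return An object of class \code{genotype_matrix}.
#' @export
genotype_matrix <- function(chrom, pos, geno, samples,
                            ref = rep("A", length(pos)),
                            alt = rep("G", length(pos))) {
  geno <- as.matrix(geno)
  stopifnot(length(chrom) == length(pos), nrow(geno) == length(pos),
            ncol(geno) == length(samples), length(ref) == length(pos),
            length(alt) == length(pos))
  if (anyDuplicated(samples)) stop("sample identifiers must be unique")
  bad <- !(geno %in% c(0, 1, 2) | is.na(geno))
  if (any(bad)) stop("genotype values must be 0, 1, 2 or NA")
  check_sorted_positions(chrom, pos, "genotype")
  dimnames(geno) <- list(NULL, samples)
  structure(list(chrom = as.character(chrom), pos = as.integer(pos),
                 geno = geno, samples = as.character(samples),
                 ref = as.character(ref), alt = as.character(alt)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d SNPs x %d samples on %d chromosome(s)\n",
              length(x$pos), length(x$samples), length(unique(x$chrom))))
  invisible(x)
}

#' Construct a phased, polarized haplotype set
#'
#' The substrate of the EHH statistics: a 2N x S binary matrix with 0 =
#' ancestral and 1 = derived allele.  No missing entries are permitted;
#' failing SNPs must be removed upstream.
#'
#' @param hap binary matrix, haplotypes (2 per sample) x SNPs.
#' @param chrom chromosome label (single chromosome per set).
#' @param pos 1-based physical positions, strictly increasing.
#' @param sample_of_haplotype character vector mapping haplotype row to
#'   sample identifier; each sample must appear exactly twice.
#' @return An object of class \code{haplotype_set}.
#' @export
haplotype_set <- function(hap, chrom, pos, sample_of_haplotype = NULL) {
  hap <- as.matrix(hap)
  stopifnot(ncol(hap) == length(pos))
  if (anyNA(hap)) stop("haplotype_set forbids missing entries")
  if (!all(hap %in% c(0, 1))) stop("haplotypes must be coded 0 (ancestral) / 1 (derived)")
  if (length(chrom) != 1L) stop("a haplotype_set spans a single chromosome")
  check_sorted_positions(rep(chrom, length(pos)), pos, "haplotype")
  if (is.null(sample_of_haplotype)) {
    sample_of_haplotype <- rep(sprintf("S%d", seq_len(nrow(hap) / 2)), each = 2)
  }
  if (length(sample_of_haplotype) != nrow(hap) ||
      any(table(sample_of_haplotype) != 2)) {
    stop("each sample must contribute exactly 2 haplotypes")
  }
  structure(list(hap = hap, chrom = as.character(chrom), pos = as.integer(pos),
                 sample_of_haplotype = as.character(sample_of_haplotype)),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat(sprintf("haplotype_set: %d haplotypes x %d SNPs on %s (%s-%s bp)\n",
              nrow(x$hap), ncol(x$hap), x$chrom,
              format(min(x$pos), big.mark = ","), format(max(x$pos), big.mark = ",")))
  invisible(x)
}

#' Construct a per-SNP scan track
#'
#' One row per SNP carrying the unstandardized statistic, its standardized
#' score and the -log10 p-value of one selection test on one population.
#'
#' @param chrom,pos per-SNP coordinates, sorted by (chrom, pos).
#' @param raw unstandardized statistic (NA where undefined).
#' @param z standardized score.
#' @param neglog_p -log10 p-value (>= 0).
#' @param test_name one of \code{"iHS"}, \code{"Rsb"}, \code{"dAF"},
#'   \code{"metaSS"}, \code{"ZHp"}.
#' @param population free-text population label.
#' @return A data frame of class \code{scan_track}.
#' @export
scan_track <- function(chrom, pos, raw, z, neglog_p,
                       test_name = "unknown", population = "pop") {
  stopifnot(length(pos) == length(chrom), length(raw) == length(pos),
            length(z) == length(pos), length(neglog_p) == length(pos))
  if (any(neglog_p < 0, na.rm = TRUE)) stop("neglog_p must be >= 0")
  if (any(!is.na(raw) & !is.finite(z) & !is.na(z))) stop("z must be finite wherever raw is defined")
  o <- order(chrom, pos)
  out <- data.frame(chrom = as.character(chrom)[o], pos = as.integer(pos)[o],
                    raw = raw[o], z = z[o], neglog_p = neglog_p[o],
                    stringsAsFactors = FALSE)
  attr(out, "test_name") <- test_name
  attr(out, "population") <- population
  class(out) <- c("scan_track", "data.frame")
  out
}

#' Construct a set of candidate genomic regions
#'
#' @param chrom,start,end 1-based interval bounds with \code{start < end};
#'   \code{size = end - start}.
#' @param n_snps number of contributing significant SNPs (or windows).
#' @param score summary score (peak -log10 p, or mean ZHp for sweep regions).
#' @param provenance character label(s) recording test/population origin.
#' @return A data frame of class \code{genomic_region}.
#' @export
genomic_regions <- function(chrom = character(), start = integer(),
                            end = integer(), n_snps = NA_integer_,
                            score = NA_real_, provenance = NA_character_) {
  if (length(chrom) && any(start >= end)) stop("regions require start < end")
  if (!length(chrom)) {
    n_snps <- integer(); score <- numeric(); provenance <- character()
  }
  out <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                    end = as.numeric(end), size = as.numeric(end) - as.numeric(start),
                    n_snps = n_snps, score = score, provenance = provenance,
                    stringsAsFactors = FALSE)
  class(out) <- c("genomic_region", "data.frame")
  out
}

#' Construct pooled-sequencing allele-depth counts
#'
#' Per-site read counts of the most (\code{n_maj}) and least (\code{n_min})
#' frequent allele in a sequenced DNA pool.  Rows violating
#' \code{n_maj >= n_min} are repaired by swapping (with a counter kept in the
#' \code{"n_swapped"} attribute); negative counts are rejected.
#'
#' @param chrom,pos per-site coordinates.
#' @param n_maj,n_min non-negative read counts.
#' @return A data frame of class \code{pooled_counts}.
#' @export
pooled_counts <- function(chrom = character(), pos = integer(),
                          n_maj = integer(), n_min = integer()) {
  stopifnot(length(chrom) == length(pos), length(n_maj) == length(pos),
            length(n_min) == length(pos))
  if (any(n_maj < 0 | n_min < 0)) stop("read counts must be non-negative")
  swap <- n_min > n_maj
  if (any(swap)) {
    tmp <- n_maj[swap]; n_maj[swap] <- n_min[swap]; n_min[swap] <- tmp
  }
  out <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                    n_maj = as.numeric(n_maj), n_min = as.numeric(n_min),
                    stringsAsFactors = FALSE)
  attr(out, "n_swapped") <- sum(swap)
  class(out) <- c("pooled_counts", "data.frame")
  out
}

#' Construct a coverage mask
#'
#' Sorted, non-overlapping covered intervals per chromosome, 1-based start,
#' exclusive end (same convention as \code{genomic_regions}).  The uncovered
#' base count of any window is its length minus its covered overlap.
#'
#' @param chrom,start,end covered intervals.
#' @return A data frame of class \code{coverage_mask}.
#' @export
coverage_mask <- function(chrom = character(), start = integer(), end = integer()) {
  if (length(chrom) && any(start >= end)) stop("mask intervals require start < end")
  o <- order(chrom, start)
  out <- data.frame(chrom = as.character(chrom)[o], start = as.numeric(start)[o],
                    end = as.numeric(end)[o], stringsAsFactors = FALSE)
  for (ch in unique(out$chrom)) {
    m <- out[out$chrom == ch, ]
    if (nrow(m) > 1L && any(m$start[-1L] < m$end[-nrow(m)])) {
      stop(sprintf("mask intervals overlap on chromosome %s", ch))
    }
  }
  class(out) <- c("coverage_mask", "data.frame")
  out
}

#' Construct a local-ancestry dosage matrix
#'
#' Per-SNP, per-individual zebu-ancestry fraction in [0, 1], as produced by
#' an external local-ancestry inference tool (or by the simulator's truth).
#'
#' @param chrom,pos per-SNP coordinates.
#' @param dosage numeric matrix, SNPs x individuals, values in [0, 1].
#' @return An object of class \code{local_ancestry_matrix}.
#' @export
local_ancestry_matrix <- function(chrom, pos, dosage) {
  dosage <- as.matrix(dosage)
  stopifnot(nrow(dosage) == length(pos), length(chrom) == length(pos))
  bad <- which(dosage < 0 | dosage > 1, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("ancestry dosage outside [0,1] at SNP %d, individual %d",
                 bad[1, 1], bad[1, 2]))
  }
  structure(list(chrom = as.character(chrom), pos = as.integer(pos),
                 dosage = dosage),
            class = "local_ancestry_matrix")
}

#' Construct a named interval set (genes or QTL)
#'
#' @param chrom,start,end 1-based intervals, \code{start < end}, exclusive end.
#' @param label feature names.
#' @return A data frame of class \code{interval_set}.
#' @export
interval_set <- function(chrom = character(), start = integer(),
                         end = integer(), label = character()) {
  if (length(chrom) && any(start >= end)) stop("intervals require start < end")
  o <- order(chrom, start)
  out <- data.frame(chrom = as.character(chrom)[o], start = as.numeric(start)[o],
                    end = as.numeric(end)[o], label = as.character(label)[o],
                    stringsAsFactors = FALSE)
  class(out) <- c("interval_set", "data.frame")
  out
}

#' Construct a variant-presence table
#'
#' Presence/absence flags of each variant in the admixed population's
#' sequences and in two outgroup (African taurine) sequence panels; the basis
#' of variant-origin classification.
#'
#' @param chrom,pos,ref,alt variant keys.
#' @param admixed,taurine1,taurine2 logical presence flags.
#' @return A data frame of class \code{variant_presence}.
#' @export
variant_presence <- function(chrom, pos, ref, alt, admixed, taurine1, taurine2) {
  out <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                    ref = as.character(ref), alt = as.character(alt),
                    admixed = as.logical(admixed), taurine1 = as.logical(taurine1),
                    taurine2 = as.logical(taurine2), stringsAsFactors = FALSE)
  if (any(!out$admixed & !out$taurine1 & !out$taurine2)) {
    stop("every variant must be present in at least one set")
  }
  class(out) <- c("variant_presence", "data.frame")
  out
}
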