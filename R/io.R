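# Readers and writers for the standard formats the pipeline touches.
# Internal coordinates are 1-based with size = end - start; BED conversion is
# start_bed = start - 1, end_bed = end.

#' Read phased or unphased genotypes from a VCF
#'
#' Parses a VCF 4.x file into a \code{\link{genotype_matrix}} and, when all
#' calls are phased (pipe-separated) and complete, additionally into one
#' \code{\link{haplotype_set}} per chromosome with alleles recoded
#' 0 = ancestral / 1 = derived using an ancestral-allele table.
#'
#' SNPs whose ancestral allele is absent from the table, or matches neither
#' observed allele, are flagged unpolarized and excluded from the haplotype
#' sets (and hence from iHS downstream).
#'
#' @param vcf_path path to a VCF (optionally bgzipped).
#' @param ancestral_table_path optional path to a tab-separated table with
#'   columns \code{CHROM}, \code{POS}, \code{ANCESTRAL}; see
#'   \code{\link{read_ancestral_table}}.
#' @return A list with elements \code{genotypes} (a
#'   \code{genotype_matrix}), \code{haplotypes} (named list of
#'   \code{haplotype_set}, or \code{NULL} if the VCF is unphased), and
#'   \code{unpolarized} (logical per-SNP flag).
#' @export
read_genotypes <- function(vcf_path, ancestral_table_path = NULL) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  chrom <- as.character(fix[, "CHROM"])
  pos <- as.integer(fix[, "POS"])
  check_sorted_positions(chrom, pos, "VCF")
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)

  phased <- all(grepl("\\|", gt) | gt %in% c(".", "./.", ".|."), na.rm = TRUE) &&
    !anyNA(gt) && !any(gt %in% c(".", "./.", ".|."))
  a1 <- matrix(suppressWarnings(as.integer(substr(gt, 1, 1))), nrow = nrow(gt))
  a2 <- matrix(suppressWarnings(as.integer(substr(gt, 3, 3))), nrow = nrow(gt))
  geno <- matrix(a1 + a2, nrow = nrow(gt), dimnames = list(NULL, samples))

  G <- genotype_matrix(chrom, pos, geno, samples,
                       ref = as.character(fix[, "REF"]),
                       alt = as.character(fix[, "ALT"]))

  unpolarized <- rep(TRUE, length(pos))
  haps <- NULL
  if (!is.null(ancestral_table_path)) {
    anc <- read_ancestral_table(ancestral_table_path)
    key <- paste(chrom, pos)
    m <- match(key, paste(anc$chrom, anc$pos))
    ancestral <- anc$ancestral[m]
    ok <- !is.na(ancestral) & (ancestral == G$ref | ancestral == G$alt)
    mismatch <- !is.na(ancestral) & !ok
    if (any(mismatch)) {
      warning(sprintf("%d SNP(s) with ancestral allele matching neither REF nor ALT; flagged unpolarized",
                      sum(mismatch)))
    }
    unpolarized <- !ok
    if (phased) {
      haps <- lapply(unique(chrom), function(ch) {
        sel <- which(chrom == ch & !unpolarized)
        if (!length(sel)) return(NULL)
        h <- matrix(0L, nrow = 2 * length(samples), ncol = length(sel))
        h[seq(1, nrow(h), by = 2), ] <- t(a1[sel, , drop = FALSE])
        h[seq(2, nrow(h), by = 2), ] <- t(a2[sel, , drop = FALSE])
        # polarize: where ancestral == ALT, derived is REF, so flip codes
        flip <- ancestral[sel] == G$alt[sel]
        h[, flip] <- 1L - h[, flip]
        haplotype_set(h, ch, pos[sel],
                      sample_of_haplotype = rep(samples, each = 2))
      })
      names(haps) <- unique(chrom)
      haps <- Filter(Negate(is.null), haps)
    }
  } else if (phased) {
    haps <- NULL  # phased but unpolarizable: no ancestral states supplied
  }

  list(genotypes = G, haplotypes = haps, unpolarized = unpolarized)
}

#' Read an ancestral-allele table
#'
#' Tab-separated file with header columns \code{CHROM}, \code{POS},
#' \code{ANCESTRAL} (case-insensitive).  Only SNPs with a fixed ancestral
#' state in the outgroup species belong in this table; joins to genotypes are
#' by exact (chrom, pos).
#'
#' @param path file path.
#' @return data frame with columns \code{chrom}, \code{pos}, \code{ancestral}.
#' @export
read_ancestral_table <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(x) <- tolower(names(x))
  need <- c("chrom", "pos", "ancestral")
  if (!all(need %in% names(x))) {
    stop("ancestral table requires columns CHROM, POS, ANCESTRAL")
  }
  data.frame(chrom = as.character(x$chrom), pos = as.integer(x$pos),
             ancestral = toupper(as.character(x$ancestral)),
             stringsAsFactors = FALSE)
}

#' Write genotypes (or phased haplotypes) to a VCF
#'
#' A minimal VCF 4.2 writer.  For a \code{genotype_matrix}, diploid calls are
#' written unphased (\code{0/0}, \code{0/1}, \code{1/1}, \code{./.}).  For a
#' \code{haplotype_set}, calls are written phased with REF set to the
#' ancestral allele label, so that re-reading with a matching ancestral table
#' reproduces the 0/1 coding exactly.
#'
#' @param x a \code{genotype_matrix} or \code{haplotype_set}.
#' @param path output file path (plain text).
#' @return \code{path}, invisibly.
#' @export
write_vcf <- function(x, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  if (inherits(x, "genotype_matrix")) {
    gt_str <- matrix(c("0/0", "0/1", "1/1")[x$geno + 1L], nrow = nrow(x$geno))
    gt_str[is.na(x$geno)] <- "./."
    body <- paste(x$chrom, x$pos, ".", x$ref, x$alt, ".", "PASS", ".", "GT",
                  apply(gt_str, 1L, paste, collapse = "\t"), sep = "\t")
    samples <- x$samples
  } else if (inherits(x, "haplotype_set")) {
    samples <- unique(x$sample_of_haplotype)
    n <- length(samples)
    h1 <- x$hap[seq(1, 2 * n, by = 2), , drop = FALSE]
    h2 <- x$hap[seq(2, 2 * n, by = 2), , drop = FALSE]
    gt_str <- matrix(paste(t(h1), t(h2), sep = "|"), nrow = ncol(x$hap))
    body <- paste(x$chrom, x$pos, ".", "A", "G", ".", "PASS", ".", "GT",
                  apply(gt_str, 1L, paste, collapse = "\t"), sep = "\t")
  } else {
    stop("write_vcf handles genotype_matrix or haplotype_set objects")
  }
  head_line <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t")
  writeLines(c(hdr, head_line, body), path)
  invisible(path)
}

#' Read pooled allele-depth counts
#'
#' Tab-separated file with header \code{CHROM}, \code{POS}, \code{N_MAJ},
#' \code{N_MIN}.  Rows violating \code{n_maj >= n_min} are auto-swapped and
#' counted (attribute \code{"n_swapped"}); rows with negative counts are
#' rejected and counted (attribute \code{"n_rejected"}).  An empty file
#' yields an empty \code{pooled_counts} without error.
#'
#' @param path file path.
#' @return A \code{\link{pooled_counts}} object.
#' @export
read_pooled_counts <- function(path) {
  x <- tryCatch(utils::read.delim(path, stringsAsFactors = FALSE),
                error = function(e) NULL)
  if (is.null(x) || nrow(x) == 0L) {
    out <- pooled_counts()
    attr(out, "n_rejected") <- 0L
    return(out)
  }
  names(x) <- tolower(names(x))
  need <- c("chrom", "pos", "n_maj", "n_min")
  if (!all(need %in% names(x))) {
    stop("pooled counts require columns CHROM, POS, N_MAJ, N_MIN")
  }
  bad <- x$n_maj < 0 | x$n_min < 0
  if (any(bad)) {
    warning(sprintf("%d row(s) with negative counts rejected", sum(bad)))
    x <- x[!bad, , drop = FALSE]
  }
  out <- pooled_counts(x$chrom, x$pos, x$n_maj, x$n_min)
  attr(out, "n_rejected") <- sum(bad)
  out
}

#' Write regions to BED / read intervals from BED
#'
#' Internal 1-based coordinates convert to BED's 0-based half-open system as
#' \code{start_bed = start - 1}, \code{end_bed = end}; reading inverts this
#' exactly, so \code{read_intervals(write_regions(x))} reproduces \code{x}'s
#' coordinates.
#'
#' @param regions a \code{genomic_region} or \code{interval_set} data frame.
#' @param path output BED path.
#' @return \code{path}, invisibly.
#' @export
write_regions <- function(regions, path) {
  label <- if ("label" %in% names(regions)) regions$label else
    if ("provenance" %in% names(regions)) regions$provenance else "."
  lines <- sprintf("%s\t%d\t%d\t%s", regions$chrom,
                   as.integer(regions$start) - 1L, as.integer(regions$end),
                   ifelse(is.na(label), ".", label))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_regions
#' @param bed_path input BED (3 or 6 column) path.
#' @export
read_intervals <- function(bed_path) {
  lines <- readLines(bed_path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (!length(lines)) return(interval_set())
  parts <- strsplit(lines, "\t")
  n <- vapply(parts, length, 0L)
  if (any(n < 3L)) {
    stop(sprintf("malformed BED line %d: fewer than 3 fields", which(n < 3L)[1L]))
  }
  s <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
  e <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 3L)))
  bad <- is.na(s) | is.na(e) | e <= s
  if (any(bad)) {
    stop(sprintf("malformed BED line %d: end <= start or non-numeric coordinates",
                 which(bad)[1L]))
  }
  lab <- vapply(parts, function(p) if (length(p) >= 4L) p[4L] else ".", "")
  interval_set(vapply(parts, `[`, "", 1L), s + 1, e, lab)
}

#' Read a coverage mask from BED
#'
#' Covered intervals of a pooled-sequencing experiment, used to extend Hp
#' windows by their uncovered base count.
#'
#' @param bed_path input BED path.
#' @return A \code{\link{coverage_mask}} object.
#' @export
read_coverage_mask <- function(bed_path) {
  iv <- read_intervals(bed_path)
  coverage_mask(iv$chrom, iv$start, iv$end)
}

#' Read a local-ancestry dosage table
#'
#' Tab-separated file with header \code{CHROM}, \code{POS}, then one column
#' per individual holding zebu-ancestry dosages in [0, 1] (the per-SNP output
#' format of local-ancestry inference tools).
#'
#' @param path file path.
#' @return A \code{\link{local_ancestry_matrix}}.
#' @export
read_local_ancestry <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  names(x)[1:2] <- tolower(names(x)[1:2])
  if (!all(c("chrom", "pos") %in% names(x)[1:2])) {
    stop("local-ancestry table requires leading columns CHROM, POS")
  }
  local_ancestry_matrix(x$chrom, x$pos, as.matrix(x[, -(1:2), drop = FALSE]))
}
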