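# SNP- and sample-level quality control for BeadChip-style genotype panels.

#' SNP-level quality filters
#'
#' Removes SNPs with minor allele frequency strictly below \code{maf_min} or
#' call rate strictly below \code{callrate_min}.  Boundary values are
#' retained (a SNP with MAF exactly 0.05 passes).  MAF is computed over
#' non-missing calls; a SNP with all calls missing counts as a call-rate
#' failure only (its MAF is undefined).
#'
#' @param G a \code{\link{genotype_matrix}}.
#' @param maf_min minimum minor allele frequency retained (default 0.05).
#' @param callrate_min minimum per-SNP call rate retained (default 0.95).
#' @return list with the filtered \code{genotype_matrix} and a
#'   \code{qc_report} whose counters satisfy
#'   \code{n_snps_out = n_snps_in - (n_removed_maf + n_removed_callrate -
#'   n_removed_both)}.
#' @export
snp_filters <- function(G, maf_min = 0.05, callrate_min = 0.95) {
  n_called <- rowSums(!is.na(G$geno))
  callrate <- n_called / ncol(G$geno)
  af <- rowSums(G$geno, na.rm = TRUE) / (2 * n_called)
  maf <- pmin(af, 1 - af)
  fail_cr <- callrate < callrate_min
  fail_maf <- !is.na(maf) & n_called > 0 & maf < maf_min
  drop <- fail_cr | fail_maf
  rep <- qc_report(n_snps_in = length(G$pos),
                  n_removed_maf = sum(fail_maf),
                  n_removed_callrate = sum(fail_cr),
                  n_removed_both = sum(fail_maf & fail_cr),
                  n_snps_out = sum(!drop))
  G2 <- genotype_matrix(G$chrom[!drop], G$pos[!drop],
                        G$geno[!drop, , drop = FALSE], G$samples,
                        G$ref[!drop], G$alt[!drop])
  list(genotypes = G2, report = rep)
}

qc_report <- function(n_snps_in = 0L, n_removed_maf = 0L, n_removed_callrate = 0L,
                      n_removed_both = 0L, n_snps_out = 0L,
                      n_samples_removed_callrate = 0L, n_samples_removed_ibs = 0L,
                      removed_sample_ids = character()) {
  stopifnot(n_snps_out == n_snps_in - (n_removed_maf + n_removed_callrate - n_removed_both))
  structure(list(n_snps_in = n_snps_in, n_removed_maf = n_removed_maf,
                 n_removed_callrate = n_removed_callrate,
                 n_removed_both = n_removed_both, n_snps_out = n_snps_out,
                 n_samples_removed_callrate = n_samples_removed_callrate,
                 n_samples_removed_ibs = n_samples_removed_ibs,
                 removed_sample_ids = removed_sample_ids),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC: %d SNPs in, %d out (MAF %d, call rate %d, both %d); samples removed: %d call rate, %d IBS\n",
              x$n_snps_in, x$n_snps_out, x$n_removed_maf, x$n_removed_callrate,
              x$n_removed_both, x$n_samples_removed_callrate, x$n_samples_removed_ibs))
  invisible(x)
}

#' Pairwise identity-by-state between two diploid genotype vectors
#'
#' IBS is the mean, over SNPs non-missing in both samples, of
#' \code{(2 - |g_i - g_j|) / 2} with genotypes coded 0/1/2.
#'
#' @param g_i,g_j numeric genotype vectors (0, 1, 2, NA).
#' @return fraction in [0, 1], or \code{NA} (with a warning) if no SNP is
#'   non-missing in both.
#' @export
pairwise_ibs <- function(g_i, g_j) {
  ok <- !is.na(g_i) & !is.na(g_j)
  if (!any(ok)) {
    warning("no shared non-missing SNPs; IBS undefined")
    return(NA_real_)
  }
  mean((2 - abs(g_i[ok] - g_j[ok])) / 2)
}

#' Sample-level quality filters
#'
#' Removes samples with call rate strictly below \code{callrate_min}, then
#' resolves pairs with IBS above \code{ibs_max} among the remaining samples:
#' pairs are processed greedily by descending IBS, removing the lower
#' call-rate member of each offending pair (ties broken by removing the
#' later sample in input order).
#'
#' @param G a \code{\link{genotype_matrix}}.
#' @param callrate_min minimum sample call rate retained (default 0.95).
#' @param ibs_max maximum pairwise IBS tolerated (default 0.95; strictly
#'   greater triggers removal).
#' @return list with the filtered \code{genotype_matrix} and a
#'   \code{qc_report}.
#' @export
sample_filters <- function(G, callrate_min = 0.95, ibs_max = 0.95) {
  cr <- colSums(!is.na(G$geno)) / nrow(G$geno)
  drop_cr <- cr < callrate_min
  keep <- which(!drop_cr)
  removed_ids <- G$samples[drop_cr]

  # all-pairs IBS among survivors, resolved greedily by descending IBS
  drop_ibs <- character()
  if (length(keep) > 1L) {
    pairs <- utils::combn(keep, 2L)
    ibs <- apply(pairs, 2L, function(ij) pairwise_ibs(G$geno[, ij[1L]], G$geno[, ij[2L]]))
    active <- rep(TRUE, length(keep))
    names(active) <- as.character(keep)
    for (o in order(-ibs)) {
      if (is.na(ibs[o]) || ibs[o] <= ibs_max) break
      i <- pairs[1L, o]; j <- pairs[2L, o]
      if (!active[as.character(i)] || !active[as.character(j)]) next
      victim <- if (cr[i] < cr[j]) i else if (cr[j] < cr[i]) j else max(i, j)
      active[as.character(victim)] <- FALSE
      drop_ibs <- c(drop_ibs, G$samples[victim])
    }
    keep <- keep[active]
  }

  rep <- qc_report(n_snps_in = length(G$pos), n_snps_out = length(G$pos),
                  n_samples_removed_callrate = sum(drop_cr),
                  n_samples_removed_ibs = length(drop_ibs),
                  removed_sample_ids = c(removed_ids, drop_ibs))
  G2 <- genotype_matrix(G$chrom, G$pos, G$geno[, keep, drop = FALSE],
                        G$samples[keep], G$ref, G$alt)
  list(genotypes = G2, report = rep)
}
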