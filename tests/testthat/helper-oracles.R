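# Independent brute-force oracles and small fixture builders used across the
# suite.  Each oracle is a direct transcription of the defining formula,
# deliberately naive, and shares no code with the implementation it checks.

# EHH by literal pair counting: fraction of carrier pairs identical over
# every SNP strictly between (and including) focal and target index.
bf_ehh <- function(hap, focal, target, allele) {
  carriers <- which(hap[, focal] == allele)
  n <- length(carriers)
  if (n < 2) return(NA_real_)
  span <- seq(min(focal, target), max(focal, target))
  same <- 0L
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (all(hap[carriers[i], span] == hap[carriers[j], span])) same <- same + 1L
    }
  }
  same / (n * (n - 1) / 2)
}

# Allele-agnostic site version (all haplotypes, identity includes the focal).
bf_ehhs <- function(hap, focal, target) {
  n <- nrow(hap)
  span <- seq(min(focal, target), max(focal, target))
  same <- 0L
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (all(hap[i, span] == hap[j, span])) same <- same + 1L
    }
  }
  same / (n * (n - 1) / 2)
}

# Exhaustive region caller: walks significant SNPs one by one, opening a new
# cluster at every gap violation, then filters by cluster size.
bf_call_regions <- function(pos, neglog_p, threshold = 4, min_snps = 5,
                            max_gap = 5e5) {
  sig <- pos[!is.na(neglog_p) & neglog_p >= threshold]
  if (!length(sig)) return(data.frame(start = numeric(), end = numeric(), n = integer()))
  clusters <- list(sig[1])
  for (p in sig[-1]) {
    last <- clusters[[length(clusters)]]
    if (p - last[length(last)] <= max_gap) {
      clusters[[length(clusters)]] <- c(last, p)
    } else {
      clusters[[length(clusters) + 1]] <- p
    }
  }
  keep <- Filter(function(cl) length(cl) >= min_snps, clusters)
  data.frame(start = vapply(keep, min, 0), end = vapply(keep, max, 0),
             n = vapply(keep, length, 0L))
}

# All-pairs interval overlap with the end-exclusive convention.
bf_overlap_pairs <- function(a, b) {
  out <- NULL
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] == b$chrom[j] &&
          max(a$start[i], b$start[j]) < min(a$end[i], b$end[j])) {
        out <- rbind(out, c(i, j))
      }
    }
  }
  out
}

# One-pass mean / SD (sample) z-standardization oracle.
bf_standardize <- function(x) {
  n <- length(x)
  s1 <- sum(x); s2 <- sum(x^2)
  m <- s1 / n
  sd1 <- sqrt((s2 - n * m^2) / (n - 1))
  (x - m) / sd1
}

# Hudson's two-population FST estimator from true allele frequencies.
bf_hudson_fst <- function(p1, p2) {
  num <- (p1 - p2)^2
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  mean(num) / mean(den)
}

# Random small haplotype fixture.
random_hapset <- function(n_hap = 8, n_snp = 12, seed = 1, spacing = 1000) {
  set.seed(seed)
  hap <- matrix(rbinom(n_hap * n_snp, 1, runif(1, 0.3, 0.7)), nrow = n_hap)
  haplotype_set(hap, "1", seq(spacing, by = spacing, length.out = n_snp))
}

# Phased two-sample VCF text written to a temp file; returns the path.
write_phased_vcf_fixture <- function(path, chrom, pos, ref, alt, gt) {
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", paste0("s", seq_len(ncol(gt)))),
                   collapse = "\t"))
  for (i in seq_along(pos)) {
    lines <- c(lines, paste(c(chrom[i], pos[i], ".", ref[i], alt[i], ".",
                              "PASS", ".", "GT", gt[i, ]), collapse = "\t"))
  }
  writeLines(lines, path)
  path
}

write_ancestral_fixture <- function(path, chrom, pos, ancestral) {
  writeLines(c("CHROM\tPOS\tANCESTRAL",
               paste(chrom, pos, ancestral, sep = "\t")), path)
  path
}
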