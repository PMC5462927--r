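# Synthetic-data generators: two diverged ancestral populations, admixed
# haplotypes with Markov ancestry tracts, planted selective sweeps, and
# pooled short-read sampling with coverage gaps.  Every generator is
# deterministic under the configuration seed.
#
# The sweep generator copies one carrier haplotype over a chosen tract into
# a fraction of the population.  This is a haplotype-copying emulation, not
# a forward population-genetic simulation: it produces exactly the long
# shared haplotype / depressed heterozygosity signal the detectors target,
# orders of magnitude faster than a coalescent or forward simulator.

#' Simulation configuration
#'
#' @param n_snps number of SNPs on the synthetic chromosome.
#' @param n_ind diploid individuals per population.
#' @param fst divergence between the two ancestral populations
#'   (Balding-Nichols model).
#' @param alpha zebu admixture proportion (stationary ancestry probability).
#' @param generations generations since admixture began (drives ancestry
#'   tract lengths).
#' @param recomb recombination rate per bp per generation; the default
#'   1e-8 corresponds to a uniform 1 cM = 1 Mb map.
#' @param chrom_length synthetic chromosome length in bp.
#' @param depth mean pooled-sequencing depth of coverage per site.
#' @param gap_fraction fraction of the chromosome left uncovered by the
#'   simulated sequencing.
#' @param sweep optional sweep specification: list with \code{locus} (SNP
#'   index), \code{final_freq} and \code{length_bp}.
#' @param seed mandatory RNG seed; every generator derives its stream from
#'   it, so outputs are bit-identical across runs.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(n_snps = 5000, n_ind = 50, fst = 0.1, alpha = 0.7,
                       generations = 500, recomb = 1e-8, chrom_length = 1e7,
                       depth = 11, gap_fraction = 0.05, sweep = NULL, seed) {
  if (missing(seed)) stop("a seed is mandatory: the generators have no nondeterministic defaults")
  stopifnot(fst > 0, fst < 1, alpha >= 0, alpha <= 1,
            gap_fraction >= 0, gap_fraction < 1, depth > 0)
  structure(list(n_snps = n_snps, n_ind = n_ind, fst = fst, alpha = alpha,
                 generations = generations, recomb = recomb,
                 chrom_length = chrom_length, depth = depth,
                 gap_fraction = gap_fraction, sweep = sweep,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate diverged ancestral allele frequencies
#'
#' Balding-Nichols divergence model: a shared ancestral frequency
#' \code{p ~ U(0.05, 0.95)} per SNP, and per-population frequencies drawn
#' from \code{Beta(p(1-F)/F, (1-p)(1-F)/F)}, which has mean p and variance
#' \code{F p (1-p)}.  SNP positions are drawn uniformly (without
#' replacement) along the chromosome.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @param seed RNG seed (defaults to \code{cfg$seed}).
#' @return list with \code{pos} (sorted positions), \code{p_anc},
#'   \code{p_zebu}, \code{p_taurine} (allele-1 frequency vectors).
#' @export
simulate_ancestral_freqs <- function(cfg, seed = cfg$seed) {
  set.seed(seed)
  pos <- sort(sample.int(cfg$chrom_length, cfg$n_snps))
  p <- stats::runif(cfg$n_snps, 0.05, 0.95)
  f <- cfg$fst
  draw <- function() stats::rbeta(cfg$n_snps, p * (1 - f) / f, (1 - p) * (1 - f) / f)
  list(pos = pos, p_anc = p, p_zebu = draw(), p_taurine = draw())
}

#' Simulate admixed haplotypes with Markov ancestry tracts
#'
#' Each haplotype is a Markov path over \{zebu, taurine\} with stationary
#' zebu probability \code{alpha}: between adjacent SNPs at distance d, the
#' ancestry is redrawn from the stationary distribution with probability
#' \code{1 - exp(-g * r * d)} and copied otherwise.  Alleles are drawn from
#' the tract ancestry's population frequency; allele 1 is treated as the
#' derived allele.  The per-individual truth dosage (mean of the two
#' haplotype ancestry indicators) is returned alongside.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @param freqs output of \code{\link{simulate_ancestral_freqs}}.
#' @param seed RNG seed (defaults to \code{cfg$seed + 1}).
#' @param chrom chromosome label for the output set.
#' @return list with \code{haplotypes} (a \code{\link{haplotype_set}}) and
#'   \code{ancestry} (a \code{\link{local_ancestry_matrix}} of truth
#'   dosages).
#' @export
simulate_admixed <- function(cfg, freqs, seed = cfg$seed + 1L, chrom = "1") {
  set.seed(seed)
  S <- cfg$n_snps
  nh <- 2L * cfg$n_ind
  d <- diff(freqs$pos)
  p_switch <- 1 - exp(-cfg$generations * cfg$recomb * d)
  hap <- matrix(0L, nrow = nh, ncol = S)
  anc <- matrix(0L, nrow = nh, ncol = S)
  for (h in seq_len(nh)) {
    redraw <- c(TRUE, stats::runif(S - 1) < p_switch)
    seg <- cumsum(redraw)
    is_zebu <- stats::runif(max(seg)) < cfg$alpha
    a <- is_zebu[seg]
    frq <- ifelse(a, freqs$p_zebu, freqs$p_taurine)
    hap[h, ] <- as.integer(stats::runif(S) < frq)
    anc[h, ] <- as.integer(a)
  }
  samples <- sprintf("ind%03d", seq_len(cfg$n_ind))
  dosage <- (anc[seq(1, nh, by = 2), , drop = FALSE] +
               anc[seq(2, nh, by = 2), , drop = FALSE]) / 2
  list(haplotypes = haplotype_set(hap, chrom, freqs$pos,
                                  sample_of_haplotype = rep(samples, each = 2)),
       ancestry = local_ancestry_matrix(rep(chrom, S), freqs$pos, t(dosage)))
}

#' Plant a selective sweep by haplotype copying
#'
#' Overwrites a fraction \code{final_freq} of haplotypes, over
#' \code{length_bp} centred on the sweep locus, with copies of one randomly
#' chosen haplotype carrying the derived allele at the locus (the donor; if
#' no carrier exists, a random haplotype is made one).  This creates the
#' long shared haplotype that iHS/Rsb detect and the loss of heterozygosity
#' that Hp detects.
#'
#' @param H a \code{\link{haplotype_set}}.
#' @param spec list with \code{locus} (focal SNP index),
#'   \code{final_freq} (target derived frequency) and \code{length_bp}
#'   (copied tract length).
#' @param seed optional RNG seed for donor/recipient choice.
#' @return the modified \code{haplotype_set}.  If \code{final_freq} is not
#'   above the locus's current derived frequency, the set is returned
#'   unchanged with a warning.
#' @export
impose_sweep <- function(H, spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(c("locus", "final_freq", "length_bp") %in% names(spec)))
  s <- spec$locus
  nh <- nrow(H$hap)
  cur <- mean(H$hap[, s])
  if (spec$final_freq <= cur) {
    warning(sprintf("final_freq %.2f not above current derived frequency %.2f at locus %d: sweep not imposed",
                    spec$final_freq, cur, s))
    return(H)
  }
  carriers <- which(H$hap[, s] == 1L)
  donor <- if (length(carriers)) {
    if (length(carriers) == 1L) carriers else sample(carriers, 1L)
  } else {
    d <- sample.int(nh, 1L); H$hap[d, s] <- 1L; d
  }
  cols <- which(H$pos >= H$pos[s] - spec$length_bp / 2 &
                  H$pos <= H$pos[s] + spec$length_bp / 2)
  n_target <- round(spec$final_freq * nh)
  pool <- setdiff(seq_len(nh), donor)
  recipients <- sample(pool, min(n_target - 1L, length(pool)))
  H$hap[recipients, cols] <- matrix(H$hap[donor, cols], nrow = length(recipients),
                                    ncol = length(cols), byrow = TRUE)
  H
}

#' Simulate pooled short-read allele counts with coverage gaps
#'
#' Per-site total depth is Poisson with the configured mean; reads carrying
#' allele 1 are Binomial(depth, allele frequency).  A fraction of the
#' chromosome is removed from the coverage mask as contiguous gaps (one gap
#' placed uniformly inside each of \code{n_gaps} equal-width blocks, so gaps
#' never collide); sites falling in a gap, or with fewer than
#' \code{min_depth} reads, yield no counts.
#'
#' @param x a \code{\link{haplotype_set}} (site frequencies are taken from
#'   it) or a list with elements \code{pos}, \code{freq} and optionally
#'   \code{chrom}.
#' @param depth mean depth of coverage.
#' @param gap_fraction fraction of the chromosome left uncovered.
#' @param seed RNG seed.
#' @param chrom_length chromosome length (defaults to just past the last
#'   site).
#' @param n_gaps number of uncovered gaps (default 10).
#' @param min_depth minimum reads required to report a site (default 2).
#' @return list with \code{counts} (a \code{\link{pooled_counts}}) and
#'   \code{mask} (a \code{\link{coverage_mask}}).
#' @export
simulate_pooled_reads <- function(x, depth = 11, gap_fraction = 0.05, seed,
                                  chrom_length = NULL, n_gaps = 10L,
                                  min_depth = 2L) {
  set.seed(seed)
  if (inherits(x, "haplotype_set")) {
    pos <- x$pos; freq <- colMeans(x$hap); chrom <- x$chrom
  } else {
    pos <- x$pos; freq <- x$freq; chrom <- x$chrom %||% "1"
  }
  L <- chrom_length %||% (max(pos) + 1)

  # coverage mask: one gap per equal-width block
  if (gap_fraction > 0) {
    gap_len <- floor(gap_fraction * L / n_gaps)
    block <- floor(L / n_gaps)
    gap_start <- vapply(seq_len(n_gaps), function(i) {
      lo <- (i - 1) * block + 1
      lo + sample.int(max(1, block - gap_len), 1L) - 1
    }, 0)
    gap_end <- gap_start + gap_len
    cov_start <- c(1, gap_end)
    cov_end <- c(gap_start, L + 1)
    keep <- cov_start < cov_end
    mask <- coverage_mask(rep(chrom, sum(keep)), cov_start[keep], cov_end[keep])
  } else {
    mask <- coverage_mask(chrom, 1, L + 1)
  }

  covered <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(mask))) {
    covered <- covered | (pos >= mask$start[i] & pos < mask$end[i])
  }
  tot <- stats::rpois(length(pos), depth)
  tot[!covered] <- 0L
  n1 <- stats::rbinom(length(pos), tot, freq)
  n0 <- tot - n1
  keep <- tot >= min_depth
  list(counts = pooled_counts(rep(chrom, sum(keep)), pos[keep],
                              pmax(n0, n1)[keep], pmin(n0, n1)[keep]),
       mask = mask)
}

#' Convert phased haplotypes to a diploid genotype matrix
#'
#' Genotypes count derived-allele copies; REF is labelled as the ancestral
#' allele ("A") and ALT as the derived ("G"), matching the VCF writer's
#' convention for haplotype sets.
#'
#' @param H a \code{\link{haplotype_set}}.
#' @return a \code{\link{genotype_matrix}}.
#' @export
as_genotype_matrix <- function(H) {
  samples <- unique(H$sample_of_haplotype)
  n <- length(samples)
  g <- H$hap[seq(1, 2 * n, by = 2), , drop = FALSE] +
    H$hap[seq(2, 2 * n, by = 2), , drop = FALSE]
  genotype_matrix(rep(H$chrom, ncol(H$hap)), H$pos, t(g), samples)
}
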