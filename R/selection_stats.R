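# Per-SNP selection statistics: iHS, Rsb and dAF, with the standardizations
# and p-value transforms used by the meta-analysis stage.
#
# EHH at distance d from a focal SNP is the probability that two randomly
# drawn carrier haplotypes are identical over the whole interval [focal, d]:
#   EHH(d) = sum_h C(n_h, 2) / C(n_c, 2)
# where n_c carriers split into groups of n_h identical haplotypes.  iHH is
# the trapezoidal integral of the decay curve over physical distance (the
# recombination map is assumed uniform, 1 cM = 1 Mb, so bp is the axis),
# truncated where EHH first drops below a floor, summed over both arms.

# Single-arm EHH walk.  carriers: haplotype row indices; dir: +1 right /
# -1 left; init_grp: initial identity grouping (all-1 for allele-split EHH,
# split by the focal allele for the allele-agnostic site version).
# Truncates at the first point below ehh_floor (that point is kept) or at a
# gap > max_gap / the chromosome edge (curve censored).
.ehh_walk <- function(hap, pos, focal, carriers, dir, ehh_floor, max_gap, init_grp) {
  n <- length(carriers)
  denom <- n * (n - 1) / 2
  S <- length(pos)
  grp <- init_grp
  off <- numeric(0)
  eh <- numeric(0)
  censored <- FALSE
  j <- focal
  repeat {
    jn <- j + dir
    if (jn < 1L || jn > S) { censored <- TRUE; break }
    if (abs(pos[jn] - pos[j]) > max_gap) { censored <- TRUE; break }
    key <- grp * 2L + hap[carriers, jn]
    grp <- match(key, unique(key))
    cnt <- tabulate(grp)
    e <- sum(cnt * (cnt - 1)) / 2 / denom
    off <- c(off, abs(pos[jn] - pos[focal]))
    eh <- c(eh, e)
    if (e < ehh_floor || e == 0) break
    j <- jn
  }
  list(offsets = c(0, off), ehh = c(1, eh), censored = censored)
}

#' Extended haplotype homozygosity decay curve
#'
#' Computes the EHH decay curve around a focal SNP for one allele class
#' (0 = ancestral, 1 = derived), separately for the left and right arms.
#' EHH at offset 0 is 1 by definition and the curve is non-increasing with
#' distance.
#'
#' @param H a \code{\link{haplotype_set}}.
#' @param focal focal SNP index (column of \code{H$hap}).
#' @param allele allele class, 0 or 1.
#' @param ehh_floor stop extending an arm once EHH drops below this value
#'   (default 0 = walk until homozygosity is exhausted).
#' @param max_gap censor an arm at the first inter-SNP gap larger than this
#'   many bp (default 200 kb).
#' @return An object of class \code{ehh_curve}: a list with \code{focal},
#'   \code{allele}, \code{n_carriers} and per-arm \code{left}/\code{right}
#'   lists of \code{offsets} (bp), \code{ehh} values and a \code{censored}
#'   flag (arm ended at the chromosome edge or a gap before reaching the
#'   floor).
#' @export
ehh <- function(H, focal, allele, ehh_floor = 0, max_gap = 2e5) {
  carriers <- which(H$hap[, focal] == allele)
  if (length(carriers) < 2L) {
    stop(sprintf("fewer than 2 carriers of allele %d at SNP %d: EHH undefined",
                 allele, focal))
  }
  init <- rep(1L, length(carriers))
  structure(list(
    focal = focal, allele = allele, n_carriers = length(carriers),
    left = .ehh_walk(H$hap, H$pos, focal, carriers, -1L, ehh_floor, max_gap, init),
    right = .ehh_walk(H$hap, H$pos, focal, carriers, +1L, ehh_floor, max_gap, init)
  ), class = "ehh_curve")
}

# Trapezoidal area of one arm, truncated at the first sub-floor point (the
# partial trapezoid ending at that point is included).
.ihh_arm <- function(arm, ehh_floor) {
  off <- arm$offsets; eh <- arm$ehh
  below <- which(eh < ehh_floor)
  k <- if (length(below)) below[1L] else length(eh)
  censored <- !length(below) && arm$censored
  area <- if (k >= 2L) {
    sum(diff(off[1:k]) * (eh[1:(k - 1)] + eh[2:k]) / 2)
  } else 0
  list(area = area, censored = censored)
}

#' Integrated EHH (iHH) of a decay curve
#'
#' Trapezoidal integral of EHH over physical distance, truncated where EHH
#' first drops below \code{ehh_floor}, summed over the left and right arms.
#' If an arm reaches the chromosome edge (or a censoring gap) before its EHH
#' crosses the floor, the value is flagged censored; censored SNPs are
#' excluded from standardization by default in the scan functions.
#'
#' @param curve an \code{\link{ehh}} curve.
#' @param ehh_floor truncation threshold (default 0.05).
#' @return list with \code{ihh} (bp-scaled area) and \code{censored}.
#' @export
ihh <- function(curve, ehh_floor = 0.05) {
  l <- .ihh_arm(curve$left, ehh_floor)
  r <- .ihh_arm(curve$right, ehh_floor)
  list(ihh = l$area + r$area, censored = l$censored || r$censored)
}

# Fused walk + integral for the scan loops.
.ihh_fast <- function(hap, pos, focal, carriers, ehh_floor, max_gap, init_grp) {
  a <- 0; censored <- FALSE
  for (dir in c(-1L, 1L)) {
    w <- .ehh_walk(hap, pos, focal, carriers, dir, ehh_floor, max_gap, init_grp)
    if (length(w$ehh) >= 2L) {
      a <- a + sum(diff(w$offsets) * (w$ehh[-length(w$ehh)] + w$ehh[-1L]) / 2)
    }
    if (w$censored && w$ehh[length(w$ehh)] >= ehh_floor) censored <- TRUE
  }
  list(ihh = a, censored = censored)
}

#' Within-population iHS scan
#'
#' For every SNP with within-population MAF of at least \code{maf_min} and
#' at least two carriers of each allele, computes
#' \code{raw = ln(iHH_ancestral / iHH_derived)}, standardizes it to mean 0 /
#' SD 1 within derived-allele-frequency bins, and transforms the score to a
#' two-sided p-value \code{1 - 2|Phi(z) - 0.5|}.  Negative standardized
#' values mark unusually long haplotypes around the derived allele.
#'
#' @param H a polarized \code{\link{haplotype_set}}.
#' @param maf_min minimum within-population MAF (default 0.05; the statistic
#'   has no power at nearly fixed SNPs).
#' @param bin_width derived-allele-frequency bin width for standardization
#'   (default 0.05).
#' @param ehh_floor,max_gap EHH truncation parameters (see \code{\link{ehh}}).
#' @param include_censored keep SNPs whose iHH was censored at the
#'   chromosome edge (default FALSE).
#' @param population label recorded on the output track.
#' @return A \code{\link{scan_track}} (test \code{"iHS"}) containing only the
#'   SNPs where the statistic is defined; the standardization bins are
#'   attached as attribute \code{"bins"}.
#' @export
ihs <- function(H, maf_min = 0.05, bin_width = 0.05, ehh_floor = 0.05,
                max_gap = 2e5, include_censored = FALSE, population = "pop") {
  S <- ncol(H$hap)
  daf <- colMeans(H$hap)
  raw <- rep(NA_real_, S)
  cens <- rep(FALSE, S)
  for (s in seq_len(S)) {
    if (pmin(daf[s], 1 - daf[s]) < maf_min) next
    anc <- which(H$hap[, s] == 0L)
    der <- which(H$hap[, s] == 1L)
    if (length(anc) < 2L || length(der) < 2L) next
    ia <- .ihh_fast(H$hap, H$pos, s, anc, ehh_floor, max_gap, rep(1L, length(anc)))
    id <- .ihh_fast(H$hap, H$pos, s, der, ehh_floor, max_gap, rep(1L, length(der)))
    if (ia$ihh <= 0 || id$ihh <= 0) next
    cens[s] <- ia$censored || id$censored
    raw[s] <- log(ia$ihh / id$ihh)
  }
  keep <- !is.na(raw) & (include_censored | !cens)
  idx <- which(keep)
  bins <- cut(daf[idx], breaks = seq(0, 1, by = bin_width), include.lowest = TRUE)
  z <- rep(NA_real_, length(idx))
  bin_stats <- data.frame(bin = levels(bins), mean = NA_real_, sd = NA_real_,
                          n = 0L, stringsAsFactors = FALSE)
  for (b in levels(bins)) {
    in_b <- which(bins == b)
    bin_stats$n[bin_stats$bin == b] <- length(in_b)
    if (length(in_b) >= 2L) {
      m <- mean(raw[idx][in_b]); s <- stats::sd(raw[idx][in_b])
      bin_stats$mean[bin_stats$bin == b] <- m
      bin_stats$sd[bin_stats$bin == b] <- s
      if (is.finite(s) && s > 0) z[in_b] <- (raw[idx][in_b] - m) / s
    }
  }
  ok <- !is.na(z)
  out <- scan_track(rep(H$chrom, sum(ok)), H$pos[idx][ok], raw[idx][ok],
                    z[ok], neglog10_p(p_two_sided(z[ok])),
                    test_name = "iHS", population = population)
  attr(out, "bins") <- bin_stats
  out
}

# Allele-agnostic integrated site EHH (iES): pair homozygosity over all
# haplotypes, with identity measured over [focal, d] including the focal
# allele itself (the curve still starts at 1 at offset 0).
.ies_track <- function(H, ehh_floor, max_gap) {
  S <- ncol(H$hap)
  all_rows <- seq_len(nrow(H$hap))
  ies <- rep(NA_real_, S)
  cens <- rep(FALSE, S)
  for (s in seq_len(S)) {
    init <- H$hap[, s] + 1L
    v <- .ihh_fast(H$hap, H$pos, s, all_rows, ehh_floor, max_gap, init)
    ies[s] <- v$ihh
    cens[s] <- v$censored
  }
  list(ies = ies, censored = cens)
}

#' Cross-population Rsb scan
#'
#' Per SNP, computes the allele-agnostic integrated site EHH (iES) within
#' each population and \code{raw = ln(iES_pop1 / iES_pop2)}, standardized
#' genome-wide to mean 0 / SD 1.  The p-value is one-sided upper tail,
#' \code{1 - Phi(z)}: large positive scores mark haplotypes unusually long
#' in population 1 relative to population 2.
#'
#' @param H1,H2 \code{\link{haplotype_set}}s over identical SNP sets
#'   (focal and reference population).
#' @param center \code{"mean"} (default) or \code{"median"} centring of the
#'   standardization.
#' @param ehh_floor,max_gap EHH truncation parameters.
#' @param include_censored keep chromosome-edge-censored SNPs.
#' @param population label recorded on the output track.
#' @return A \code{\link{scan_track}} (test \code{"Rsb"}).
#' @export
rsb <- function(H1, H2, center = c("mean", "median"), ehh_floor = 0.05,
                max_gap = 2e5, include_censored = FALSE, population = "pop") {
  center <- match.arg(center)
  if (!identical(H1$pos, H2$pos) || !identical(H1$chrom, H2$chrom)) {
    stop("rsb requires identical SNP sets in both populations")
  }
  t1 <- .ies_track(H1, ehh_floor, max_gap)
  t2 <- .ies_track(H2, ehh_floor, max_gap)
  ok <- !is.na(t1$ies) & !is.na(t2$ies) & t1$ies > 0 & t2$ies > 0 &
    (include_censored | (!t1$censored & !t2$censored))
  raw <- log(t1$ies[ok] / t2$ies[ok])
  if (length(raw) && pop_sd(raw) == 0) {
    # identical populations (or a constant ratio): no signal anywhere
    warning("Rsb has zero variance across SNPs; standardized scores set to 0")
    z <- rep(0, length(raw))
  } else {
    z <- standardize(raw, center = center)
  }
  scan_track(rep(H1$chrom, sum(ok)), H1$pos[ok], raw, z,
             neglog10_p(p_upper(z)), test_name = "Rsb", population = population)
}

#' Inter-population allele-frequency differentiation (dAF) scan
#'
#' \code{raw = AF_pop1 - AF_pop2} where AF is the reference-allele frequency
#' computed over non-missing calls, standardized genome-wide and transformed
#' to a two-sided p-value \code{1 - 2|Phi(z) - 0.5|}.
#'
#' @param G1,G2 \code{\link{genotype_matrix}} objects over the same SNPs.
#' @param population label recorded on the output track.
#' @return A \code{\link{scan_track}} (test \code{"dAF"}).
#' @export
delta_af <- function(G1, G2, population = "pop") {
  if (!identical(G1$pos, G2$pos) || !identical(G1$chrom, G2$chrom)) {
    stop("delta_af requires the same SNPs in both populations")
  }
  af_ref <- function(G) {
    n_called <- rowSums(!is.na(G$geno))
    1 - rowSums(G$geno, na.rm = TRUE) / (2 * n_called)
  }
  a1 <- af_ref(G1); a2 <- af_ref(G2)
  ok <- is.finite(a1) & is.finite(a2)
  raw <- a1[ok] - a2[ok]
  z <- standardize(raw)
  scan_track(G1$chrom[ok], G1$pos[ok], raw, z, neglog10_p(p_two_sided(z)),
             test_name = "dAF", population = population)
}
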