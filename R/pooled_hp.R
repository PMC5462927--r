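# Pooled-heterozygosity (Hp / ZHp) sliding-window sweep scan over
# pooled-sequencing allele-depth counts.
#
#   Hp = 2 * sum(n_MAJ) * sum(n_MIN) / (sum(n_MAJ) + sum(n_MIN))^2
#
# computed per window from the summed major/minor read counts of the SNPs it
# contains; 0 <= Hp <= 0.5 with the maximum at balanced counts.  Deeply
# negative Z-transformed values mark swept (near-monomorphic) windows.

# Covered bases in [1, x) given sorted non-overlapping mask intervals
# (1-based start, exclusive end).  Vectorized over x.
.covered_before <- function(x, st, en) {
  if (!length(st)) return(rep(0, length(x)))
  cums <- c(0, cumsum(en - st))
  j <- findInterval(x, en)                       # intervals with en <= x
  partial <- pmax(0, x - st[pmin(j + 1L, length(st))])
  partial[j >= length(st)] <- 0
  partial <- pmin(partial, (en - st)[pmin(j + 1L, length(st))])
  cums[j + 1L] + partial
}

#' Sliding-window pooled heterozygosity
#'
#' Tiles each chromosome with nominal windows of \code{window} bp advanced
#' by \code{step} bp.  When a coverage mask is supplied, each window is
#' extended by the number of uncovered bases within its nominal span
#' (single-pass: the extension itself is not re-examined for further gaps),
#' improving comparability of the per-window SNP supply.  SNPs inside the
#' extended window contribute their read counts to the Hp sums; windows
#' containing no SNP get \code{hp = 0} and are flagged empty.
#'
#' @param counts a \code{\link{pooled_counts}} object, sorted by position.
#' @param mask optional \code{\link{coverage_mask}}; if absent, window
#'   extension is disabled with a warning.
#' @param window nominal window size in bp (default 100 kb).
#' @param step window step in bp (default 10 kb).
#' @param chrom_length optional named vector of chromosome lengths; defaults
#'   to the mask's (or counts') last covered position per chromosome.
#' @return data frame of class \code{hp_windows} with columns \code{chrom},
#'   \code{start}, \code{end} (nominal), \code{ext_end} (extended),
#'   \code{n_snps}, \code{sum_nmaj}, \code{sum_nmin}, \code{hp},
#'   \code{empty}.
#' @export
window_hp <- function(counts, mask = NULL, window = 1e5, step = 1e4,
                      chrom_length = NULL) {
  if (is.null(mask)) {
    warning("no coverage mask supplied: window extension by uncovered bases is disabled")
  }
  chroms <- unique(counts$chrom)
  if (!is.null(mask)) chroms <- unique(c(chroms, mask$chrom))
  out <- list()
  for (ch in chroms) {
    cc <- counts[counts$chrom == ch, , drop = FALSE]
    L <- if (!is.null(chrom_length) && ch %in% names(chrom_length)) {
      chrom_length[[ch]]
    } else if (!is.null(mask) && any(mask$chrom == ch)) {
      max(mask$end[mask$chrom == ch]) - 1
    } else if (nrow(cc)) max(cc$pos) else 0
    if (L < 1) next
    starts <- seq(1, max(1, L - window + 1), by = step)
    if (!is.null(mask)) {
      m <- mask[mask$chrom == ch, , drop = FALSE]
      cov <- .covered_before(starts + window, m$start, m$end) -
        .covered_before(starts, m$start, m$end)
      u <- window - cov
    } else {
      u <- rep(0, length(starts))
    }
    ext_end <- starts + window + u
    pos <- cc$pos
    cmaj <- c(0, cumsum(cc$n_maj)); cmin <- c(0, cumsum(cc$n_min))
    lo <- findInterval(starts - 1, pos)            # SNPs with pos < start
    hi <- findInterval(ext_end - 1, pos)           # SNPs with pos < ext_end
    smaj <- cmaj[hi + 1L] - cmaj[lo + 1L]
    smin <- cmin[hi + 1L] - cmin[lo + 1L]
    tot <- smaj + smin
    hp <- ifelse(tot > 0, 2 * smaj * smin / tot^2, 0)
    out[[ch]] <- data.frame(chrom = ch, start = starts, end = starts + window,
                            ext_end = ext_end, n_snps = hi - lo,
                            sum_nmaj = smaj, sum_nmin = smin, hp = hp,
                            empty = hi == lo, stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               ext_end = numeric(), n_snps = integer(), sum_nmaj = numeric(),
               sum_nmin = numeric(), hp = numeric(), empty = logical())
  rownames(res) <- NULL
  class(res) <- c("hp_windows", "data.frame")
  res
}

#' Z-transform window Hp values
#'
#' \code{zhp = (hp - mean) / SD} with mean and SD taken over all non-empty
#' windows; empty windows keep \code{zhp = NA} and can never be significant.
#' The SD is the population (divide-by-n) form by default; at genome-scale
#' window counts the difference from the sample form is negligible.
#'
#' @param windows an \code{hp_windows} data frame from
#'   \code{\link{window_hp}}.
#' @param sd_type \code{"population"} (default) or \code{"sample"}.
#' @return the input with a \code{zhp} column added.
#' @export
zhp_transform <- function(windows, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  ne <- !windows$empty
  if (sum(ne) < 2L) stop("ZHp requires at least 2 non-empty windows")
  m <- mean(windows$hp[ne])
  s <- if (sd_type == "population") pop_sd(windows$hp[ne]) else stats::sd(windows$hp[ne])
  if (!is.finite(s) || s == 0) {
    stop("ZHp undefined: all window Hp values are equal (degenerate input)")
  }
  windows$zhp <- ifelse(ne, (windows$hp - m) / s, NA_real_)
  windows
}

#' Call sweep regions from significant Hp windows
#'
#' Selects windows with \code{zhp <= zhp_max} and merges overlapping or
#' bookended (touching) windows into single regions by interval union,
#' using the extended window ends.  The region score is the mean ZHp of the
#' constituent windows.
#'
#' @param windows an \code{hp_windows} data frame with a \code{zhp} column.
#' @param zhp_max significance threshold (default -4).
#' @return A \code{\link{genomic_regions}} data frame of pairwise-disjoint
#'   sweep regions.
#' @export
sweep_regions <- function(windows, zhp_max = -4) {
  sig <- windows[!is.na(windows$zhp) & windows$zhp <= zhp_max, , drop = FALSE]
  out <- genomic_regions()
  for (ch in unique(sig$chrom)) {
    s <- sig[sig$chrom == ch, , drop = FALSE]
    r <- IRanges::IRanges(s$start, s$ext_end - 1)      # end-exclusive -> closed
    merged <- IRanges::reduce(r)                       # merges touching windows
    hits <- IRanges::findOverlaps(r, merged)
    for (i in seq_along(merged)) {
      members <- S4Vectors::queryHits(hits)[S4Vectors::subjectHits(hits) == i]
      out <- rbind(out, genomic_regions(
        ch, IRanges::start(merged)[i], IRanges::end(merged)[i] + 1,
        n_snps = length(members), score = mean(s$zhp[members]),
        provenance = "ZHp:pool"))
    }
  }
  class(out) <- c("genomic_region", "data.frame")
  out
}
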