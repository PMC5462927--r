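# Stouffer-style meta-analysis of selection signals (meta-SS), candidate
# region calling, cross-population sharing and fine-mapping.

#' Meta-analysis and region-calling configuration
#'
#' @param mode Z-score combination rule: \code{"paper"} divides the summed
#'   per-test Z-scores by the number of tests k (the rule as printed in the
#'   source analysis); \code{"stouffer"} divides by \code{sqrt(k)}
#'   (Whitlock's standard, under which the combined p-value is uniform under
#'   the null).  The paper rule is conservative for k > 1; see the vignette.
#' @param threshold_neglog_p -log10 p significance threshold (default 4).
#' @param min_snps minimum number of clustered significant SNPs to call a
#'   region (default 5).
#' @param max_gap_bp maximum distance between consecutive significant SNPs
#'   within one cluster (default 500 kb).
#' @param adjacency \code{"significant"} (default): only consecutive
#'   significant SNPs are subject to the gap rule, non-significant SNPs in
#'   between do not break a cluster.  \code{"array"}: any intervening
#'   non-significant SNP breaks the run.
#' @return list of class \code{meta_config}.
#' @export
meta_config <- function(mode = c("paper", "stouffer"), threshold_neglog_p = 4,
                        min_snps = 5, max_gap_bp = 5e5,
                        adjacency = c("significant", "array")) {
  stopifnot(threshold_neglog_p > 0, min_snps >= 1, max_gap_bp > 0)
  structure(list(mode = match.arg(mode),
                 threshold_neglog_p = threshold_neglog_p,
                 min_snps = min_snps, max_gap_bp = max_gap_bp,
                 adjacency = match.arg(adjacency)),
            class = "meta_config")
}

#' Combine per-SNP p-values across selection tests (meta-SS)
#'
#' Each test's p-value is transformed to a Z-score
#' \code{Z = Phi^-1(1 - p)}; the per-SNP scores are combined as
#' \code{Z_i = sum(Z) / k} (mode \code{"paper"}) or
#' \code{Z_i = sum(Z) / sqrt(k)} (mode \code{"stouffer"}), where k is the
#' number of tests with a defined p-value at that SNP, and referred back to
#' the normal distribution: combined \code{p = 1 - Phi(Z_i)}.  SNPs at which
#' every test is undefined are absent from the output.
#'
#' @param pvals data frame with columns \code{chrom}, \code{pos} and one
#'   column per test holding p-values in (0, 1] (NA = test undefined at that
#'   SNP).  p = 0 is clamped to the package floor before transformation.
#' @param cfg a \code{\link{meta_config}}.
#' @param population label recorded on the output track.
#' @return A \code{\link{scan_track}} (test \code{"metaSS"}) whose \code{z}
#'   is the combined score and \code{raw} the combined p-value.
#' @export
stouffer_combine <- function(pvals, cfg = meta_config(), population = "pop") {
  pcols <- setdiff(names(pvals), c("chrom", "pos"))
  if (!length(pcols)) stop("no test p-value columns supplied")
  P <- clamp_p(as.matrix(pvals[, pcols, drop = FALSE]))
  Z <- stats::qnorm(P, lower.tail = FALSE)  # Phi^-1(1 - p)
  k <- rowSums(!is.na(Z))
  keep <- k > 0
  zsum <- rowSums(Z, na.rm = TRUE)[keep]
  kk <- k[keep]
  zi <- if (cfg$mode == "paper") zsum / kk else zsum / sqrt(kk)
  p_comb <- clamp_p(p_upper(zi))
  scan_track(pvals$chrom[keep], pvals$pos[keep], raw = p_comb, z = zi,
             neglog_p = neglog10_p(p_comb), test_name = "metaSS",
             population = population)
}

#' Call candidate selected regions from a scan track
#'
#' Significant SNPs (\code{neglog_p >= threshold}) are clustered per
#' chromosome: consecutive significant SNPs separated by at most
#' \code{max_gap_bp} join one cluster, and clusters with at least
#' \code{min_snps} members become regions spanning the first to the last
#' significant SNP.  The region score is the peak \code{neglog_p}.
#'
#' @param track a \code{\link{scan_track}}, sorted by (chrom, pos).
#' @param cfg a \code{\link{meta_config}}.
#' @return A \code{\link{genomic_regions}} data frame (possibly empty).
#' @export
call_regions <- function(track, cfg = meta_config()) {
  out <- genomic_regions()
  prov <- paste0(attr(track, "test_name") %||% "scan", ":",
                 attr(track, "population") %||% "pop")
  for (ch in unique(track$chrom)) {
    t <- track[track$chrom == ch, ]
    if (cfg$adjacency == "significant") {
      sig <- t[!is.na(t$neglog_p) & t$neglog_p >= cfg$threshold_neglog_p, ]
      if (nrow(sig) < cfg$min_snps) next
      new_cluster <- c(TRUE, diff(sig$pos) > cfg$max_gap_bp)
      cl <- cumsum(new_cluster)
    } else {
      is_sig <- !is.na(t$neglog_p) & t$neglog_p >= cfg$threshold_neglog_p
      sig <- t[is_sig, ]
      if (nrow(sig) < cfg$min_snps) next
      run <- cumsum(!is_sig)[is_sig]      # runs of array-adjacent significant SNPs
      gap_break <- c(TRUE, diff(sig$pos) > cfg$max_gap_bp | diff(run) > 0)
      cl <- cumsum(gap_break)
    }
    for (g in unique(cl)) {
      s <- sig[cl == g, ]
      if (nrow(s) < cfg$min_snps) next
      out <- rbind(out, genomic_regions(ch, min(s$pos), max(s$pos),
                                        n_snps = nrow(s),
                                        score = max(s$neglog_p),
                                        provenance = prov))
    }
  }
  class(out) <- c("genomic_region", "data.frame")
  out
}

#' Cross-population shared candidate regions
#'
#' Reports every pair of regions (one from each list) on the same chromosome
#' that overlap by at least 1 bp; with the package's end-exclusive size
#' convention, intervals that merely touch (one's end equals the other's
#' start) do not overlap.  A region may appear in multiple pairs.
#'
#' @param a,b \code{\link{genomic_regions}} data frames.
#' @return data frame with the indices (\code{a_idx}, \code{b_idx}) and
#'   coordinates of each overlapping pair.
#' @export
shared_regions <- function(a, b) {
  empty <- data.frame(a_idx = integer(), b_idx = integer(),
                      chrom = character(), a_start = numeric(), a_end = numeric(),
                      b_start = numeric(), b_end = numeric(),
                      stringsAsFactors = FALSE)
  if (!nrow(a) || !nrow(b)) return(empty)
  out <- empty
  for (ch in intersect(unique(a$chrom), unique(b$chrom))) {
    ai <- which(a$chrom == ch); bi <- which(b$chrom == ch)
    # end-exclusive intervals -> closed IRanges [start, end - 1]
    ra <- IRanges::IRanges(a$start[ai], a$end[ai] - 1)
    rb <- IRanges::IRanges(b$start[bi], b$end[bi] - 1)
    hits <- IRanges::findOverlaps(ra, rb)
    if (!length(hits)) next
    qi <- ai[S4Vectors::queryHits(hits)]; si <- bi[S4Vectors::subjectHits(hits)]
    out <- rbind(out, data.frame(a_idx = qi, b_idx = si, chrom = ch,
                                 a_start = a$start[qi], a_end = a$end[qi],
                                 b_start = b$start[si], b_end = b$end[si],
                                 stringsAsFactors = FALSE))
  }
  out[order(out$a_idx, out$b_idx), , drop = FALSE]
}

#' Fine-map a candidate region by an overlapping shared region
#'
#' The fine-mapped interval is the intersection
#' \code{[max(starts), min(ends)]}; sizes follow the \code{end - start}
#' convention and \code{reduction_bp = original_size - intersection_size}
#' (0 when the shared region contains the original).
#'
#' @param original,shared single-row \code{\link{genomic_regions}} (or any
#'   data frame with \code{chrom}, \code{start}, \code{end}).
#' @return single-row data frame of class \code{fine_map_row} with the
#'   original and intersection coordinates, sizes and \code{reduction_bp};
#'   or, if the regions do not overlap, the same shape with NA intersection
#'   fields and \code{overlap = FALSE}.
#' @export
fine_map <- function(original, shared) {
  stopifnot(nrow(original) == 1L, nrow(shared) == 1L)
  o_size <- original$end - original$start
  i_start <- max(original$start, shared$start)
  i_end <- min(original$end, shared$end)
  overlaps <- original$chrom == shared$chrom && i_start < i_end
  out <- data.frame(
    chrom = original$chrom, start = original$start, end = original$end,
    size = o_size,
    int_start = if (overlaps) i_start else NA_real_,
    int_end = if (overlaps) i_end else NA_real_,
    int_size = if (overlaps) i_end - i_start else NA_real_,
    reduction_bp = if (overlaps) o_size - (i_end - i_start) else NA_real_,
    overlap = overlaps, stringsAsFactors = FALSE)
  class(out) <- c("fine_map_row", "data.frame")
  out
}

#' Fine-map a table of region pairs
#'
#' Convenience wrapper applying \code{\link{fine_map}} row-wise to paired
#' original/shared regions (e.g. the output of a sharing analysis);
#' non-overlapping pairs are excluded.
#'
#' @param originals,shareds \code{\link{genomic_regions}}-like data frames
#'   with the same number of rows (row i of each forms a pair).
#' @return data frame with one \code{fine_map_row} per overlapping pair.
#' @export
fine_map_table <- function(originals, shareds) {
  stopifnot(nrow(originals) == nrow(shareds))
  rows <- lapply(seq_len(nrow(originals)), function(i) {
    fine_map(originals[i, , drop = FALSE], shareds[i, , drop = FALSE])
  })
  out <- do.call(rbind, rows)
  out[out$overlap, , drop = FALSE]
}

#' Assemble per-test p-value columns from scan tracks
#'
#' Outer-joins a named list of \code{\link{scan_track}}s on (chrom, pos) and
#' recovers each test's p-value from its \code{neglog_p} column, producing
#' the input expected by \code{\link{stouffer_combine}}.  SNPs absent from a
#' track get NA for that test (the combination's k adapts per SNP).
#'
#' @param tracks named list of \code{scan_track} data frames.
#' @return data frame with columns \code{chrom}, \code{pos} and one p-value
#'   column per track, sorted by (chrom, pos).
#' @export
track_pvalues <- function(tracks) {
  stopifnot(length(tracks) >= 1, !is.null(names(tracks)))
  keys <- unique(do.call(rbind, lapply(tracks, function(t) t[, c("chrom", "pos")])))
  keys <- keys[order(keys$chrom, keys$pos), , drop = FALSE]
  rownames(keys) <- NULL
  for (nm in names(tracks)) {
    t <- tracks[[nm]]
    m <- match(paste(keys$chrom, keys$pos), paste(t$chrom, t$pos))
    keys[[nm]] <- 10^(-t$neglog_p[m])
  }
  keys
}
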