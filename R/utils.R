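# Shared numerical helpers.

# Lower clamp applied to every p-value before -log10; keeps the transform
# finite when a Z-score is far in a tail.
P_FLOOR <- 1e-300

clamp_p <- function(p) pmin(pmax(p, P_FLOOR), 1)

neglog10_p <- function(p) -log10(clamp_p(p))

# Two-sided p from a standard-normal score: 1 - 2|Phi(z) - 0.5|, computed in
# the tail for precision.
p_two_sided <- function(z) 2 * stats::pnorm(abs(z), lower.tail = FALSE)

# One-sided upper-tail p: 1 - Phi(z).
p_upper <- function(z) stats::pnorm(z, lower.tail = FALSE)

# Population (divide-by-n) standard deviation.
pop_sd <- function(x) {
  x <- x[!is.na(x)]
  sqrt(mean((x - mean(x))^2))
}

# Genome-wide Z-standardization with selectable centre and SD convention.
standardize <- function(x, center = c("mean", "median"), sd_type = c("sample", "population")) {
  center <- match.arg(center)
  sd_type <- match.arg(sd_type)
  ctr <- if (center == "mean") mean(x, na.rm = TRUE) else stats::median(x, na.rm = TRUE)
  s <- if (sd_type == "sample") stats::sd(x[!is.na(x)]) else pop_sd(x)
  if (!is.finite(s) || s == 0) {
    stop("standardization undefined: statistic has zero variance (degenerate input)")
  }
  (x - ctr) / s
}

# Order check for (chrom, pos) tracks; positions must be strictly increasing
# within each chromosome.
check_sorted_positions <- function(chrom, pos, what = "input") {
  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    if (length(p) > 1L && any(diff(p) <= 0)) {
      i <- which(diff(p) <= 0)[1L]
      stop(sprintf("%s positions not strictly increasing on chromosome %s near position %s",
                   what, ch, format(p[i + 1L], big.mark = ",")))
    }
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
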