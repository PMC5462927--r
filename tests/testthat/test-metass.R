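test_that("Stouffer combination reproduces closed-form normal-CDF cases", {
  pv <- data.frame(chrom = "1", pos = 100,
                   t1 = 0.5, t2 = 0.5, t3 = 0.5)
  for (mode in c("paper", "stouffer")) {
    out <- stouffer_combine(pv, meta_config(mode = mode))
    expect_equal(out$z, 0)
    expect_equal(out$raw, 0.5)           # combined p
  }

  # single defined test: both modes reduce to the identity
  pv1 <- data.frame(chrom = "1", pos = 100, t1 = 0.01, t2 = NA_real_, t3 = NA_real_)
  for (mode in c("paper", "stouffer")) {
    out <- stouffer_combine(pv1, meta_config(mode = mode))
    expect_equal(out$raw, 0.01, tolerance = 1e-12)
  }

  # p = (0.0013499, 0.5, 0.5): Z ~ (3, 0, 0)
  pv3 <- data.frame(chrom = "1", pos = 100, t1 = 0.0013499, t2 = 0.5, t3 = 0.5)
  z1 <- qnorm(0.0013499, lower.tail = FALSE)
  paper <- stouffer_combine(pv3, meta_config(mode = "paper"))
  expect_equal(paper$z, z1 / 3, tolerance = 1e-9)
  expect_equal(paper$raw, pnorm(z1 / 3, lower.tail = FALSE), tolerance = 1e-12)
  stf <- stouffer_combine(pv3, meta_config(mode = "stouffer"))
  expect_equal(stf$z, z1 / sqrt(3), tolerance = 1e-9)
  expect_lt(stf$raw, paper$raw)          # sqrt(k) scaling is less conservative
})

test_that("SNPs with no defined test are absent and k adapts per SNP", {
  pv <- data.frame(chrom = "1", pos = c(1, 2, 3),
                   t1 = c(0.01, NA, NA), t2 = c(0.02, 0.05, NA))
  out <- stouffer_combine(pv, meta_config())
  expect_equal(out$pos, c(1L, 2L))
  expect_equal(out$raw[2], 0.05, tolerance = 1e-12)  # k = 1 identity
})

test_that("region calling honours the five-SNP / 500-kb rule", {
  cfg <- meta_config()
  mk <- function(pos, nlp) scan_track(rep("1", length(pos)), pos,
                                      raw = nlp, z = nlp, neglog_p = nlp)
  # five significant SNPs at 10 kb spacing -> one region
  r <- call_regions(mk(seq(1e6, by = 1e4, length.out = 5), rep(5, 5)), cfg)
  expect_equal(nrow(r), 1)
  expect_equal(r$n_snps, 5)
  expect_equal(c(r$start, r$end), c(1e6, 1e6 + 4e4))
  expect_equal(r$size, r$end - r$start)

  # four significant SNPs -> nothing
  r4 <- call_regions(mk(seq(1e6, by = 1e4, length.out = 4), rep(5, 4)), cfg)
  expect_equal(nrow(r4), 0)

  # six significant SNPs with a 600 kb gap after the third -> two clusters of 3
  pos <- c(1e6, 1.01e6, 1.02e6, 1.62e6, 1.63e6, 1.64e6)
  expect_equal(nrow(call_regions(mk(pos, rep(5, 6)), cfg)), 0)

  # non-significant SNPs between significant ones do not break a cluster
  pos2 <- seq(1e6, by = 1e4, length.out = 9)
  nlp2 <- c(5, 1, 5, 1, 5, 1, 5, 1, 5)
  r9 <- call_regions(mk(pos2, nlp2), cfg)
  expect_equal(nrow(r9), 1)
  expect_equal(r9$n_snps, 5)
  # ...but do under the array-adjacency reading
  expect_equal(nrow(call_regions(mk(pos2, nlp2),
                                 meta_config(adjacency = "array"))), 0)
})

test_that("region calling matches exhaustive clustering on random small tracks", {
  set.seed(77)
  for (rep in 1:25) {
    n <- sample(3:10, 1)
    pos <- sort(sample.int(3e6, n))
    nlp <- ifelse(runif(n) < 0.7, runif(n, 4, 9), runif(n, 0, 3.9))
    cfg <- meta_config(min_snps = sample(2:5, 1), max_gap_bp = sample(c(2e5, 5e5), 1))
    got <- call_regions(scan_track(rep("1", n), pos, nlp, nlp, nlp), cfg)
    want <- bf_call_regions(pos, nlp, 4, cfg$min_snps, cfg$max_gap_bp)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$n_snps, want$n)
    }
  }
})

test_that("raising the threshold never enlarges regions or claims new territory", {
  set.seed(78)
  pos <- sort(sample.int(5e6, 300))
  nlp <- abs(rnorm(300, 2, 2.5))
  tr <- scan_track(rep("1", 300), pos, nlp, nlp, nlp)
  prev <- call_regions(tr, meta_config(threshold_neglog_p = 4, min_snps = 3))
  for (thr in c(5, 6, 7)) {
    cur <- call_regions(tr, meta_config(threshold_neglog_p = thr, min_snps = 3))
    # every stricter-threshold region is contained in a laxer one (a cluster
    # may split, but never grow or appear in new territory)
    for (i in seq_len(nrow(cur))) {
      expect_true(any(prev$start <= cur$start[i] & prev$end >= cur$end[i]))
    }
    expect_lte(sum(cur$size), sum(prev$size))
    prev <- cur
  }
})

test_that("region sharing requires a true 1-bp overlap and matches brute force", {
  a <- genomic_regions("1", c(100, 500), c(200, 700))
  expect_equal(nrow(shared_regions(a, a)), 2)

  touching <- shared_regions(genomic_regions("1", 100, 200),
                             genomic_regions("1", 200, 300))
  expect_equal(nrow(touching), 0)

  set.seed(90)
  for (rep in 1:10) {
    na <- sample(1:8, 1); nb <- sample(1:8, 1)
    mk <- function(n) {
      s <- sample.int(1e4, n)
      genomic_regions(sample(c("1", "2"), n, replace = TRUE), s, s + sample.int(2000, n))
    }
    a <- mk(na); b <- mk(nb)
    got <- shared_regions(a, b)
    want <- bf_overlap_pairs(a, b)
    expect_equal(nrow(got), if (is.null(want)) 0L else nrow(want))
    if (!is.null(want)) {
      o <- order(want[, 1], want[, 2])
      expect_equal(got$a_idx, want[o, 1])
      expect_equal(got$b_idx, want[o, 2])
    }
  }
})

test_that("fine-mapping reproduces the published interval arithmetic", {
  r <- fine_map(genomic_regions("1", 149241884, 149992523),
                genomic_regions("1", 149547998, 149960460))
  expect_equal(r$int_size, 412462)
  expect_equal(r$reduction_bp, 338177)

  r2 <- fine_map(genomic_regions("2", 70314631, 71161113),
                 genomic_regions("2", 70314631, 71161113))
  expect_equal(r2$int_size, 846482)
  expect_equal(r2$reduction_bp, 0)

  r3 <- fine_map(genomic_regions("12", 27050192, 29151436),
                 genomic_regions("12", 28949354, 29151436))
  expect_equal(r3$int_size, 202082)
  expect_equal(r3$reduction_bp, 1899162)
})

test_that("fine-mapping is commutative on the intersection, non-negative, and honest about disjoint input", {
  a <- genomic_regions("1", 100, 1000)
  b <- genomic_regions("1", 500, 2000)
  ab <- fine_map(a, b); ba <- fine_map(b, a)
  expect_equal(c(ab$int_start, ab$int_end), c(ba$int_start, ba$int_end))
  expect_gte(ab$reduction_bp, 0)
  expect_equal(fine_map(a, a)$reduction_bp, 0)   # idempotent

  disjoint <- fine_map(a, genomic_regions("1", 5000, 6000))
  expect_false(disjoint$overlap)
  expect_true(is.na(disjoint$int_size))
  expect_equal(nrow(fine_map_table(rbind(a, a), rbind(b, genomic_regions("1", 5000, 6000)))), 1)
})

test_that("track_pvalues outer-joins tracks and recovers per-test p-values", {
  t1 <- scan_track(c("1", "1"), c(100, 200), c(0, 0), c(0, 0), c(2, 3), test_name = "iHS")
  t2 <- scan_track(c("1", "1"), c(200, 300), c(0, 0), c(0, 0), c(1, 4), test_name = "Rsb")
  pv <- track_pvalues(list(iHS = t1, Rsb = t2))
  expect_equal(pv$pos, c(100L, 200L, 300L))
  expect_equal(pv$iHS, c(1e-2, 1e-3, NA))
  expect_equal(pv$Rsb, c(NA, 1e-1, 1e-4))
})
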