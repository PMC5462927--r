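test_that("EHH equals brute-force pair counting on small fixtures", {
  for (seed in 1:6) {
    H <- random_hapset(n_hap = 8 + (seed %% 3) * 2, n_snp = 12, seed = seed)
    for (allele in 0:1) {
      focal <- 6
      if (sum(H$hap[, focal] == allele) < 2) next
      cv <- ehh(H, focal, allele, ehh_floor = 0, max_gap = Inf)
      # right arm: offsets map to SNP indices focal+1, focal+2, ...
      for (k in seq_along(cv$right$offsets)[-1]) {
        expect_equal(cv$right$ehh[k], bf_ehh(H$hap, focal, focal + k - 1, allele))
      }
      for (k in seq_along(cv$left$offsets)[-1]) {
        expect_equal(cv$left$ehh[k], bf_ehh(H$hap, focal, focal - k + 1, allele))
      }
      expect_equal(cv$left$ehh[1], 1)
      expect_equal(cv$right$ehh[1], 1)
      # non-increasing decay
      expect_true(all(diff(cv$right$ehh) <= 1e-12))
      expect_true(all(diff(cv$left$ehh) <= 1e-12))
    }
  }
})

test_that("four carriers splitting into two haplotype pairs give EHH = 1/3", {
  hap <- rbind(c(0, 1, 0), c(0, 1, 0), c(0, 1, 1), c(0, 1, 1), c(1, 0, 0), c(0, 0, 1))
  H <- haplotype_set(hap, "1", c(100, 200, 300),
                     sample_of_haplotype = rep(c("a", "b", "c"), each = 2))
  cv <- ehh(H, 2, 1)
  expect_equal(cv$right$ehh, c(1, 1 / 3))
})

test_that("identical carrier haplotypes keep EHH at 1 to the chromosome end", {
  hap <- matrix(rep(c(0, 1, 1, 0, 1), each = 4), nrow = 4)
  H <- haplotype_set(hap, "1", c(1, 1001, 2001, 3001, 4001),
                     sample_of_haplotype = rep(c("a", "b"), each = 2))
  cv <- ehh(H, 3, 1)
  expect_true(all(cv$left$ehh == 1) && all(cv$right$ehh == 1))
  expect_true(cv$left$censored && cv$right$censored)
  v <- ihh(cv)
  expect_equal(v$ihh, 4000)   # 2000 bp per arm of constant EHH = 1
  expect_true(v$censored)
})

test_that("fewer than two carriers makes EHH undefined", {
  hap <- rbind(c(0, 1), c(0, 0), c(0, 0), c(0, 0))
  H <- haplotype_set(hap, "1", c(1, 101),
                     sample_of_haplotype = rep(c("a", "b"), each = 2))
  expect_error(ehh(H, 1, 1), "fewer than 2 carriers")
})

test_that("iHH matches hand-computed trapezoid arithmetic with floor truncation", {
  curve <- structure(list(
    focal = 1, allele = 1, n_carriers = 4,
    left = list(offsets = c(0, 100, 200), ehh = c(1, 0.6, 0.3), censored = FALSE),
    right = list(offsets = c(0, 150), ehh = c(1, 0.02), censored = FALSE)
  ), class = "ehh_curve")
  # left: 100*(1+0.6)/2 + 100*(0.6+0.3)/2 = 125; right truncates after the
  # first sub-floor point: 150*(1+0.02)/2 = 76.5
  expect_equal(ihh(curve, ehh_floor = 0.05)$ihh, 201.5)

  single <- structure(list(focal = 1, allele = 1, n_carriers = 4,
                           left = list(offsets = 0, ehh = 1, censored = TRUE),
                           right = list(offsets = 0, ehh = 1, censored = TRUE)),
                      class = "ehh_curve")
  v <- ihh(single)
  expect_equal(v$ihh, 0)
  expect_true(v$censored)
})

test_that("complementing the ancestral/derived labels negates raw iHS", {
  cfg <- sim_config(n_snps = 400, n_ind = 30, seed = 21)
  H <- simulate_admixed(cfg, simulate_ancestral_freqs(cfg))$haplotypes
  Hc <- haplotype_set(1L - H$hap, H$chrom, H$pos, H$sample_of_haplotype)
  t1 <- ihs(H, include_censored = TRUE)
  t2 <- ihs(Hc, include_censored = TRUE)
  common <- intersect(t1$pos, t2$pos)
  expect_gt(length(common), 100)
  expect_equal(t1$raw[match(common, t1$pos)], -t2$raw[match(common, t2$pos)])
})

test_that("standardized iHS is centred and unit-scaled within frequency bins", {
  cfg <- sim_config(n_snps = 5000, n_ind = 40, seed = 31)
  H <- simulate_admixed(cfg, simulate_ancestral_freqs(cfg))$haplotypes
  tr <- ihs(H)
  daf <- colMeans(H$hap)[match(tr$pos, H$pos)]
  bin <- cut(daf, seq(0, 1, 0.05), include.lowest = TRUE)
  for (b in levels(bin)) {
    zz <- tr$z[bin == b]
    if (length(zz) < 50) next
    expect_lt(abs(mean(zz)), 0.05)
    expect_lt(abs(sd(zz) - 1), 0.05)
  }
  expect_true(all(tr$neglog_p >= 0))
})

test_that("Rsb is exactly antisymmetric and zero for identical populations", {
  cfg <- sim_config(n_snps = 300, n_ind = 20, seed = 41)
  fr <- simulate_ancestral_freqs(cfg)
  H1 <- simulate_admixed(cfg, fr)$haplotypes
  H2 <- simulate_admixed(cfg, fr, seed = 99)$haplotypes
  a <- rsb(H1, H2)
  b <- rsb(H2, H1)
  expect_equal(a$raw, -b$raw)
  expect_equal(a$z, -b$z)

  expect_warning(same <- rsb(H1, H1), "zero variance")
  expect_true(all(same$raw == 0))
  # z = 0 under the one-sided transform: p = 0.5, -log10 p ~ 0.301
  expect_equal(same$neglog_p, rep(-log10(0.5), nrow(same)), tolerance = 1e-12)
})

test_that("planted hard sweeps drive standardized iHS strongly negative at the locus", {
  zs <- vapply(c(101, 102, 103), function(seed) {
    cfg <- sim_config(n_snps = 1500, n_ind = 50,
                      sweep = list(locus = 750, final_freq = 0.9, length_bp = 150000),
                      seed = seed)
    fr <- simulate_ancestral_freqs(cfg)
    H <- suppressWarnings(
      impose_sweep(simulate_admixed(cfg, fr)$haplotypes, cfg$sweep, seed = seed + 2))
    tr <- ihs(H)
    loc <- H$pos[750]
    near <- which(abs(tr$pos - loc) < 20000)
    min(tr$z[near])
  }, 0)
  expect_lt(mean(zs), -2)
})

test_that("dAF respects frequency bounds, flips sign under allele relabelling, and matches the standardization oracle", {
  set.seed(55)
  n <- 200
  g1 <- matrix(rbinom(n * 30, 2, runif(n)), nrow = n)
  g2 <- matrix(rbinom(n * 30, 2, runif(n)), nrow = n)
  G1 <- genotype_matrix(rep("1", n), seq_len(n) * 100, g1, sprintf("a%d", 1:30))
  G2 <- genotype_matrix(rep("1", n), seq_len(n) * 100, g2, sprintf("b%d", 1:30))
  tr <- delta_af(G1, G2)
  expect_true(all(tr$raw >= -1 & tr$raw <= 1))
  expect_equal(tr$z, bf_standardize(tr$raw), tolerance = 1e-12)

  # endpoint check: pop1 fixed ref at SNP1 and fixed alt at SNP2, pop2 opposite
  Ga <- genotype_matrix(rep("1", 2), c(1, 2), rbind(rep(0, 4), rep(2, 4)), letters[1:4])
  Gb <- genotype_matrix(rep("1", 2), c(1, 2), rbind(rep(2, 4), rep(0, 4)), letters[5:8])
  tr2 <- delta_af(Ga, Gb)
  expect_equal(sort(tr2$raw), c(-1, 1))

  # flipping the allele labels at every SNP flips raw's sign
  Gf1 <- genotype_matrix(G1$chrom, G1$pos, 2 - g1, G1$samples)
  Gf2 <- genotype_matrix(G2$chrom, G2$pos, 2 - g2, G2$samples)
  trf <- delta_af(Gf1, Gf2)
  expect_equal(trf$raw, -tr$raw)
})

test_that("dAF on frequency-identical populations demands non-degenerate input", {
  g <- matrix(rbinom(50 * 10, 2, 0.4), nrow = 50)
  G1 <- genotype_matrix(rep("1", 50), 1:50, g, sprintf("a%d", 1:10))
  G2 <- genotype_matrix(rep("1", 50), 1:50, g, sprintf("b%d", 1:10))
  expect_error(delta_af(G1, G2), "degenerate")
})

test_that("neutral scans are calibrated: almost no SNP reaches -log10 p of 4", {
  cfg <- sim_config(n_snps = 10000, n_ind = 40, seed = 61)
  fr <- simulate_ancestral_freqs(cfg)
  H1 <- simulate_admixed(cfg, fr)$haplotypes
  H2 <- simulate_admixed(cfg, fr, seed = 4242)$haplotypes
  t_ihs <- ihs(H1)
  t_rsb <- rsb(H1, H2)
  t_daf <- delta_af(as_genotype_matrix(H1), as_genotype_matrix(H2))
  # On panels without background LD the standardized scores are approximately
  # normal but mildly leptokurtic (kurtosis ~ 4), so the 4-sigma tail carries
  # up to ~2x the Gaussian mass; the bound reflects that (see the vignette).
  # Single extreme SNPs are harmless downstream: region calling requires five
  # clustered hits (see the null-calibration acceptance test).
  for (tr in list(t_ihs, t_rsb, t_daf)) {
    expect_lt(mean(tr$neglog_p >= 4), 0.0025)
  }
})
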