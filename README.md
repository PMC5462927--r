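# admixscan

Genome scans for signatures of positive selection in admixed cattle
populations.

African zebu cattle such as the East African Shorthorn Zebu are ancient
hybrids of Asian zebu (*Bos indicus*) and African taurine (*Bos taurus*)
ancestry, kept by smallholders for their adaptation to heat, poor forage and
heavy pathogen challenge. Finding the genomic regions that selection has
shaped in such populations requires combining several weak, complementary
signals: unusually long haplotypes, allele-frequency shifts against a
reference panel, localized loss of heterozygosity in pooled sequence, and
distortions of the local zebu/taurine ancestry mosaic. `admixscan`
implements that whole tool chain as composable R functions, for population
geneticists working on admixed livestock (or any two-way admixed diploid
population).

## What it computes

* **iHS** — within-population integrated extended haplotype homozygosity.
  For each SNP, EHH(d) = Σₕ C(nₕ,2) / C(n꜀,2) is the probability that two
  carrier haplotypes are identical from the focal SNP out to distance d;
  iHH is its trapezoidal integral over physical distance and
  raw iHS = ln(iHH_A / iHH_D), standardized to mean 0 / SD 1 within
  derived-allele-frequency bins. Two-sided p = 1 − 2|Φ(z) − 0.5|.
* **Rsb** — between-population ratio ln(iES₁ / iES₂) of allele-agnostic
  integrated site EHH, standardized genome-wide; one-sided p = 1 − Φ(z)
  flags haplotypes unusually long in the focal population.
* **ΔAF** — reference-allele frequency difference AF₁ − AF₂, standardized
  genome-wide; two-sided p.
* **meta-SS** — Stouffer-style combination: each test's p becomes
  Z = Φ⁻¹(1 − p) and the per-SNP scores combine as Zᵢ = ΣZ / k
  (as-printed mode) or ΣZ / √k (the textbook Stouffer rule; both are
  provided, see the vignette), with combined p = 1 − Φ(Zᵢ). Candidate
  regions are runs of ≥ 5 significant SNPs (−log₁₀ p ≥ 4) separated by
  ≤ 500 kb.
* **Hp / ZHp** — pooled heterozygosity of sliding windows (100 kb nominal,
  10 kb step, extended by their uncovered base count):
  Hp = 2 Σn_MAJ Σn_MIN / (Σn_MAJ + Σn_MIN)², Z-transformed genome-wide;
  windows with ZHp ≤ −4 merge into sweep regions.
* **ΔAZ** — per-SNP deviation of mean zebu local-ancestry dosage from the
  genome-wide mean; regions whose significant SNPs have a median ΔAZ more
  than one SD from zero are classified as zebu-ancestry excess or
  deficiency.
* **Region algebra** — cross-population sharing (≥ 1 bp overlap),
  fine-mapping by intersection with the reduction in size, gene/QTL
  annotation with gene-desert flagging, and variant-origin classification
  (zebu / taurine / undefined) against two outgroup sequence panels.
* **Simulator** — Balding–Nichols ancestral divergence, Markov ancestry
  tracts (stationary proportion α, switch rate g·r per bp), copy-based
  selective sweeps, and Poisson/binomial pooled read sampling with coverage
  gaps, so every stage is testable without external data.

All coordinates are 1-based with region size defined as `end − start`; BED
import/export converts explicitly.

## Worked example

Plant a hard sweep (derived allele at 90%, 150 kb shared haplotype) on a
synthetic admixed chromosome, scan it, and call candidate regions:

```r
library(admixscan)

cfg <- sim_config(n_snps = 2000, n_ind = 50,
                  sweep = list(locus = 1000, final_freq = 0.9, length_bp = 150000),
                  seed = 7)
freqs <- simulate_ancestral_freqs(cfg)
pop   <- simulate_admixed(cfg, freqs)
swept <- impose_sweep(pop$haplotypes, cfg$sweep, seed = 9)
ref   <- simulate_admixed(cfg, freqs, seed = 1007)$haplotypes

tracks <- list(
  iHS = ihs(swept, population = "KEASZ"),
  Rsb = rsb(swept, ref, population = "KEASZ"),
  dAF = delta_af(as_genotype_matrix(swept), as_genotype_matrix(ref))
)
meta    <- stouffer_combine(track_pvalues(tracks), meta_config())
regions <- call_regions(meta)
regions
#>   chrom   start     end   size n_snps   score provenance
#> 1     1 4996878 5140537 143659     24 12.3258 metaSS:pop
```

One region is called, spanning 24 significant SNPs over 143,659 bp with a
peak −log₁₀ p of 12.3 — and it contains the planted sweep locus
(position 5,069,607). The pooled-sequencing scan finds the same sweep as a
ZHp trough:

```r
pool <- simulate_pooled_reads(swept, depth = 20, gap_fraction = 0.05,
                              seed = 11, chrom_length = cfg$chrom_length)
zw <- zhp_transform(window_hp(pool$counts, pool$mask))
sweep_regions(zw)
#>   chrom   start     end   size n_snps     score provenance
#> 1     1 4970001 5180001 210000     12 -5.772229   ZHp:pool
```

Twelve overlapping significant windows merge into one 210 kb region with
mean ZHp −5.77 around the same locus. Local-ancestry classification of a
planted zebu-excess tract:

```r
cfg <- sim_config(n_snps = 2000, n_ind = 50, seed = 21)
sim <- simulate_admixed(cfg, simulate_ancestral_freqs(cfg))
dos <- sim$ancestry$dosage
tract <- sim$ancestry$pos >= 4.5e6 & sim$ancestry$pos <= 5.5e6
dos[tract, ] <- pmin(1, dos[tract, ] + 0.2)   # plant a zebu-ancestry excess
daz <- delta_az(local_ancestry_matrix(sim$ancestry$chrom, sim$ancestry$pos, dos))
med <- region_daz(genomic_regions("1", 4.5e6, 5.5e6), daz, sim$ancestry$pos[tract])
sprintf("median dAZ = %.3f (SD = %.3f) -> %s",
        med, attr(daz, "sd_daz"), classify_daz(med, attr(daz, "sd_daz")))
#> "median dAZ = 0.097 (SD = 0.061) -> excess"
```

The tract's median ΔAZ of +0.097 exceeds one genome-wide SD (0.061), so the
region is classified as carrying an excess of zebu ancestry.

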