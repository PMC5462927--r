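---
title: "Selection scans in admixed cattle: methods and design notes"
author: "admixscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selection scans in admixed cattle: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the statistics it implements, the
modelling assumptions behind its synthetic-data generator, and the design
choices made where the methodology left genuine freedom. Nothing here states
an empirical result that the test suite does not itself compute.

## The scientific setting

African zebu cattle are stabilized hybrids of Asian zebu and African taurine
ancestry, with roughly 70% zebu autosomal background in East African
populations and an admixture age on the order of 500 generations. Selection
since admixture leaves several distinct marks on such a genome:

1. a favoured allele drags a long shared haplotype to high frequency
   (detectable by EHH statistics within and between populations),
2. its frequency diverges from related populations not under the same
   pressure (allele-frequency differentiation),
3. heterozygosity collapses locally in sequencing data (pooled
   heterozygosity), and
4. if the favoured variant is ancestry-specific, the local zebu/taurine
   mosaic is distorted around it (local-ancestry deviation).

No single signal is decisive; the package's pipeline computes all of them on
a shared coordinate system and combines the haplotype- and frequency-based
tests into one composite score per SNP.

## Per-SNP statistics

### EHH, iHH and iHS

For a focal SNP and allele class (0 = ancestral, 1 = derived after
polarization against an outgroup-derived ancestral-allele table), EHH at
distance $d$ is the probability that two randomly drawn carrier haplotypes
are identical-by-state over the whole interval from the focal SNP to $d$:

$$\mathrm{EHH}(d) = \frac{\sum_h \binom{n_h}{2}}{\binom{n_c}{2}},$$

where the $n_c$ carriers split into groups of $n_h$ identical haplotypes.
iHH is the trapezoidal integral of the decay curve over physical distance,
computed separately for each arm and summed. A uniform recombination map
(1 cM = 1 Mb) is assumed throughout, so base pairs are the integration
axis; no genetic map is consumed.

Numerical choices:

* **Truncation floor** (default 0.05): each arm stops at the first point
  where EHH drops below the floor; the partial trapezoid ending at that
  point is included. The floor prevents the integral from accumulating
  noise from the asymptotic tail.
* **Censoring**: an arm that reaches the chromosome edge, or an inter-SNP
  gap larger than `max_gap` (default 200 kb), while still above the floor
  is *censored*; censored SNPs are excluded from standardization by
  default (`include_censored = FALSE`) because their iHH is a lower bound,
  not an estimate.
* **Standardization bins**: raw iHS = ln(iHH$_A$/iHH$_D$) is standardized
  to mean 0 / SD 1 within derived-allele-frequency bins of width 0.05
  (configurable); bins with fewer than two usable SNPs yield no score.
  The bin width is not dictated by the methodology this package follows;
  0.05 matches common practice in EHH software.
* SNPs with within-population MAF < 0.05 are skipped — the statistic has
  essentially no power near fixation — as are SNPs with fewer than two
  carriers of either allele.

The two-sided p-value is $1 - 2\,\lvert\Phi(z) - 0.5\rvert$, computed in
the tail as `2 * pnorm(abs(z), lower.tail = FALSE)` for precision, and
clamped to $[10^{-300}, 1]$ before $-\log_{10}$.

### Rsb

The between-population statistic uses the allele-agnostic *site* EHH:
pair-homozygosity over **all** haplotypes of a population, with identity
measured over the closed interval including the focal allele itself (the
curve still starts at 1 at offset zero). Its integral iES is computed per
population with the same truncation rules, and

$$\mathrm{Rsb} = \ln(\mathrm{iES}_{\text{focal}} / \mathrm{iES}_{\text{reference}})$$

is standardized genome-wide (mean-centred by default; median-centring — the
convention of some EHH packages — is available via `center = "median"`).
The p-value is one-sided upper-tail: only unusually long haplotypes in the
focal population are of interest. Degenerate input with zero variance
(e.g. identical populations) yields zero scores with a warning rather than
an error, so that the raw antisymmetry rsb(a,b) = −rsb(b,a) remains
observable.

### ΔAF

The reference allele is the "first allele" whose frequency difference is
taken; flipping any SNP's allele labels flips the sign of its raw value.
Standardization is genome-wide with the sample SD. Frequency-identical
populations are rejected as degenerate, since a zero SD makes every score
undefined.

### meta-SS

Each defined test p-value becomes $Z = \Phi^{-1}(1 - p)$ and the per-SNP
scores are combined as

$$Z_i = \frac{\sum Z}{k} \quad (\texttt{mode = "paper"}) \qquad
  Z_i = \frac{\sum Z}{\sqrt{k}} \quad (\texttt{mode = "stouffer"}),$$

with combined $p = 1 - \Phi(Z_i)$ and $k$ the number of tests defined at
that SNP ($k$ adapts per SNP: iHS is commonly undefined at low MAF). The
two modes differ materially: dividing by $k$ is the formula as printed in
the analysis this package reimplements, but under the null it gives a
combined $Z$ with SD $1/\sqrt{k}$ — a conservative, super-uniform p-value.
Dividing by $\sqrt{k}$ is Whitlock's standard Stouffer rule, under which
the combined p is exactly uniform (the test suite verifies both
behaviours by Kolmogorov–Smirnov statistics at $n = 10^5$). The package
defaults to the as-printed $k$ divisor for fidelity and exposes the
standard rule one argument away; reports should state which mode was used.

### Candidate regions

A candidate region is a run of at least `min_snps = 5` significant SNPs
($-\log_{10} p \ge 4$) in which consecutive *significant* SNPs are
separated by at most `max_gap_bp` = 500 kb. "Adjacent" is read as adjacency
among significant SNPs: non-significant SNPs in between do not break a run.
The alternative reading — adjacency on the genotyping array, where any
intervening non-significant SNP breaks the run — would make the rule almost
unsatisfiable at a 4-sigma threshold on a dense chip and is available as
`adjacency = "array"`. Region bounds are the first and last significant SNP
positions, not midpoints to flanking SNPs; the region score is the peak
$-\log_{10} p$.

### Coordinates and interval algebra

Internally all coordinates are 1-based and a region's size is defined as
`end − start` exactly. This convention was fixed by requiring exact
agreement with every printed size and reduction in the published
fine-mapping table the acceptance suite replays (22 interval pairs, 18 with
positive reduction), and it makes `end` behave as an exclusive bound:
intervals that merely touch do not overlap, and overlap length is
`min(ends) − max(starts)`. BED export converts to 0-based half-open
explicitly (`start − 1`, `end`), and `read_intervals(write_regions(x))` is
an exact bijection. Fine-mapping intersects a region with an overlapping
region found in another population; the reduction in size is
`original − intersection`, zero when the shared region contains the
original.

## Pooled heterozygosity

$$H_p = \frac{2\,\Sigma n_{MAJ}\,\Sigma n_{MIN}}{(\Sigma n_{MAJ} + \Sigma n_{MIN})^2}$$

over the summed major/minor read counts of the SNPs in each window
(bounded by $[0, 0.5]$, maximal at balance, invariant to uniform depth
scaling). Windows are 100 kb advanced by 10 kb, and each window is extended
by the number of bases of its *nominal* span that the coverage mask marks
uncovered. The extension is single-pass: gaps inside the appended extension
are not re-examined. An iterative fixed point would re-extend until no new
gap appears; the one-line description of the procedure this reimplements
supports no iteration, and at realistic gap fractions the second-order
correction is tiny. Without a mask the extension is disabled with a
prominent warning.

ZHp standardizes the Hp of all non-empty windows with the population
(divide-by-$n$) SD — at genome-scale window counts the $n$ vs $n-1$ choice
is far below the reporting precision, and the choice is stated here rather
than hidden. Empty windows carry no score and can never be significant; no
minimum SNP count is imposed beyond non-emptiness, matching the
methodology's silence (a `min-snps`-style filter would suppress the
shallow-coverage artifacts that dominate the lower tail at low depth, but
also genuine near-fixed windows). Windows at or below ZHp = −4 are merged
by interval union — including bookended windows — using their extended
ends; the region score is the mean ZHp of its constituent windows.

## Local-ancestry deviation (ΔAZ)

ΔAZ at a SNP is its mean zebu dosage across individuals minus the grand
mean over all SNPs; the mean of ΔAZ is therefore zero by construction (the
acceptance suite asserts this to $10^{-12}$, and the acceptance script
recomputes it from a fresh simulation). Dosages are consumed from an
external local-ancestry tool's per-SNP output, never inferred here; the
genome-wide zebu proportion used for centring is always the empirical grand
mean of the supplied dosages rather than any externally reported admixture
proportion, because the two can differ (0.70 vs 0.76 in the source data's
two estimators) and the deviation track must be internally consistent.

A region's ΔAZ is the median over the meta-SS-significant SNPs inside it
(even counts: mean of the two middle values). Classification uses the SD of
the per-SNP ΔAZ distribution with strict boundaries: excess above +1 SD,
deficiency below −1 SD, typical otherwise — "more than" one SD is read as
exclusive.

## Variant origin

A variant observed in the admixed population is of probable zebu origin if
absent from both African taurine outgroup panels, of probable taurine
origin if present in both, and undefined if present in exactly one —
presence in a single panel is treated as insufficient evidence for the
conjunction the taurine label asserts. Any called occurrence counts as
presence; no minimum allele count is imposed. The three labels partition
all observed variants.

## Quality control

SNP filters remove markers with MAF < 0.05 or call rate < 95%, both
strict: boundary values survive, matching the stated "<" thresholds. A SNP
with every call missing is a call-rate failure only (its MAF is
undefined). Sample filters first drop samples below 95% call rate, then
resolve pairs with IBS > 95% — IBS being the mean of
$(2 - |g_i - g_j|)/2$ over mutually non-missing SNPs — greedily by
descending IBS, removing the lower-call-rate member; ties remove the
later sample in input order (the methodology describes only pairs, so the
clique resolution order is a package choice, and the greedy result is
checked against exhaustive minimal removal in the tests). Whether MAF
should be computed per population or across the full multi-breed panel is
not specified upstream; the functions operate on whatever genotype matrix
they are given, so either policy is a matter of what the caller passes.

## The synthetic-data generator

The generator produces data with the statistical structure each stage
assumes, not a population-genetic forward simulation:

* **Ancestral divergence**: per SNP, a shared frequency
  $p \sim U(0.05, 0.95)$ and population frequencies from the
  Balding–Nichols $\mathrm{Beta}\!\left(p\frac{1-F}{F}, (1-p)\frac{1-F}{F}\right)$
  distribution. The default $F_{ST} = 0.1$ is a realistic indicine–taurine
  differentiation for chip markers; Hudson's estimator recovers it on
  simulated panels in the tests.
* **Admixture**: each haplotype is a Markov path over {zebu, taurine} with
  stationary zebu probability $\alpha = 0.7$ (the admixed population's
  genome-wide proportion) and redraw probability $1 - e^{-g r d}$ between
  adjacent SNPs, with $g = 500$ generations and $r = 10^{-8}$ per bp per
  generation (1 cM = 1 Mb). Alleles are drawn independently from the tract
  ancestry's population frequency. One synthetic chromosome (default
  10 Mb, 5,000 SNPs, 50 diploids) stands in for a genome; multi-chromosome
  fixtures are built by concatenating seeds.
* **Sweeps** are emulated by copying one randomly chosen derived-allele
  carrier haplotype over a chosen tract into a fraction `final_freq` of
  haplotypes. This creates exactly the long shared haplotype and local
  heterozygosity loss the detectors target, at a tiny fraction of the cost
  of forward simulation — but it is an emulation: no partial recombination
  onto the swept background, no allele-age structure.
* **Pooled reads**: per-site depth Poisson (default mean 11, the source
  experiment's coverage), allele-1 reads Binomial(depth, frequency), a
  two-read minimum to report a site, and a coverage mask with one uniform
  gap per equal-width block totalling `gap_fraction` of the chromosome.

Every generator is deterministic given the mandatory seed.

**What passing tests do and do not show.** The simulated panels carry
admixture LD (from ancestry tracts) but no background LD between sites
given ancestry. Real chip data has strong background LD: EHH decays more
smoothly there, and standardized scores are closer to Gaussian. On the
LD-free panels the standardized iHS/Rsb distributions are mildly
leptokurtic (excess kurtosis around 1), so the $4\sigma$ tail carries
roughly twice the Gaussian mass — the calibration test bounds the tail at
0.25% rather than the 0.1% a strictly normal score would give. This
inflation is a property of the panel, not of the estimators (EHH is
verified SNP-by-SNP against brute-force pair counting, and the
standardizations against an independent one-pass oracle), and it does not
propagate to region calling: five clustered significant SNPs are required,
and the null-calibration tests observe zero called regions across seeds at
the default thresholds. Power numbers (sweep recovery rates) on the
copy-based sweeps should likewise be read as detector sanity checks, not
as power estimates for real demographies.

**Problem sizes in the tests.** The suite runs the full pipeline at 2,000
to 10,000 SNPs and 40 to 100 haplotypes, 20 replicates for the power and
calibration suites, and 100,000 draws for the meta-analysis uniformity
checks — sizes at which every property asserted is stable across seeds
while the whole suite completes in minutes on one CPU.

## Known limitations

* Integration is on physical distance under a uniform map; no genetic-map
  input is accepted.
* Phasing is assumed done upstream; haplotype input forbids missing calls.
* The pooled-heterozygosity stage consumes called per-site counts; read
  alignment, variant calling and their error models are out of scope.
* Local-ancestry dosages are taken at face value from the upstream tool;
  their uncertainty is not propagated into ΔAZ classification.
* The as-printed meta-analysis mode is conservative (see above); cross-mode
  comparability of "number of candidate regions" should not be assumed.
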