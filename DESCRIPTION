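Package: admixscan
Title: Selection-Signature Scans in Admixed Cattle Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genome scans for signatures of positive selection in admixed
    (zebu x taurine) cattle populations. Implements extended haplotype
    homozygosity statistics (iHS and Rsb), inter-population allele-frequency
    differentiation (dAF), a Stouffer Z-score meta-analysis that combines the
    per-SNP p-values of the three tests (meta-SS), pooled-heterozygosity
    sliding-window sweep scans (Hp/ZHp) from pooled sequencing read counts,
    candidate-region calling with cross-population sharing and fine-mapping,
    local-ancestry excess/deficiency classification (dAZ), and variant-origin
    assignment against outgroup sequence panels. A synthetic-data module
    simulates admixed haplotypes with Markov ancestry tracts, divergent
    ancestral allele frequencies, planted selective sweeps and pooled
    short-read sampling, so every stage of the pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    IRanges,
    S4Vectors,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
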