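Package: stratlink
Title: Heterogeneity-Aware Stratified Nonparametric Linkage Analysis for Multiplex Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-level stratification of multiplex pedigrees by proband
    sub-phenotype, sibling concordance and gender, followed by nonparametric
    multipoint allele-sharing linkage analysis (Lander-Green inheritance-vector
    HMM, S_pairs scoring, Kong-Cox one-parameter LOD), randomized-cohort
    permutation for study-wide significance across the stratified subgroup
    analyses, and a stratified transmission disequilibrium test. Reads and
    writes PLINK-style PED/MAP pedigree files, applies marker-level quality
    control (founder MAF, missingness, exact Hardy-Weinberg, Mendelian errors),
    and ships a gene-dropping simulator of multiplex-family cohorts with
    subtype labels and subgroup-specific linked risk loci so that every
    pipeline stage is testable on synthetic data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
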