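Package: cnvdrop
Title: Copy Number Genotyping and Disease Association from Digital and
    Quantitative PCR
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Absolute copy number quantification from droplet digital PCR
    well counts via the Poisson occupancy model, relative quantification
    from qPCR cycle-threshold replicates (delta-delta-Ct against a diploid
    calibrator), resolution of continuous copy number estimates into
    discrete bi-allelic CNV genotypes, Mendelian segregation checking of
    CNV alleles in pedigrees with two-locus haplotype consistency
    screening, and allele-level case/control association statistics (odds
    ratio, risk ratio, two-tailed Fisher exact test). Includes simulators
    for droplet partitioning, Ct replicates, multi-generation pedigrees
    and case/control cohorts so that every pipeline stage can be validated
    against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    cluster,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
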