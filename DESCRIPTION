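Package: poolscan
Title: Family-Pool Candidate-Gene Association Analysis for Insecticide Resistance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of isofemale family-pool candidate-gene
    association studies of insecticide resistance in mosquitoes: per-SNP
    dye-bias estimation from individual heterozygotes and QC filtering,
    pooled allele-frequency estimation from two-channel genotyping signals,
    PCA-based detection and correction of inversion-localized population
    stratification, rank-transformed partial-correlation association
    scanning with stepwise variance decomposition and power calculations,
    and replication-stage allelic odds-ratio testing, tag-SNP selection and
    temporal allele-frequency tracking. Includes a forward simulator of the
    isofemale-family bioassay design (Mendelian families, a polymorphic
    chromosomal inversion, liability-scale SNP effects, humidity effects,
    and dye-biased two-channel array signals) so the whole pipeline is
    testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    yaml,
    jsonlite
Config/testthat/edition: 3
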