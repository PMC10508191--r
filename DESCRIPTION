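Package: invTyper
Title: Inversion Genotyping from SNP Data and Inversion-Phenotype Association
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies chromosomal inversion genotypes (NN/NI/II) from SNP
    genotype posteriors using linkage-disequilibrium-weighted similarity
    scores against reference haplotype-family genotype frequencies, with
    call-rate and score-difference quality control and tag-SNP fallback
    genotyping. Provides the downstream association pipeline: genotype and
    sample quality control, genetic-relationship-matrix relatedness pruning,
    covariate and global-measure residualization, rank-based inverse normal
    transformation, joint additive regression of phenotypes on inversion
    dosages, X-linked dosage-compensation codings, eigenvalue-based effective
    number of independent tests, stepwise SNP-conditional adjustment, and
    discovery-to-replication generalization statistics (error-adjusted beta
    correlation and sign-concordance binomial tests). A seeded synthetic-data
    generator emulates two-haplotype-family inversion loci so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
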