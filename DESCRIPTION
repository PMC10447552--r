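Package: mnlpkit
Title: Genotyping and Regulatory Dissection of Multi-Nucleotide Length Polymorphisms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for establishing a multi-nucleotide length polymorphism
    (MNLP) as a candidate causal GWAS variant. Implements
    allele-specific-reference genotyping from amplicon reads and from
    sequencing coverage patterns, two-locus EM haplotype estimation with D'/r2
    linkage statistics and recombinant-haplotype eQTL dissection, a haplotype
    beta-binomial allelic-imbalance (chromatin QTL) test with per-individual
    overdispersion, coverage-based discovery of candidate complex variants,
    and a TWAS-style summary-statistic association of predicted
    complex-variant dosage with disease risk, including LD-based conditioning
    and approximate-Bayes-factor colocalization. A seeded synthetic-data
    module generates every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    Rcpp,
    glmnet,
    jsonlite,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo: Rcpp
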