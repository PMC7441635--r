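Package: xkin
Title: Expected and Realized Relationship Matrices for the X Chromosome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative-genetics machinery for X-linked loci: the pedigree-based
    X-chromosome relationship matrix S of Fernando and Grossman with its sparse
    inverse and a metafounder variant, the genomic relationship matrix G^X built
    from sex-aware gene content with explicit dosage-compensation scaling, the
    position-dependent expected relationship matrix P^r for the pseudo-autosomal
    region, and the single-step matrix H^X combining genotyped and ungenotyped
    individuals. Includes restricted maximum likelihood estimation of the
    heritability of gene content (a genotype/pedigree quality-control statistic),
    bivariate REML estimation of the dosage-compensation factor k from phenotypes
    of both sexes, dimensionality and relationship-class diagnostics, and a
    gene-dropping simulator used as a Monte-Carlo oracle for every expected
    relationship formula.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
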