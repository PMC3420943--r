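Package: popallele
Title: Allele Calling, Population Differentiation, and
    Expression-Phenotype Association for Small Gene Families
Version: 1.0.0
Authors@R:
    person("popallele", "developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis chain for linking allelic variation and expression of
    a small gene family to a quantitative chemical phenotype across
    structured populations.  Collapses noisy clone sequences into consensus
    alleles with a nucleotide-difference merge rule, assigns allele groups
    by p-distance UPGMA with bootstrap support, annotates loss-of-function
    lesions and tests their enrichment, estimates multiallelic
    Weir-Cockerham F_ST with in-silico diploid resampling of
    expression-inferred genotypes, screens pairwise dN/dS (Nei-Gojobori
    1986), and fits transform-specified fixed- and mixed-effect models of
    compound amounts on allele-group expression with backward stepwise AIC
    simplification.  Includes a seeded synthetic-data generator emulating
    diploid individuals in an island-model metapopulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    lme4,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
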