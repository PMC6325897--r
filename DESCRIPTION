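Package: mamutkit
Title: Mutation-Accumulation Sequencing and Life-History Analysis Toolkit
Version: 0.1.0
Authors@R:
    person("MA", "Toolkit Developers", email = "mamutkit@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for mutation-accumulation (MA) experiments in
    cyclically parthenogenetic organisms such as Daphnia pulex. Identifies de
    novo single-nucleotide mutations (SNMs), multinucleotide mutations (MNMs)
    and small INDELs from multi-line allele read-count tables using
    callable-site rules and exact binomial consistency filters; assembles,
    sizes and mechanistically classifies loss-of-heterozygosity (LOH) events
    from Het-Hom site patterns and standardized relative read depth; converts
    calls and callable masks into per-line and pooled mutation rates, spectrum
    statistics and treatment comparisons; and estimates life-history
    mutational parameters (intrinsic rate of increase via the Euler-Lotka
    equation, mutational bias by anchored weighted regression, mutational
    coefficients of variation and heritabilities by variance partitioning).
    A synthetic MA-experiment generator with recorded ground truth makes every
    stage verifiable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
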