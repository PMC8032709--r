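Package: clonediv
Title: Clonal Genetic Diversity from Somatic Single-Nucleotide Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying intra-cultivar (clonal) genetic diversity in
    vegetatively propagated crops from somatic single-nucleotide variants
    (SNVs). Implements a stringent multi-caller consensus variant filter
    (three-caller intersection, depth and variant-allele-frequency windows,
    strand- and read-position-bias tests, read edit-distance filter),
    classification of retained variants into cultivar-level SNPs and
    single-clone (SC) or shared (Sh) SNVs, genotyping-panel design from
    classified SNVs, multilocus genotype collapsing, median-joining networks,
    neighbor-joining trees with bootstrap supports, principal coordinates
    analysis and AMOVA with the Phi-PT statistic on codominant genotypic
    distances. Includes a synthetic-data generator that emulates resequenced
    clone panels with planted somatic mutations (chimeric L1/L2 variant-allele
    frequencies, transition excess, imperfect callers) and two-lineage
    genotyping cohorts, so the whole pipeline can be exercised end-to-end with
    known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    seqinr,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
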