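Package: oakdiv
Title: Population Genomics, Phylogenomics and Shared Ancestral Variation in White Oaks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for whole-genome population genomics and phylogenomics of
    highly diverse outcrossing trees such as white oaks (Quercus). Includes a
    multispecies-coalescent simulator of diploid resequencing datasets with
    incomplete lineage sorting, pseudo-reference construction from variant
    calls, nucleotide diversity and the Reich-Patterson F_ST estimator, a
    shared-ancestral-variation statistic, neighbor-joining window trees with
    gene and site concordance factors, penalized-likelihood divergence dating
    with an ancestral-polymorphism correction based on nucleotide diversity,
    and genomic interval accounting for resistance-gene clusters and
    structural variants.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    vcfR,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    methods,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn
Config/testthat/edition: 3
RoxygenNote: 7.3.3
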