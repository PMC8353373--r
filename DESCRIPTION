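Package: bovarch
Title: Genome Architecture of Cattle Breeds: LD Decay, Effective
    Population Size, Runs of Homozygosity and Breed Structure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for multi-breed SNP genotype panels:
    quality control of PLINK-style text genotypes, pairwise composite
    linkage disequilibrium (r2) and its decay with distance under Sved's
    model, LD-based effective population size across past generations,
    sliding-window detection of runs of homozygosity (ROH) and of ROH
    islands shared by most individuals of a population, and
    allele-frequency based breed structure summaries (Euclidean
    distances, neighbor-joining trees, PCA). Includes a forward
    Wright-Fisher simulator with recombination so every stage can be
    validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ape,
    cluster,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Config/testthat/edition: 3
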