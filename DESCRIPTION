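Package: popgenarray
Title: Population Genetics of Dense SNP Array Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis of diploid biallelic SNP genotypes from dense arrays
    across multiple populations: quality control (minor allele frequency,
    call rate, Hardy-Weinberg exact test), per-population diversity
    (observed and expected heterozygosity, SNP-ascertained nucleotide
    diversity), pairwise Weir-Cockerham FST with a four-level
    classification, two-locus EM-based linkage disequilibrium and LD-decay
    curves, PLINK-style sliding-window runs of homozygosity with genomic
    inbreeding coefficients and ROH islands, LD-based historical and
    contemporary effective population size, and an effective-sex-ratio
    estimator contrasting drift on sex-linked versus autosomal markers.
    Includes a two-sex Wright-Fisher forward simulator with recombination
    and recorded ground truth for validating every estimator, plus a
    configurable end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    vcfR,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
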