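Package: clovermap
Title: Multi-Population Linkage Map Integration for Allotetraploid White
    Clover
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for building and integrating genetic linkage maps of
    allotetraploid white clover (Trifolium repens, 2n=4x=32) from
    microsatellite (SSR) marker data in double pseudo-testcross F1
    populations.  Covers SSR array mining with class-specific repeat
    thresholds and primer feasibility screening, two-point recombination
    and LOD estimation for outbred (CP-type) populations, LOD-threshold
    grouping, heuristic marker ordering with Kosambi distances,
    parental-consensus and multi-population map integration via joining
    loci, designation of single-locus homoeologue-specific markers from a
    diversity panel, inter-population homoeologue pairing from marker and
    allele-size evidence, segregation-distortion scans, genome length,
    coverage and saturation statistics, and normalized-coordinate synteny
    alignment against a reference genome.  A synthetic allotetraploid
    population generator with full truth labels makes every stage testable
    without external genotype data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
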