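Package: haplogeo
Title: Chloroplast Haplotype Phylogeography, Differentiation Statistics,
    and Landscape Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for range-wide chloroplast-DNA phylogeography of trees
    and other plants: indel coding and haplotype collapsing of aligned
    cpDNA spacers, median-joining haplotype networks, per-site haplotype
    and nucleotide diversity, Pons & Petit (1996) ordered/unordered
    differentiation statistics (hS, hT, GST, NST) with the NST-vs-GST
    permutation test, hierarchical distance-based AMOVA, spatially
    constrained SAMOVA by simulated annealing, principal coordinate
    analysis, Mantel isolation-by-distance tests, strict-clock divergence
    estimates, niche-overlap statistics (Schoener's D, Warren's I) with a
    randomization identity test, and least-cost dispersal corridors over
    friction surfaces. Ships a worked multi-country sampling-site dataset
    and synthetic-data generators for every input format.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    geosphere,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
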