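Package: phyloconsensus
Title: Branch-Weighted Phylogenetic Consensus Design and Thermostability Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for non-biased (branch-length-weighted) phylogenetic
    consensus design of stabilizing protein substitutions. Reads and filters
    protein family alignments, computes a minimum-ungapped-length p-distance,
    builds neighbor-joining trees, roots them with an outgroup, derives
    per-sequence weights from branch lengths so that over-represented
    subfamilies do not dominate, nominates candidate consensus substitutions
    above a frequency cutoff, and screens them against a query structure
    (active-site distance, side-chain hydrogen bonds and salt bridges).
    Also fits the standard thermostability readouts from assay curves:
    first-order inactivation half-life, T50 from a Boltzmann sigmoid, and
    melting temperature from the first-derivative peak of a nanoDSF
    fluorescence ratio, plus fold-improvement summaries across variants.
    A seeded simulation module generates families evolved along a known tree
    and synthetic assay curves for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    bio3d,
    minpack.lm,
    phangorn,
    phytools,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
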