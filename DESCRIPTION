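Package: dotangle
Title: Displacement-Optimized Tanglegrams for Rooted Phylogenetic Trees and
    Networks
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes tanglegram layouts for pairs of rooted phylogenetic
    trees or networks on overlapping taxon sets by heuristically minimizing
    taxon displacement (the Spearman footrule between the rank orders of
    shared taxa on the two sides) and reticulate displacement (the vertical
    extent of reticulation edges within each network).  Provides an extended
    Newick (eNewick) reader and writer with support for transfer-acceptor
    edges, backbone-tree reduction via lowest stable ancestors, a
    neighbor-net based presorting heuristic, one-sided and two-sided
    optimization by exhaustive child-permutation search and simulated
    annealing, seeded parallel restarts, a synthetic benchmark generator,
    and plain-text/JSON/SVG reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
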