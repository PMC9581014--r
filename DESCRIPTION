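Package: efloop
Title: Descriptors of Elementary Functional Loops and Objective-Function Loop Grafting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives per-position statistical descriptors of 30-residue
    elementary functional loops from protein structures (sequence profiles,
    backbone dihedral mixture models, van der Waals contact and hydrogen-bond
    count distributions, with intra-loop and loop-to-fold interactions encoded
    separately), and uses a weighted multi-feature objective function to find,
    assemble and graft the best-fitting realization of a descriptor into a
    target protein scaffold, including recombinant loops merged from segments
    of several source structures. Ships a synthetic-fixture generator
    (ideal-geometry peptides, planted-motif structure families,
    profile-sampled sequence databases) so the whole pipeline runs without
    external downloads.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    mclust,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
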