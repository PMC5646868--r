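Package: ligapath
Title: Monte Carlo Exploration of Ligand Migration Paths in Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to map how ligands and co-ligands travel between a
    buried enzyme active site and bulk solvent. Implements a rigid-body
    Monte Carlo migration explorer with Metropolis filtering, spawning
    (restart-at-best) trajectory management, adaptive epoch restarts
    biased toward sparsely populated clusters, and anisotropic network
    model backbone moves over a pluggable energy oracle. Companion
    analyses cover per-residue fluctuation (RMSF), protein-ligand atom
    contacts, binding-energy versus distance profiles, migration-path
    assignment, solvent-accessible surface area and subunit-interface
    residue classification, and an alignment-column conservation
    statistic (conserved / similar / dissimilar and subfamily-discordant
    positions) for flavoenzyme subfamily comparisons. A synthetic-data
    generator provides a two-chain receptor with designed channels, an
    analytic energy oracle, trajectories with known ground truth, and
    subfamily alignments with planted per-column categories, so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    Biostrings,
    graphics,
    grDevices,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
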