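Package: cofanet
Title: Cofactor Networks and Electron-Transfer Pathways in Metalloenzyme Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-analysis of atomic models of multi-cofactor redox enzymes:
    detection of iron-sulfur clusters, flavins, nicotinamide cofactors and
    bimetallic NiFe centers in PDB/mmCIF models; center-to-center and
    edge-to-edge (side-to-side) inter-cofactor distances; threshold
    electron-transfer graphs with branch-point and dead-end classification;
    simple-path enumeration and minimax (bottleneck) pathways; least-squares
    superposition and rigid-body domain-rotation angles between conformational
    states; cofactor-pair distance gating between states; and elemental
    (Fe:Ni) stoichiometry checks. Includes a seeded synthetic-structure
    generator that realizes user-specified inter-cofactor distance
    constraints, used to emulate the cofactor constellation of an
    electron-bifurcating NiFe-hydrogenase in apo, bifurcation-ready and
    post-bifurcation conformations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    igraph,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
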