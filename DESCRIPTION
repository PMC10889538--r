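Package: confens
Title: Conformational-Ensemble Analysis of Protein Dynamics and Cryptic Pockets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for characterising protein conformational ensembles
    from molecular-dynamics-style multi-model structures: least-squares
    superposition with RMSD/RMSF/radius-of-gyration statistics, geometric
    hydrogen-bond and hydrophobic-contact detection, secondary-structure
    assignment with reduced-alphabet Jaccard clustering, reference-based
    RMSD ensemble clustering, Cartesian principal component analysis with
    cross-correlation maps, free-energy landscapes on principal-component
    reaction coordinates with well decomposition, and grid-based detection
    of transient (cryptic) cavities.  Includes a synthetic-ensemble
    generator with planted ground truth so every stage is testable without
    large trajectory archives.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    cluster,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
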