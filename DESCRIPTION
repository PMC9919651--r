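Package: ProtacSAR
Title: Structure-Degradation Relationship Mining for PROTAC Degraders
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A ligand-based workflow for mining structure-degradation
    relationships in PROTAC (proteolysis-targeting chimera) degradation
    data reported as percent degradation at two concentrations.
    Implements Bemis-Murcko scaffold and skeleton extraction, hashed
    sphere fingerprints with count Tanimoto similarity, matched molecular
    pair (MMP) clustering, degradation-cliff detection with a
    dual-concentration consistency rule, tripartite
    warhead/linker/E3-ligand decomposition with linker-degradation
    parabola fits, seven permeability-related 2D descriptors (including
    Ertl TPSA and Kier's flexibility index PHI), and a binary activity
    classification harness with cross-validation, external validation,
    Y-randomization and attribute ranking. A synthetic PROTAC dataset
    generator with planted ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    randomForest,
    e1071,
    class
Suggests:
    testthat (>= 3.0.0),
    ChemmineOB,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
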