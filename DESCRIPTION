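Package: LogicCascade
Title: Gene Logic Networks and Degree-Strength Cascading Failure Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers directed, weighted gene logic networks from binary
    (presence/absence) expression matrices using first- and second-order
    uncertainty coefficients, refines in-/out-degree and degree-strength
    accounting for the ten two-input Boolean regulation types, and simulates
    load-capacity cascading failures triggered by single-node deletion.
    Provides robustness statistics (cascade size ratios, largest cascade
    ratio, cumulative cascade-probability curves), logic-doublet motif
    classification, seeded synthetic-data generators with planted logic
    relationships, and plain-text import/export of matrices, networks and
    cascade outcomes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite, igraph
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'LogicCascade-package.R'
    'cascade.R'
    'io.R'
    'logic-core.R'
    'metrics-motifs.R'
    'network-build.R'
    'synthetic.R'
    'workflows.R'
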