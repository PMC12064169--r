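Package: ppiscorekit
Title: Pre- and Post-Processing for High-Throughput Protein-Protein
    Interaction Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automates the bookkeeping around large-scale protein-protein
    interaction (PPI) screens run with AlphaFold-Multimer-class structure
    predictors. Provides sequence cleaning and signal-peptide trimming,
    multiple-sequence-alignment depth quality control with shallow-MSA
    flagging, all-against-all and homo-oligomer job planning with
    memory-aware exclusion of oversized complexes, composite interaction
    scoring (iQ-score for hetero pairs, hiQ-score for homo-oligomers) built
    on upstream pi-score, ipTM_pTM and pDockQ values, a predicted-aligned-
    error (PAE) gate, distogram and interface-contact analysis of predicted
    complex structures, and report generation (score heatmap, interaction
    network with homo-oligomer annotations). A deterministic toy-cohort
    generator makes every stage testable without running a predictor.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    Biostrings,
    igraph,
    jsonlite,
    grDevices,
    graphics,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
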