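Package: flipms
Title: Fractionation-Based Limited-Proteolysis Interaction Marker Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for limited-proteolysis mass spectrometry
    (LiP-MS) of size-fractionated lysates. Identifies peptide markers of
    protein-protein interaction changes from fraction-wise peptide and protein
    intensity tables via protein-abundance-corrected, error-propagated one-way
    ANOVA; groups peptides into unique-region markers with molecular-weight
    based confidence classes; overlays the marker library onto perturbation
    LiP-MS experiments; scores marker proximity to protein-binding interfaces
    detected on multimeric structures by relative solvent-accessibility change;
    propagates interaction changes over protein-complex networks with
    personalized PageRank and walktrap clustering; and provides differential
    AP-MS interaction statistics. Includes a synthetic-data generator with
    known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    Biostrings,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
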