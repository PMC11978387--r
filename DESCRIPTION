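Package: abdocktools
Title: Post-Docking Analytics for Antibody-Antigen Complex Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytics for evaluating and re-ranking antibody-antigen docking
    poses. Standardizes model confidences into certainty values, derives
    pTM/ipTM scores from aligned-confidence probability distributions, and
    combines them with physics-based docking scores into an equal-weight
    composite used to re-rank poses. Scores poses against native complexes
    with DockQ components, classifies interface residues into core, rim and
    support regions from relative solvent accessibility, and computes an
    interface property panel (surface areas, stickiness, global atom density,
    surface complementarity). Benchmark utilities cover manifest enumeration,
    naive and confidence-guided model selection, top-N success rates with
    bootstrap intervals, and success/failure discriminant statistics. A
    synthetic fixture generator builds toy complexes, graded pose decoys and
    correlated confidence bundles so the full pipeline runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
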