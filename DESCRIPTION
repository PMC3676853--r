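Package: enmconf
Title: Elastic Network Analysis of Two-Domain Protein Conformer Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coarse-grained elastic network analysis of hinge-bending proteins
    observed in two conformations, such as the open and closed forms of
    bacterial periplasmic binding proteins. Builds Gaussian Network Model
    (GNM) Kirchhoff matrices and Anisotropic Network Model (ANM) Hessians
    from C-alpha coordinates, computes mean-square fluctuations and predicted
    B-factors with a fitted kBT/gamma scale, detects slow-mode hinge residues
    and fast-mode kinetically hot residues, derives cross-correlation and
    difference-distance maps, and measures the rigid rotation angle between
    two domains by two-stage least-squares superposition. A synthetic
    structure generator provides two-domain dumbbells with known linkers,
    rotation angles and noise-corrupted B-factors so every stage is testable
    against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
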