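Package: frontfish
Title: Quantifying RNA Accumulation at the Invasive Front of Leader Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Image-quantification and sequence-scanning toolkit for studies of
    subcellular RNA localization during collective 3D invasion. Computes
    per-spot normalized distances between manually annotated invasive and
    nuclear edges of leader cells with internal-control comparisons (Wilcoxon
    signed-rank, ANOVA/Dunnett, Kruskal-Wallis/Dunn), the isoperimetric
    "complexity" metric of spheroid invasion, perimeter intensity profiles
    relative to the protrusion tip with confidence bands, the Peripheral
    Distribution Index for single cells, and sliding-window GA-content scans
    of 3'UTR sequences. Includes a Laplacian-of-Gaussian single-molecule FISH
    spot detector with sub-pixel localization and a seeded synthetic-scene
    generator (leader-cell geometries, diffraction-limited spots with
    controllable front bias, branched spheroid silhouettes) so that every
    stage is verifiable without raw microscopy data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    tiff,
    jsonlite,
    yaml,
    multcomp,
    Biostrings,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
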