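Package: cyclefate
Title: Cell-Cycle Phase Calling, Proliferation-Quiescence Fate Analysis and
    Lineage Statistics for Fucci/CDK2 Live-Cell Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing single-cell live-imaging trajectories of
    cell-cycle reporters. Provides a seeded synthetic-cohort generator for
    lineage-linked Fucci4 (Cdt1, Geminin, SLBP, histone H1.0) and CDK2
    (DHB cytoplasm/nucleus) reporter trajectories with p21 dynamics under
    control and glucose-depletion conditions; per-frame phase calling
    (G1/S/G2/M) from reporter waveform rules; proliferation-quiescence fate
    classification from the CDK2 cytoplasm/nucleus ratio; mitosis-anchored
    lineage statistics (mother-daughter inheritance correlation, sibling
    discrepancy and concordance, time-to-mitosis analysis); and a synthetic
    image rendering and quantification chain (illumination flattening,
    Laplacian-of-Gaussian nuclear detection, nuclear-disk and cytoplasmic-ring
    measurement, frame linking).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    EBImage,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
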