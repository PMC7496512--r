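Package: agglomsizer
Title: Automated Sizing of Nanoparticle Agglomerates in Dark-Field STEM Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An automated workflow for quantifying nanoparticle agglomerate
    dispersion from dark-field scanning transmission electron microscopy
    (STEM) images. Provides illumination correction, sparse-annotation
    random-forest pixel classification that separates agglomerates from
    background and salt precipitates, halo-corrected per-agglomerate size and
    shape measurement (Feret diameter, area, perimeter, form factor, moment
    axes), number-, volume- and simulated light-scattering intensity-weighted
    size distribution statistics, segmentation validation against reference
    masks via per-object Jaccard agreement, and a seeded synthetic scene
    generator with full ground truth for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    ranger,
    tiff,
    png,
    yaml,
    jsonlite,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
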