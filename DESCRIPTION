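Package: AstroMigrate
Title: Quantitative Analysis of Astrocyte-Progenitor Migration in Developing Cortex
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for classifying and quantifying the migration of astrocyte
    progenitors in the embryonic cerebral cortex from time-lapse imaging data.
    Implements per-frame trajectory statistics (speed gating, signed directional
    changes, angles to the radial axis, net-displacement polar summaries,
    motility filtering), a blood-vessel proximity pipeline (vessel mask
    construction with skeletonization, anisotropy-aware centroid-to-surface
    distances with edge exclusion, association fractions, per-frame on/off
    vessel classification, on-vessel persistence and off/on ratios), cortical
    depth distributions of detected cells (channel-product detection with 3D
    maxima and size filtering, relative depth between cortical-plate borders,
    binned distributions with multiple-comparison testing), a statistical
    reporting layer (Welch/Student t, Mann-Whitney, Dunnett, Tukey,
    Kruskal-Wallis with Dunn post hoc), and a seeded synthetic-data generator
    emulating the imaging inputs (radially biased vessel networks, erratic,
    radial and vessel-guided trajectory classes, nuclei clouds, rasterized
    two-channel volumes) so that every stage is verifiable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'AstroMigrate-package.R'
    'vesselmask.R'
    'distance.R'
    'contacts.R'
    'stats.R'
    'cortical.R'
    'io.R'
    'simulate.R'
    'rasterize.R'
    'trajectory.R'
    'pipeline.R'
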