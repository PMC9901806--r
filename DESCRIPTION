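Package: filamentr
Title: Detection, Segmentation and Tracking of Cytoskeletal Filaments
Version: 0.1.0
Authors@R: person("filamentr", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for quantitative analysis of fibrous cytoskeletal
    structures (stress fibers, microtubules, intermediate filaments) in 2D
    fluorescence microscopy images and time-lapse stacks. Provides a filter
    pipeline and binarization front end, a circle-mask width map, straight
    line sensing, seeded bidirectional curve tracing with orientation-field
    validation, per-filament and per-cell shape descriptors including a
    nematic order parameter, frame-to-frame single-filament tracking via
    unbalanced optimal transport over filament fragments, bounding-box cell
    event monitoring (division, fusion, touch) with lifeline assembly, a
    ground-truthed synthetic image and movie generator, and a batch
    command-line interface with re-importable JSON settings. Includes
    minimal readers and writers for uncompressed grayscale TIFF stacks and
    PNG images so no external image libraries are required.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
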