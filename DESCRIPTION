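Package: leitrack
Title: Dual-View Time-Lapse Quantification of Rosette Leaf Elevation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Low-cost phenotyping of leaf hyponasty in rosette plants such
    as Arabidopsis thaliana from paired top-view and side-view time-lapse
    photographs. Segments green plant material with an excess-green
    threshold, measures the rosette's equal-moment ellipse from the top
    view and plant height above a soil reference line from the side view,
    converts to millimetres with per-camera calibration factors, and
    computes a leaf elevation index (LEI), the arctangent of the
    height-to-radius ratio of the plant treated as a cylinder. Per-plant
    time courses are aggregated into normalized group mean and standard
    error trajectories. A synthetic scene renderer with exact geometric
    ground truth supports validation and benchmarking without real images.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    png,
    EBImage,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
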