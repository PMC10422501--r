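Package: egopool
Title: Spatial and Temporal Pooling of Convolutional Features for
    Egocentric Activity Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies pre-segmented egocentric (wearable-camera) video
    clips into activities of daily living. Per-frame convolutional feature
    maps are summarised by regional mean and max spatial pooling (MMSP),
    frame descriptors are aggregated per clip by a two-level max/mean
    temporal pyramid (TPMM), appearance and dense-optical-flow motion
    streams are fused early, and clips are classified with a one-vs-all
    linear support vector machine evaluated under leave-one-person-out
    cross-validation. Includes a deterministic mock feature extractor, an
    architecture-only VGG16 forward pass, a pyramidal Lucas-Kanade dense
    flow estimator with hue/saturation flow rendering, and seeded synthetic
    fixture generators so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    png,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
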