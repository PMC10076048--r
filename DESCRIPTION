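Package: skelflow
Title: Unsupervised 3D Skeleton Action Representation Learning with Decoupled Pose Flow
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Learns fixed-length action representations from unlabeled 3D
    skeleton sequences. Handcrafted pose-flow supervision signals (consecutive
    and reference pose flow, decoupled into magnitude and orientation fields)
    drive LSTM sequence autoencoders with one encoder and two decoders in four
    variants: a pose-reconstruction baseline, an explicit decoupled-flow
    network, an implicit variant that derives flows from decoder outputs, and
    a generalized variant regularized by pose reconstruction. Includes NTU-style
    skeleton file parsing, the spine-centering/axis-alignment normalization
    recipe, multi-task losses with adaptive homoscedastic-uncertainty
    weighting, Adam training with full backpropagation through time, the
    1-nearest-neighbor cosine evaluation protocol, and a seeded synthetic
    skeleton-action generator whose classes isolate motion direction, motion
    norm, and static shape contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
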