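Package: lmiar
Title: Position-Aware Indoor Activity Recognition from Smartphone Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Recognizes compound indoor human activities (eating, sleeping,
    cooking, ...) from smartphone multisensor recordings by fusing indoor
    location features with motion features. Location features come from a
    convolutional network over time-series-as-image encodings of geomagnetic
    and ambient-light channels; motion features come from a transformer
    encoder over accelerometer and gyroscope segments; the two are combined
    by low-rank multimodal tensor fusion. Includes a self-contained neural
    network engine (convolution, batch/layer normalization, multi-head
    attention, Adam) with analytic gradients, a synthetic apartment/activity
    simulator that generates labeled sensor traces for end-to-end testing,
    file I/O for a per-sensor CSV recording dialect, a two-stage training
    protocol with an ablation harness, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
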