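Package: drivecog
Title: Driving-Related Cognitive Ability Scoring and Multimodal Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies ten driving-related cognitive components from task
    performance records into a PCA-weighted composite score and a four-level
    ability grade, and predicts that grade from windowed multimodal driving
    sensor data (electrodermal activity, heart rate, respiration, perinasal
    perspiration, eye tracking, vehicle telemetry, facial emotion) with a
    dual-branch Transformer encoder fused by an attentional feature fusion
    gate. Includes a reproducible synthetic cohort simulator that plants a
    latent per-driver ability in both the performance indicators and the
    sensor statistics, signal preprocessing (trimming, interpolation, min-max
    normalization, resampling, sliding windows, modality split), training
    with Adam and step-decay, and leave-one-subject-out evaluation with
    confusion matrices and an ablation harness.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
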