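Package: recoverhome
Title: Home-Monitoring Analysis of Post-Surgical Recovery from Wearable Sensor Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for long-term home monitoring of recovery after joint
    replacement surgery using a wrist-worn wearable relayed through Bluetooth
    Low-Energy gateways. Implements indoor localisation from per-gateway RSSI
    fingerprints (1-s window statistics classified by a small multilayer
    perceptron), non-parametric rest-activity analysis of the acceleration
    magnitude signal (L5, M10, interdaily stability, intradaily variability,
    relative amplitude), posture and ambulation classification from 6-s
    accelerometer windows with a random forest, gateway-health diagnostics, and
    clinician-facing summaries comparing sensor-derived trends with patient
    reported outcome measures. A synthetic smart-home generator produces homes,
    circadian routines, multimodal sensor streams, annotation protocols and
    failure injections so every stage is testable without private patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    ggplot2,
    jsonlite,
    randomForest,
    stats,
    utils,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
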