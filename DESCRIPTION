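Package: camtel
Title: Consistency of Camera-Trap Detections and Telemetry Space Use
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for testing whether camera-trap detections and
    telemetry-based home-range estimates carry consistent information about
    animal space use.  Implements fixed-kernel utilization distributions with
    reference-bandwidth selection and isopleth extraction, camera availability
    and proximity-count construction, detection models with a complementary
    log-log link and a log utilization-density offset, quasi-likelihood and
    mixed-model variants with AICc/QAICc selection and Akaike weights, and a
    movement/camera simulator for parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    jsonlite,
    lme4,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
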