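Package: hgamapr
Title: High-Gamma Mapping and Repetition Attenuation for ECoG Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for electrocorticographic (ECoG) functional
    mapping with repetitive motor paradigms. Transforms continuous multichannel
    recordings into rest-standardized 100-ms high-gamma (60-170 Hz) band-power
    z-scores via a drift filter, common average reference, Butterworth band-pass
    and Hilbert envelope; identifies electrodes with significant movement-related
    activity; quantifies short-term (within-block) and long-term (across-block)
    repetition attenuation with Kruskal-Wallis and Dunn post hoc tests; and
    relates attenuation to cortical location (gyrus contingency, hand-knob
    distances). Includes a paradigm-locked synthetic ECoG generator with planted
    responses and attenuation profiles so every stage can be validated against
    known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
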