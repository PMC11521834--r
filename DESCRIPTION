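Package: seeghg
Title: High-Gamma Language Mapping for Stereo-EEG Depth Electrode Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for auditory-naming high-gamma (60-140 Hz)
    language mapping on stereoelectroencephalography (SEEG) depth electrodes.
    Implements common-average, bipolar and Laplacian montages as explicit
    linear re-referencing operators, complex Morlet wavelet time-frequency
    amplitude with per-trial baseline percent-change normalisation, phase-wise
    maximum-amplitude trial features stratified by anatomical compartment
    (deep white matter, shallow white matter, gray matter, outside the brain),
    and linear mixed-model contrasts of montage and vocalization condition
    with Benjamini-Hochberg false-discovery-rate control. A synthetic SEEG
    generator reproduces the statistical structure the analysis assumes
    (distance-attenuated volume conduction of gray-matter sources into white
    matter, response-phase facial EMG at extracranial contacts, 1/f
    background, a shared white-matter reference) so every stage is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    jsonlite,
    yaml,
    lme4,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    lmerTest,
    withr,
    tidyr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
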