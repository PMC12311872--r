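Package: circamark
Title: Wearable-Derived Sleep and Circadian Rhythm Biomarkers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes a 26-marker panel of sleep and circadian rhythm digital
    biomarkers from minute-resolution wearable heart-rate and step-count
    recordings: midsleep time and total sleep time summaries, single-component
    cosinor parameters (MESOR, amplitude, acrophase, circadian quotient),
    nonparametric actigraphy metrics (L5, M10, relative amplitude, interdaily
    stability, intradaily variability), singular-spectrum-analysis circadian
    activity rhythm energy (CARE), and continuous-wavelet circadian rhythm
    energy (CCE) band markers from a Morlet spectrogram. Includes wear-time
    eligibility filtering and missing heart-rate repair, case/control group
    comparison (Welch t and Wilcoxon rank-sum tests), a pluggable
    feature-importance harness with undersampling-repeat stability, and a
    synthetic wearable-cohort simulator so the full pipeline is testable
    without access to cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
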