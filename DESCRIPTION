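Package: sevopact
Title: Sevoflurane-Activated Intracranial EEG Biomarkers: Delta-HFO
    Phase-Amplitude Coupling and Transfer-Entropy Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for intraoperative electrocorticography
    (ECoG) biomarkers of epileptogenicity under stepwise sevoflurane
    anaesthesia. Computes delta (3-4 Hz) to high-frequency-oscillation
    (80-300 Hz) phase-amplitude coupling via the normalized mean-vector
    modulation index, binarized-burst transfer-entropy effective
    connectivity in the HFO and delta bands, anaesthetic-stage linear and
    logistic mixed models with Bonferroni correction, Cohen's d effect
    sizes, resection-completeness subtraction predictors, and hotspot
    selection for tractography export. Includes a synthetic multi-patient
    ECoG cohort generator with known coupling, directed burst propagation
    and stage-gain ground truth, so every pipeline stage is verifiable
    without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    lme4,
    lmerTest,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
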