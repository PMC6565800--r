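Package: muscleBIA
Title: Multi-Frequency Bioimpedance Assessment of Skeletal Muscle
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multi-frequency bioimpedance analysis (mfBIA) of individual
    skeletal muscles. Fits the single-dispersion Cole impedance model to measured
    impedance spectra by algebraic circle fitting in the complex plane followed by
    Levenberg-Marquardt refinement, derives the eight muscle parameters routinely
    reported at 50 kHz (impedance, resistance, reactance, phase angle, centre
    frequency, extracellular and intracellular resistance, membrane capacitance),
    compares recordings against packaged normative reference ranges for eight
    muscles in healthy adults via z-scores and percent changes, and implements the
    cohort statistics used to establish those norms (Mann-Whitney gender contrasts,
    normality-routed age contrasts on pooled decades). A calibrated synthetic-cohort
    generator reproduces the study design (50 subjects, 8 muscles, bilateral
    gastrocnemius) with parameter distributions matched to the packaged norms.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'calibrate.R'
    'cohort.R'
    'cole-model.R'
    'fit-cole.R'
    'io.R'
    'muscleBIA-package.R'
    'pipeline.R'
    'reference.R'
    'simulate.R'
    'statistics.R'
    'utils.R'
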