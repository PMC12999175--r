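Package: restfc
Title: Resting-State Functional Connectivity Pipeline with Synthetic Cohorts
Version: 0.1.0
Authors@R: person("NPDL", "Pipeline Maintainers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quality control, denoising, and group-level analysis of
    ROI-averaged resting-state BOLD time series: DVARS-based motion
    scrubbing, continuous-window selection, parcel-level signal-dropout
    detection, linear detrending, zero-phase Butterworth temporal
    filtering, CompCor-style nuisance regression, frame censoring,
    ROI-to-ROI Pearson connectivity, block-averaged and lateralized
    connectivity contrasts, split-half noise ceilings, mixed
    between/within ANOVA, Bonferroni-corrected paired contrasts with
    Cohen's d, and Pearson-Filon z tests for dependent correlations.
    Includes a synthetic-data generator that plants group-specific
    correlation structure, drift, shared physiological nuisance, motion
    spikes, and signal dropout, so every stage of the pipeline is
    verifiable without access to restricted MRI data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
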