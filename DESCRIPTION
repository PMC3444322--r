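Package: petcvr
Title: Oxygen-15 PET Haemodynamic Staging and Transcranial Doppler
    CO2-Reactivity Concordance
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis pipeline for comparing transcranial
    Doppler CO2-reactivity with quantitative oxygen-15 PET haemodynamics in
    symptomatic internal carotid artery occlusion. Provides a seeded
    synthetic cohort generator (ground-truth haemodynamic states, noisy
    Doppler velocity recordings, forward-simulated three-tracer dynamic PET
    scans with gamma-variate arterial input functions), tracer-kinetic
    quantification of cerebral blood flow, oxygen extraction fraction and
    cerebral blood volume (one-tissue Kety water model, Mintun-type oxygen
    model, equilibrium carbon monoxide blood-volume equation), CO2-reactivity
    computation and categorisation, haemodynamic staging from normal-range
    rules, and method-agreement statistics (2x2 concordance with Cohen's
    kappa, group contrasts, correlations with outlier re-analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    RNifti,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'aif.R'
    'kinetics-forward.R'
    'synthetic-cohort.R'
    'cohort-io.R'
    'tcd-reactivity.R'
    'concordance.R'
    'kinetics-fit.R'
    'phantom.R'
    'staging.R'
    'pipeline.R'
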