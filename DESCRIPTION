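Package: smrpipe
Title: Closed-Loop Sensorimotor-Rhythm Neurofeedback Pipeline and Analyses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Re-implementation of a closed-loop sensorimotor-rhythm (SMR)
    electroencephalography neurofeedback computation and its downstream
    analyses as a tested, reusable pipeline. Provides the online
    event-related spectral perturbation (ERSP) feedback chain (large
    Laplacian spatial filter, zero-phase Butterworth band-pass and notch
    filtering, 1-s Hanning short-time Fourier band power, within-trial
    rest-baseline normalization, frequency-of-interest calibration,
    10-sample smoothing and percentile-to-frame mapping), offline spectral
    parameterization into aperiodic 1/f and periodic Gaussian components
    with individual-alpha-frequency extraction, time-frequency ERSP maps,
    somatosensory evoked potential (N9/N13/N20) component quantification,
    exponential speed-accuracy trade-off fitting, and the inferential
    machinery of the study (mixed 2x2 repeated-measures ANOVA, aligned rank
    transform, t tests with Bonferroni correction and effect sizes, JZS
    Bayes factors, and cluster-mass permutation testing with FDR control
    for time-frequency maps). A synthetic-data module generates EEG, SEP
    and behavioral datasets with known ground truth so every stage is
    verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
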