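Package: DepthFCM
Title: Unsupervised Anesthetic-Depth Staging from Frontal EEG by Fuzzy C-Means
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for unsupervised assessment of hypnotic (anesthetic) depth
    from frontal electroencephalography. Provides EDF/CSV ingestion, channel
    averaging, zero-phase Butterworth bandpass filtering, Welch power spectral
    density estimation on sliding 30-second windows, normalized delta /
    high-theta / alpha / beta band-power ratio features with spectral-buffer
    exclusion, a from-scratch Fuzzy C-Means clusterer (c = 3, m = 2) with
    physiological centroid labeling into slight, proper and deep hypnotic
    states, per-recording fuzzy membership traces, density-spectral-array
    style visualization, and a synthetic anesthesia-EEG generator with scripted
    ground-truth depth timelines for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    signal,
    jsonlite,
    yaml,
    withr,
    S4Vectors,
    SummarizedExperiment,
    ggplot2,
    patchwork
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'DepthFCM-package.R'
    'artifact.R'
    'edf.R'
    'eeg-io.R'
    'spectral.R'
    'features.R'
    'fcm.R'
    'pipeline.R'
    'plots.R'
    'synth.R'
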