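Package: mtlmem
Title: Simulation, NWB-Style Storage and Analysis of Human Medial Temporal
    Lobe Single-Neuron Recognition-Memory Sessions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for working with human single-neuron recordings acquired
    during a new/old recognition-memory task. Provides a generator of complete
    synthetic sessions (task timeline with TTL event markers, confidence-rated
    recognition behavior from an equal-variance signal-detection model,
    inhomogeneous-Poisson spike trains of visually and memory selective units,
    extracellular waveforms and sorting-quality metrics), a writer and reader
    for the Neurodata Without Borders (NWB:N 2.x, HDF5-backed) session layout
    used by human intracranial laboratories, reconstruction of the trials
    table from raw event streams, confidence-ROC behavioral analysis (AUC,
    zROC slope, confidence-split accuracy), and single-neuron screening for
    visual and memory selectivity (one-way ANOVA and two-tailed bootstrap mean
    comparison) with population summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    rhdf5,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
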