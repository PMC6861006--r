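Package: svpool
Title: Synaptic Vesicle Super-Pool Dynamics from FRAP, Axonal Transport and
    Miniature Current Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantification pipeline for presynaptic vesicle exchange between
    boutons and the axonal super-pool. Implements FRAP trace processing
    (background subtraction, ratio photobleaching correction, full-scale
    normalization, quality control), double-exponential recovery fitting with
    the extra sum-of-squares F test for nested-model comparison, fixed
    timepoint group statistics, kymograph construction with automated track
    tracing and the cumulative cross-section traffic statistic, and
    template-matching detection of miniature postsynaptic currents with cell
    quality control. A seeded synthetic-data generator produces FRAP traces
    and image stacks from a two-pool exchange model, axonal time-lapse movies
    with moving puncta, and voltage-clamp traces with Poisson-timed events,
    so every stage can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    jsonlite,
    yaml,
    tiff,
    EBImage,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    minpack.lm
Config/testthat/edition: 3
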