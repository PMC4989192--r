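Package: posterp
Title: Post-Error Adjustment Analysis for Go/No-go EEG Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of post-error behavioral and
    electrophysiological adjustments in equiprobable visual Go/No-go
    experiments. Generates synthetic cohorts (event sequences, behavioral
    outcomes and continuous multichannel EEG with known ground truth),
    classifies trials by sequential context, computes post-error slowing and
    post-error improvement of accuracy together with signal-detection
    measures (d-prime, criterion C), builds condition-sorted event-related
    potential averages with artifact rejection, zero-phase Butterworth
    smoothing and several baseline schemes, quantifies preparatory
    (prefrontal negativity, Bereitschaftspotential) and visual (P1, N1)
    components, and runs the corresponding inferential layer: two-way
    repeated-measures ANOVA with Bonferroni post-hoc tests, paired t-tests,
    Pearson correlations and percent-change effect summaries.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
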