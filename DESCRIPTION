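Package: swrpipe
Title: Peri-Ripple Analysis of Hippocampal-Retrosplenial Interactions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of simultaneously recorded hippocampal CA1
    and retrosplenial cortex (RSC) electrophysiology around sharp-wave
    ripples (SWRs).  Provides sleep-state scoring from LFP and EMG,
    detection of ripples, sharp waves, delta waves, spindles and cortical
    OFF periods, peri-event spike statistics with shuffle-based
    significance, template-matching assembly reactivation, cross-validated
    GLM prediction of directional CA1-RSC coupling, waveform-based cell
    type classification, cross-session single-unit tracking via dynamic
    time warping, and place/splitter/speed cell identification on a
    figure-eight maze.  A synthetic-session generator with full ground
    truth makes every stage testable without recorded data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    minpack.lm,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
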