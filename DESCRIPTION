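Package: gravseq
Title: Nanopore Sequencing Performance Under Variable Gravity and Vibration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for assessing nanopore sequencing performance
    during parabolic flight. Processes triaxial accelerometer recordings into
    orientation-independent vibration measures (zero-phase high-pass IIR
    filtering, Welch power spectral density, 1-second RMS binning), segments
    the flight profile into parabola, transition, hypergravity and other
    phases, computes per-read and per-base sequencing metrics (representative
    read quality from mean per-base error probability, base translocation
    time, ionic-current noise, per-phase genome coverage), joins sequencing
    and acceleration data on a common 1-second-binned timeline, and applies
    the statistical battery used for such data: stepwise linear regression
    with interactions, one-way ANOVA with Tukey-Kramer HSD, two-sample
    Kolmogorov-Smirnov tests, and MAD-based outlier flagging. Includes
    synthetic generators for parabolic-flight accelerometer traces and
    event-aligned nanopore read tables with ground truth, so the full
    pipeline is testable without flight data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    pracma,
    data.table,
    jsonlite,
    yaml,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings
Config/testthat/edition: 3
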