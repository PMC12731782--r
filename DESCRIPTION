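Package: clchet
Title: Analysis of Heteromeric ClC-3/ClC-4 Transporter Electrophysiology and
    FLIM-FRET Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Processing and statistical analysis of voltage-clamp recordings of
    CLC chloride/proton exchangers, aimed at detecting dominant effects of
    disease-associated CLCN4 variants in heteromeric ClC-3/ClC-4 complexes.
    Implements P/N leak subtraction and steady-state current-voltage extraction,
    per-batch variant-to-wild-type ratio normalization with slope-based
    phenotype classification, a silent-subunit (E281A) co-expression assay, an
    acidic-pH gain-of-function assay with extrapolated leak-line subtraction,
    phasor-based FLIM-FRET lifetime and efficiency analysis, and the matching
    statistical layer (log-ratio t-tests, one-way ANOVA with Tukey post hoc,
    significance-star annotation). A seeded synthetic-data generator emulates
    two-electrode voltage-clamp and whole-cell patch-clamp sessions and
    time-correlated photon-count decay stacks so the whole chain is testable
    without experimental data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
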