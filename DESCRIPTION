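Package: fragscreen
Title: Screening Amyloid-Beta Peptide Fragments for Fibrillogenesis Inhibition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for spectroscopic screening of amyloid-beta
    (Abeta) derived peptide fragments as fibrillogenesis inhibitors.
    Provides sequence tools (fragment windows, Henderson-Hasselbalch net
    charge, theoretical isoelectric points under the Bjellqvist/ProtParam
    convention), a tidy data model for time-resolved emission fluorescence,
    light-scattering, FTIR and CD spectra with windowed band averaging and
    Savitzky-Golay smoothing, amide-I band decomposition and CD band-position
    classification of secondary structure, thioflavin-T and scattering
    aggregation time courses, the inhibition-percentage statistic with
    per-timepoint t-test summaries, the Phe-to-Tyr resonance energy transfer
    difference-spectrum procedure with Forster-theory utilities, and a
    seeded synthetic-data generator (Finke-Watzky aggregation kinetics plus
    modality-specific observation models) for ground-truth validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    signal,
    minpack.lm,
    pracma,
    yaml,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse,
    readr,
    Biostrings,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
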