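Package: midtail
Title: Middle-Down Quantification of Combinatorial Histone H3 Tail Proteoforms
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies combinatorially modified histone H3 N-terminal tail
    proteoforms from multiplexed middle-down EThcD mass spectrometry.
    Provides exact monoisotopic mass chemistry for sortase-tagged,
    TMT-labeled H3.1/H3.3 tail peptides and their a/b/c/y/z fragment ions;
    annotation of centroided MS2 spectra against candidate proteoforms with
    heavy-isotope confirmation; apportionment of fragment-ion intensity in
    chimeric spectra between co-isolated positional isomers; TMT 6-plex
    reporter-ion extraction, channel normalization and condition-coverage
    filtering; and per-proteoform log2 fold changes with two-sided t-tests.
    A seeded synthetic-data generator emits ground-truth experiments
    (spectra, peptide-spectrum-match tables, designed fold changes) so every
    pipeline stage is testable without instrument data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    yaml,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    mzR,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'constants.R'
    'chemistry.R'
    'AllClasses.R'
    'proteoform.R'
    'config.R'
    'spectra-io.R'
    'psm.R'
    'annotation.R'
    'quantify.R'
    'reporter.R'
    'simulate.R'
    'pipeline.R'
    'midtail-package.R'
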