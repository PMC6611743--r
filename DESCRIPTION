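Package: hdxrank
Title: HDX-Aware In Silico Fragmentation and Candidate Ranking for LC-MS/MS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks candidate structures for small-molecule MS/MS spectra acquired as
    normal/deuterium-exchange (HDX) pairs. Candidates are deuterated in silico according
    to the experimentally exchanged hydrogen count, fragmented by combinatorial bond
    disconnection, and scored with four terms (spectral match of the normal and the
    deuterated spectrum, matching fragment pairs across the two spectra, and agreement
    of the exchangeable-hydrogen count) combined into a weighted consensus. Includes
    consensus-weight optimization by randomized simplex search with cross-validation,
    MS1 feature pairing for untargeted acquisition, peak-list I/O (MGF, MSP, two-column
    text), and a seeded synthetic spectrum-pair generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ChemmineR,
    ChemmineOB,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
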