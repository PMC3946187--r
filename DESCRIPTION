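Package: gambi
Title: Genetics-Based Marine Biotic Index (AMBI) Feasibility Analysis
Version: 0.1.0
Authors@R: person("AZTI", "Benthos Tools", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Computes the AZTI Marine Biotic Index (AMBI) and its
    presence/absence variant (p/a AMBI) from species-by-station
    abundance data, assigns categorical pollution quality classes,
    and quantifies agreement between classifications obtained under
    different species subsets (barcode-sequenced species, most-frequent
    species, random subsets) using Cohen's kappa with a resampling null
    distribution. Also audits DNA barcode reference-library coverage of
    a species list (greedy per-species sequence deduplication,
    per-phylum coverage summaries) and evaluates degenerate PCR primer
    pairs in silico against a sequence library with a position-weighted
    mismatch score. A community simulator generates species lists,
    pollution-gradient abundance matrices and partial barcode libraries
    with the statistical structure coastal monitoring data exhibit, so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
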