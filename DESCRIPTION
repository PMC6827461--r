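Package: plasmidhet
Title: Deterministic Dynamics and Inference of Plasmid Heteroplasmy Under
    Random Segregation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the generation-to-generation dynamics of wild-type and
    mutant copies of a multicopy ColE1-type plasmid (pBR322) inside a
    bacterial population as a deterministic expected-value recursion over
    cell states: random binomial-hypergeometric partitioning of plasmids at
    division, chromosomal and plasmid mutation, floor-rate plasmid
    replication, and piecewise frequency-dependent survival. Provides the
    population mutant-plasmid fraction statistic, least-squares multi-start
    bounded fitting of the seven model parameters to duplex-sequencing
    allele-frequency time series, conversion of per-site duplex variant
    tables into observed mutant-frequency series at the focal copy-number
    control sites, turbidostat growth-rate helpers, and a synthetic
    duplex-seq-like data generator so the whole analysis runs end to end
    without external data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
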