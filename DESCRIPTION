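Package: aasupply
Title: Amino Acid Supply from Metabolic Flux and Its Role in Translation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates per-protein amino acid supply from a genome-scale
    stoichiometric metabolic model by a two-step linear-programming
    procedure (maximize growth, then maximize a protein-specific amino-acid
    sink with a partial-biomass reaction fixed at the optimal growth rate),
    builds translation efficiency and ribosome density from expression and
    ribosome-profiling summary tables with explicit reliability filters,
    and quantifies their relationship with rank-based statistics: Spearman
    correlation, one-sided Wilcoxon rank-sum tests, and rank-based
    (Jaeckel dispersion, Wilcoxon scores) multiple linear regression.
    Includes a synthetic-data module that generates toy metabolic models
    with hand-computable optima and expression tables with planted rank
    correlations for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    xml2,
    yaml,
    tibble,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Biostrings
Config/testthat/edition: 3
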