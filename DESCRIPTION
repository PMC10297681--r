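Package: voicechain
Title: Pathway-Chain Search Linking Gene Sets to Voice-Related Pathways
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for tracing "voice chains": paths through a pathway-overlap
    graph that connect an arbitrary terminal gene set (for example, the genes
    deleted in a chromosomal microdeletion syndrome) to the pathway(s)
    containing a designated voice-related head gene such as FOXP2. Includes a
    GMT gene-set reader and pathway-ensemble container, level-1/level-2
    chainlink extraction with connectivity summaries, speech-phenotype
    annotation and cohort statistics for microdeletion syndromes,
    Conway-Maxwell-Poisson maximum-likelihood modelling of chainlink count
    distributions with a code-length distance between count sets, a
    closed-form chance model for chain occurrence, and seeded synthetic
    ensemble generators with brute-force oracles for validating the search.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
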