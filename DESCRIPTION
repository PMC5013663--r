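Package: edgeweb
Title: Quantitative Host-Parasitoid Webs and Apparent Competition Across
    Habitat Edges
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@edgeweb.example.org",
           role = c("aut", "cre"))
Description: Builds quantitative host-parasitoid food webs from individual
    rearing records, with hosts indexed by habitat so that the same taxon on
    either side of a habitat edge is treated as a distinct node. Computes the
    Muller shared-parasitism dependence index and its habitat-indexed
    extension, predicts each host's future parasitism rate and abundance
    change from community-wide abundance changes (apparent competition), and
    validates the predictions with binomial and Poisson mixed models,
    AIC-based model selection, Nakagawa-Schielzeth R-squared, percent change
    in variance, and overdispersion diagnostics. Includes a synthetic-data
    generator with a before-after control-impact (BACI) herbivore-reduction
    design and tunable apparent-competition coupling, so the whole pipeline
    is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    multcomp,
    igraph,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
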