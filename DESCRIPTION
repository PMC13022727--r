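Package: retrosynthon
Title: Synthon-Abstracted Higher-Level Retrosynthesis Planning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Curates synthon-abstracted ("higher-level") reaction datasets
    from atom-mapped reaction corpora, trains a template-relevance
    single-step retrosynthesis model on the abstracted reactions, and plans
    multistep syntheses by Monte Carlo tree search over abstracted
    intermediates that terminates at building blocks via marker-aware
    substructure matching. Leaving substructures along mined routes are
    replaced by electronegativity-classed attachment markers, tactical
    steps (functional group interconversions of leaving groups,
    protections) are removed, and equivalent strategies are consolidated
    into single higher-level reactions. Includes a mapped-SMILES dialect
    with canonical serialization, a graph-rewrite retro-template engine,
    and a seeded synthetic corpus generator with planted ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
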