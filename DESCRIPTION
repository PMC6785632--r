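Package: neighborsep
Title: Evolutionary Conserved Gene Neighborhoods and Their Separation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies gene pairs whose orthologous counterparts are
    chromosomal neighbors in most of a set of related species but are
    separated (different chromosomes or many intervening genes) in a focal
    species, derives the corresponding gene groups (conserved-neighbor
    separated versus single-species-neighbor separated controls), and tests
    whether before- and after-separation neighbors of those genes share
    regulatory and functional features.  Includes correlation-based
    expression-divergence and coexpression statistics with bootstrap
    summaries, chromosome-matched permutation tests with empirical P values,
    readers for annotation, orthology, expression, gene-set (GMT) and
    interaction-network formats, a multi-species genome simulator with
    planted ground truth for end-to-end validation, and a pipeline
    orchestrator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    fgsea,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
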