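Package: phyllopan
Title: Comparative Pangenomics of Phyllosphere Yeast Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative pangenome analysis of environmental yeast
    isolate collections: orthogroup gene-count matrices in the OrthoFinder
    dialect, soft-core identification and strict source-combination
    partitioning, COG functional-category enrichment against the soft core
    with Fisher's exact test and Benjamini-Hochberg correction, per-genus
    differential orthogroup testing, KEGG-module-style pathway completeness
    scoring, amplicon core-community prevalence rules, and a leave-one-genus-out
    classification harness with permutation feature importance. Includes a
    seeded synthetic-study generator with planted signal for recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    randomForest,
    e1071
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
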