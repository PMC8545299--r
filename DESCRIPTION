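Package: funsplit
Title: Embedding-Based Sub-Clustering of Protein Functional Families
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Splits protein functional families (such as CATH FunFams) into
    functionally more consistent sub-families by density-based clustering of
    fixed-length protein language-model embeddings. Within each family, members
    are clustered with DBSCAN under a superfamily-adaptive distance threshold;
    outliers are flagged; and the functional consistency of the resulting
    clusters is quantified with Enzyme Commission (EC) annotation purity
    statistics, a size-preserving random-clustering null model, and percentile
    bootstrap confidence intervals. Includes a seeded synthetic-data generator
    with planted functional sub-structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    arrow,
    jsonlite,
    optparse,
    Biostrings,
    mclust,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
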