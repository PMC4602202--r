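Package: variantForest
Title: Random-Forest Prioritization of Nonsynonymous Single Nucleotide
    Variants by Integrating Variant Deleteriousness and Gene
    Guilt-by-Association Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Supervised prioritization of candidate nonsynonymous single
    nucleotide variants (nsSNVs) for a query disease. Eleven variant-level
    deleteriousness scores (SIFT, PolyPhen2, LRT, MutationTaster,
    MutationAccessor, MSRV, GERP, Phylop, SiPhy, CADD, SInBaD) are combined
    with eight gene-level guilt-by-association scores derived from gene
    functional-similarity matrices (expression, gene ontology, pathway,
    sequence, domain, protein interaction, transcriptional and microRNA
    regulation) through a random-forest classifier. Includes TF-IDF disease
    phenotype similarity, seed-gene selection, leakage-controlled five-fold
    cross-validation, rank-based evaluation metrics (rank ratio, mean rank
    ratio, rank-ROC AUC, false positive rate, hypergeometric top-k
    enrichment), and a synthetic-universe generator with a planted causal
    signal for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    ranger,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    optparse,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
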