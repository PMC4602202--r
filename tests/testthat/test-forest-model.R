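mkVariants <- function(n, genes, offset = 0L) {
    data.frame(chrom = "chr1", pos = offset + seq_len(n) * 10L,
               ref = "A", alt = "G",
               gene = rep_len(genes, n))
}

test_that("positive pairs enumerate unique disease-variant associations", {
    v <- mkVariants(2, c("gA", "gB"))
    assoc <- rbind(data.frame(disease = "d1", v),
                   data.frame(disease = "d2", v))
    pp <- buildPositivePairs(assoc)
    expect_equal(nrow(pp), 4)
    expect_true(all(pp$label == "positive"))
    # duplicates collapse
    expect_equal(nrow(buildPositivePairs(rbind(assoc, assoc))), 4)
    # a variant causative for two diseases yields two distinct pairs
    one <- rbind(data.frame(disease = "d1", v[1, ]),
                 data.frame(disease = "d2", v[1, ]))
    expect_equal(nrow(buildPositivePairs(one)), 2)
})

test_that("negative pool is the disease x neutral-variant product, disjoint from positives", {
    neut <- mkVariants(4, c("gC", "gD"), offset = 1000L)
    pool <- buildNegativePool(neut, c("d1", "d2", "d3"))
    expect_equal(nrow(pool), 12)
    expect_true(all(pool$label == "negative"))
    expect_equal(nrow(buildNegativePool(neut, character())), 0)
    pos <- buildPositivePairs(data.frame(disease = "d1",
                                         mkVariants(2, c("gA", "gB"))))
    keyOf <- function(p) paste(p$disease, p$chrom, p$pos, p$ref, p$alt)
    expect_length(intersect(keyOf(pool), keyOf(pos)), 0)
})

test_that("negative sampling is exact, reproducible and near-uniform", {
    neut <- mkVariants(5, "gX")
    pool <- buildNegativePool(neut, c("d1", "d2"))
    all10 <- sampleNegativePairs(pool, 10, seed = 4)
    expect_equal(nrow(all10), 10)            # whole pool
    s1 <- sampleNegativePairs(pool, 4, seed = 42)
    s2 <- sampleNegativePairs(pool, 4, seed = 42)
    expect_identical(s1, s2)
    expect_error(sampleNegativePairs(pool, 11, seed = 1), "smaller")
    # inclusion frequencies across many seeds are near uniform
    counts <- integer(10)
    for (seed in 1:5000) {
        s <- sampleNegativePairs(pool, 2, seed = seed)
        idx <- match(paste(s$disease, s$pos), paste(pool$disease, pool$pos))
        counts[idx] <- counts[idx] + 1L
    }
    p <- chisq.test(counts)$p.value
    expect_gt(p, 1e-4)
})

test_that("gene-level leakage elimination drops co-gene training variants", {
    train <- data.frame(disease = "d1", mkVariants(3, c("gA", "gB", "gC")),
                        label = "positive")
    filt <- eliminateLeakage(train, data.frame(gene = "gB"))
    expect_equal(filt$gene, c("gA", "gC"))
    expect_equal(eliminateLeakage(train, data.frame(gene = "gZ")), train)
    expect_warning(out <- eliminateLeakage(train, c("gA", "gB", "gC")),
                   "all training pairs removed")
    expect_equal(nrow(out), 0)
})

test_that("the forest separates separable features and is seed-deterministic", {
    tr <- separableFeatures(200, seed = 1)
    te <- separableFeatures(100, seed = 2)
    model <- trainModel(tr$features, tr$labels, numTrees = 200, seed = 5)
    sc <- scorePairs(model, te$features)
    expect_true(all(sc >= 0 & sc <= 1))
    auc <- pairwiseAuc(-sc[1:50], -sc[51:100])  # positives should rank high
    expect_gte(auc, 0.99)
    expect_gt(mean(sc[1:50]), mean(sc[51:100]))
    # determinism
    model2 <- trainModel(tr$features, tr$labels, numTrees = 200, seed = 5)
    expect_identical(sc, scorePairs(model2, te$features))
    # duplicated pair scores identically
    expect_equal(scorePairs(model, te$features[c(1, 1), ]),
                 rep(scorePairs(model, te$features[1, , drop = FALSE]), 2))
    # single-class training is refused
    expect_error(trainModel(tr$features, rep("positive", 200)), "both classes")
    # feature-order fingerprint is enforced
    swapped <- te$features[, rev(colnames(te$features))]
    expect_error(scorePairs(model, swapped), "fingerprint")
})

test_that("label-permuted training yields chance-level held-out AUC", {
    aucs <- vapply(1:3, function(seed) {
        tr <- separableFeatures(200, seed = seed)
        set.seed(seed + 100)
        labs <- sample(tr$labels)
        model <- trainModel(tr$features, labs, numTrees = 200, seed = seed)
        te <- separableFeatures(100, seed = seed + 50)
        sc <- scorePairs(model, te$features)
        pairwiseAuc(-sc[1:50], -sc[51:100])
    }, numeric(1))
    expect_gt(mean(aucs), 0.4)
    expect_lt(mean(aucs), 0.6)
})

test_that("prioritization orders by score with average-rank ties", {
    tr <- separableFeatures(100, seed = 3)
    model <- trainModel(tr$features, tr$labels, numTrees = 100, seed = 1)
    cand <- mkVariants(10, sprintf("g%d", 1:10))
    feat <- separableFeatures(10, seed = 4)$features
    rk <- prioritize(model, "dQ", cand, feat)
    tab <- rankingTable(rk)
    expect_equal(nrow(tab), 10)
    expect_equal(tab$score, sort(tab$score, decreasing = TRUE))
    expect_equal(tab$rank, rank(-tab$score, ties.method = "average"))
    expect_equal(tab$rank_ratio, tab$rank / 10)
    # scores are invariant to candidate presentation order
    perm <- c(7, 2, 9, 1, 10, 3, 5, 8, 6, 4)
    rk2 <- prioritize(model, "dQ", cand[perm, ], feat[perm, ])
    expect_equal(rankingTable(rk2)$score, tab$score)
    # single candidate
    one <- prioritize(model, "dQ", cand[1, ], feat[1, , drop = FALSE])
    expect_equal(rankingTable(one)$rank, 1)
    expect_equal(rankingTable(one)$rank_ratio, 1)
})

test_that("cross-validation partitions diseases once and respects both leakage rules", {
    u <- generateUniverse(smallConfig())
    mats <- universeSimilarityMatrices(u)
    cv <- runCrossValidation(u, seed = 3, numTrees = 100, matrices = mats)
    # every disease appears in exactly one test fold
    expect_setequal(cv$perDisease$disease, u@diseases)
    expect_equal(anyDuplicated(cv$perDisease$disease), 0L)
    expect_setequal(names(cv$folds), u@diseases)
    # post-hoc: recompute each fold's training pairs; no training variant
    # may share a gene with any same-fold test variant
    caus <- u@variants[u@variants$class == "causative", ]
    for (f in unique(cv$folds)) {
        testD <- names(cv$folds)[cv$folds == f]
        testGenes <- caus$gene[caus$disease %in% testD]
        trainPos <- buildPositivePairs(
            caus[!caus$disease %in% testD,
                 c("disease", "chrom", "pos", "ref", "alt", "gene")])
        kept <- eliminateLeakage(trainPos, testGenes)
        expect_length(intersect(kept$gene, testGenes), 0)
    }
    expect_true(all(cv$perDisease$auc >= 0 & cv$perDisease$auc <= 1))
    expect_error(runCrossValidation(u, nFolds = 99), "fewer diseases")
})
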