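test_that("universe generation is deterministic and matches configured counts", {
    cfg <- smallConfig(seed = 13)
    u1 <- generateUniverse(cfg)
    u2 <- generateUniverse(cfg)
    expect_identical(u1@variants, u2@variants)
    expect_identical(u1@scores, u2@scores)
    expect_identical(u1@sources$Exp, u2@sources$Exp)
    expect_identical(u1@sources$PPI, u2@sources$PPI)
    expect_identical(u1@termCounts, u2@termCounts)

    expect_length(u1@genes, cfg$n_genes)
    expect_length(u1@diseases, cfg$n_diseases)
    v <- u1@variants
    expect_equal(sum(v$class == "causative"), cfg$n_causative_variants)
    expect_equal(sum(v$class == "neutral"), cfg$n_neutral_variants)
    expect_equal(dim(u1@termCounts), c(cfg$n_diseases, cfg$n_terms))
    expect_equal(ncol(u1@sources$Exp), cfg$n_tissues)
    # a different seed gives a different universe
    u3 <- generateUniverse(smallConfig(seed = 14))
    expect_false(identical(u1@variants$pos, u3@variants$pos))
})

test_that("causative variants lie in truth-associated genes; keys are unique", {
    u <- generateUniverse(smallConfig())
    v <- u@variants
    caus <- v[v$class == "causative", ]
    truth <- paste(u@associations$disease, u@associations$gene)
    expect_true(all(paste(caus$disease, caus$gene) %in% truth))
    key <- paste(v$chrom, v$pos, v$ref, v$alt)
    expect_equal(anyDuplicated(key), 0L)
    expect_true(all(v$ref != v$alt))
    # roughly the configured fraction of scores is masked missing
    missRate <- mean(is.na(as.matrix(u@scores[variantScoreNames()])))
    expect_equal(missRate, u@config$missing_rate, tolerance = 0.05)
})

test_that("zero signal removes the causative/neutral score separation", {
    u0 <- generateUniverse(smallConfig(seed = 2, signal = 0))
    sc <- u0@scores
    caus <- u0@variants$class == "causative"
    cadd <- list(c = sc$CADD[caus], n = sc$CADD[!caus])
    p <- suppressWarnings(ks.test(cadd$c, cadd$n)$p.value)
    expect_gt(p, 0.01)
    # with strong signal the same comparison separates clearly
    u8 <- generateUniverse(smallConfig(seed = 2, signal = 0.8))
    sc8 <- u8@scores
    expect_gt(mean(sc8$CADD[caus], na.rm = TRUE),
              mean(sc8$CADD[!caus], na.rm = TRUE) + 5)
})

test_that("infeasible configurations are rejected", {
    expect_error(universeConfig(n_genes = 10, n_clusters = 4,
                                pool_size = 10), "exceed")
    expect_error(universeConfig(module_size = 50), "pool")
    expect_error(universeConfig(n_diseases = 41), "divisible")
    expect_error(universeConfig(signal_strength = 2), "signal_strength")
})

test_that("a written universe round-trips through the readers", {
    u <- generateUniverse(smallConfig(seed = 5))
    dir <- withr::local_tempdir()
    writeUniverse(u, dir)
    r <- readUniverse(dir)
    expect_equal(r@genes, u@genes)
    expect_equal(r@diseases, u@diseases)
    expect_equal(r@associations, u@associations)
    expect_equal(r@variants, u@variants)
    expect_equal(r@scores, u@scores, tolerance = 1e-12)
    expect_equal(r@sources$Exp, u@sources$Exp, tolerance = 1e-12)
    expect_equal(r@sources$KEGG, u@sources$KEGG)
    expect_equal(r@sources$PPI, u@sources$PPI)
    expect_equal(r@termCounts, u@termCounts)
    # VCF records are position-sorted within chromosomes
    vcf <- readVcfCandidates(file.path(dir, "variants.vcf"))
    expect_equal(nrow(vcf), nrow(u@variants))
    expect_true(all(tapply(vcf$pos, vcf$chrom, function(p) !is.unsorted(p))))
    # every variant in the VCF carries its host gene
    expect_setequal(unique(vcf$gene), unique(u@variants$gene))
})

test_that("gene-level features alone beat variant features on a disease control", {
    # all test-list variants are deleterious here (causative for some
    # disease), so deleteriousness scores cannot identify the query
    # disease's own variants, while association scores can
    u <- generateUniverse(smallConfig(seed = 11))
    mats <- universeSimilarityMatrices(u)
    phen <- phenotypeSimilarity(u@termCounts)
    caus <- u@variants[u@variants$class == "causative", ]
    # one test disease per phenotype cluster, so each query keeps an
    # in-cluster training disease as a seed donor
    testD <- u@diseases[c(1, 3)]
    trainD <- setdiff(u@diseases, testD)
    testPos <- caus[caus$disease %in% testD, ]
    seedSets <- lapply(u@diseases, function(d) {
        ss <- collectSeedGenes(d, topSimilarDiseases(d, phen, 3),
                               u@associations)
        filterSeedsUnbiased(ss, testD, testPos, u@associations)
    })
    names(seedSets) <- u@diseases
    bounds <- computeScoreBounds(u@scores)
    ab <- associationScoreBounds(seedSets, mats, u@genes)
    trainPos <- buildPositivePairs(
        caus[caus$disease %in% trainD,
             c("disease", "chrom", "pos", "ref", "alt", "gene")])
    trainPos <- eliminateLeakage(trainPos, testPos)
    neutral <- u@variants[u@variants$class == "neutral", ]
    pool <- buildNegativePool(neutral, trainD)
    trainNeg <- sampleNegativePairs(pool, nrow(trainPos), seed = 2)
    pairs <- rbind(trainPos, trainNeg)
    feat <- assembleFeatureMatrix(pairs, u@scores, seedSets, mats,
                                  bounds, ab)

    maskTo <- function(m, keep) {
        m[, setdiff(colnames(m), keep)] <- 0
        m
    }
    aucWith <- function(keep) {
        model <- trainModel(maskTo(feat, keep), pairs$label,
                            numTrees = 200, seed = 3)
        aucs <- vapply(testD, function(d) {
            pos <- testPos[testPos$disease == d, ]
            neg <- caus[caus$disease %in% trainD, ]
            pp <- data.frame(disease = d,
                             pos[, c("chrom", "pos", "ref", "alt", "gene")])
            np <- data.frame(disease = d,
                             neg[, c("chrom", "pos", "ref", "alt", "gene")])
            fp <- maskTo(assembleFeatureMatrix(pp, u@scores, seedSets,
                                               mats, bounds, ab), keep)
            fn <- maskTo(assembleFeatureMatrix(np, u@scores, seedSets,
                                               mats, bounds, ab), keep)
            pairwiseAuc(-scorePairs(model, fp), -scorePairs(model, fn))
        }, numeric(1))
        mean(aucs)
    }
    expect_gt(aucWith(geneSourceNames()), aucWith(variantScoreNames()))
})

test_that("benchmark AUC is non-decreasing in the planted signal strength", {
    cfg <- universeConfig(n_genes = 150, n_diseases = 20, n_tissues = 20,
                          n_terms = 80, n_pathways = 24, n_domains = 24,
                          n_factors = 24, n_mirnas = 20,
                          n_causative_variants = 200,
                          n_neutral_variants = 400, n_clusters = 5,
                          pool_size = 20, module_size = 4)
    auc <- vapply(c(0, 0.4, 0.8), function(s) {
        cfg$signal_strength <- s
        plantedSignalBenchmark(cfg, seeds = 1:5, numTrees = 150)$meanAuc
    }, numeric(1))
    expect_true(all(diff(auc) >= 0))
    expect_lt(auc[1], 0.6)
    expect_gt(auc[3], 0.85)
})
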