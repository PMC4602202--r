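## Leakage-controlled five-fold cross-validation over a study universe,
## and the planted-signal benchmark that runs it end to end.

.splitNeutralHalves <- function(neutral, seed) {
    rng <- .seededRNG(seed)
    on.exit(.restoreRNG(rng))
    n <- nrow(neutral)
    idx <- sample(n)
    half <- floor(n / 2)
    list(train = neutral[sort(idx[seq_len(half)]), , drop = FALSE],
         test = neutral[sort(idx[seq(half + 1, n)]), , drop = FALSE])
}

.assignFolds <- function(diseases, nFolds, seed) {
    rng <- .seededRNG(seed)
    on.exit(.restoreRNG(rng))
    shuffled <- sample(sort(diseases))
    ## round-robin: with equal positives per disease this balances the
    ## number of positive variants per fold
    stats::setNames(rep(seq_len(nFolds), length.out = length(shuffled)),
                    shuffled)
}

## Rank ratios of the negatives within each per-positive ranking list
## (list = one positive + all negatives), pooled over the positives.
.pooledNegativeRatios <- function(posScores, negScores) {
    base <- rank(-negScores, ties.method = "average")
    tot <- length(negScores) + 1
    unlist(lapply(posScores, function(p)
        (base + (negScores < p) + 0.5 * (negScores == p)) / tot))
}

#' Leakage-controlled cross-validation on a synthetic universe
#'
#' Diseases are partitioned into `nFolds` test subsets (shuffled
#' round-robin, balancing positive variants) and the neutral variants into
#' two halves (training and test).  In each fold a random forest is
#' trained on the positive pairs of the training diseases plus an
#' equal-sized sample of negative pairs, with two leakage rules applied:
#' seed genes associated with any test disease or hosting any test variant
#' are removed before association scores are computed, and training
#' variants sharing a gene with any test variant are discarded.  Each
#' positive test variant is then prioritized against the designated
#' negative test sample.
#'
#' @param universe a [SyntheticUniverse-class].
#' @param negative negative test sample: `"neutral"` (held-out neutral
#'   half), `"disease"` (causative variants of the training diseases,
#'   emulating a disease-variant control set), or `"combined"`.
#' @param k number of phenotypically similar diseases used for seeds.
#' @param numTrees,mtry random-forest hyperparameters.
#' @param nFolds number of folds (default 5).
#' @param seed integer master seed for fold assignment, neutral split,
#'   negative sampling and forest growing.
#' @param matrices optional precomputed similarity matrices
#'   (from [universeSimilarityMatrices()]), to avoid rebuilding.
#' @return A list with elements `perDisease` (data.frame: disease, fold,
#'   nPos, meanRankRatio, auc), `mrr`, `meanAuc`, and `neutralScores`
#'   (per-disease prediction scores of the neutral test variants, for FPR
#'   estimation; only when the negative sample includes neutrals).
#' @export
runCrossValidation <- function(universe, negative = c("neutral", "disease",
                                                      "combined"),
                               k = 10, numTrees = 500,
                               mtry = floor(sqrt(length(featureNames()))),
                               nFolds = 5, seed = 1L, matrices = NULL) {
    negative <- match.arg(negative)
    diseases <- universe@diseases
    if (length(diseases) < nFolds)
        stop("runCrossValidation: fewer diseases than folds")

    if (is.null(matrices)) matrices <- universeSimilarityMatrices(universe)
    phen <- phenotypeSimilarity(universe@termCounts)
    bounds <- computeScoreBounds(universe@scores)
    varAssoc <- universe@variants[universe@variants$class == "causative", ]
    neutral <- universe@variants[universe@variants$class == "neutral", ]
    halves <- .splitNeutralHalves(neutral, seed)
    folds <- .assignFolds(diseases, nFolds, seed + 1L)

    perDisease <- list()
    neutralScores <- list()
    for (f in seq_len(nFolds)) {
        testDiseases <- names(folds)[folds == f]
        trainDiseases <- setdiff(diseases, testDiseases)
        testPos <- varAssoc[varAssoc$disease %in% testDiseases, ]
        negTest <- switch(negative,
            neutral = halves$test,
            disease = varAssoc[varAssoc$disease %in% trainDiseases, ],
            combined = rbind(halves$test[, c("chrom", "pos", "ref", "alt",
                                             "gene")],
                             varAssoc[varAssoc$disease %in% trainDiseases,
                                      c("chrom", "pos", "ref", "alt",
                                        "gene")]))
        ## the gene-holdout filter covers the genuinely held-out test
        ## variants: the positives and the neutral test half
        heldOut <- rbind(testPos[, c("chrom", "pos", "ref", "alt", "gene")],
                         halves$test[, c("chrom", "pos", "ref", "alt",
                                         "gene")])

        ## seed sets with both leakage rules
        seedSets <- lapply(diseases, function(d) {
            sim <- topSimilarDiseases(d, phen, k = k)
            ss <- collectSeedGenes(d, sim, universe@associations)
            filterSeedsUnbiased(ss, testDiseases = testDiseases,
                                testVariants = heldOut,
                                assoc = universe@associations)
        })
        names(seedSets) <- diseases
        assocBounds <- associationScoreBounds(seedSets, matrices,
                                              universe@genes)

        ## training pairs
        trainPos <- buildPositivePairs(
            varAssoc[varAssoc$disease %in% trainDiseases,
                     c("disease", "chrom", "pos", "ref", "alt", "gene")])
        trainPos <- eliminateLeakage(trainPos, heldOut)
        neutTrain <- eliminateLeakage(halves$train, heldOut)
        pool <- buildNegativePool(neutTrain, trainDiseases)
        trainNeg <- sampleNegativePairs(pool, nrow(trainPos),
                                        seed = seed + 10L + f)
        trainPairs <- rbind(trainPos, trainNeg)
        feat <- assembleFeatureMatrix(trainPairs, universe@scores, seedSets,
                                      matrices, bounds, assocBounds)
        model <- trainModel(feat, trainPairs$label, numTrees = numTrees,
                            mtry = mtry, seed = seed + 100L + f)

        ## test: prioritize each positive against the negative sample
        for (d in testDiseases) {
            pos <- testPos[testPos$disease == d, , drop = FALSE]
            if (!nrow(pos)) next
            negPairs <- data.frame(disease = d,
                                   negTest[, c("chrom", "pos", "ref",
                                               "alt", "gene")],
                                   row.names = NULL)
            posPairs <- data.frame(disease = d,
                                   pos[, c("chrom", "pos", "ref", "alt",
                                           "gene")], row.names = NULL)
            negFeat <- assembleFeatureMatrix(negPairs, universe@scores,
                                             seedSets, matrices, bounds,
                                             assocBounds)
            posFeat <- assembleFeatureMatrix(posPairs, universe@scores,
                                             seedSets, matrices, bounds,
                                             assocBounds)
            negScore <- scorePairs(model, negFeat)
            posScore <- scorePairs(model, posFeat)
            tot <- length(negScore) + 1
            ranks <- vapply(posScore, rankOfPositive, numeric(1),
                            negScores = negScore)
            posRatios <- rankRatio(ranks, tot)
            negRatios <- .pooledNegativeRatios(posScore, negScore)
            perDisease[[length(perDisease) + 1L]] <- data.frame(
                disease = d, fold = f, nPos = nrow(pos),
                meanRankRatio = mean(posRatios),
                auc = rankRocAuc(posRatios, negRatios))
            attr(perDisease[[length(perDisease)]], "posRatios") <- posRatios
            if (negative != "disease")
                neutralScores[[d]] <- if (negative == "neutral") negScore
                    else negScore[seq_len(nrow(halves$test))]
        }
    }
    perDisease <- do.call(rbind, perDisease)
    list(perDisease = perDisease,
         mrr = mean(perDisease$meanRankRatio),
         meanAuc = mean(perDisease$auc),
         neutralScores = neutralScores,
         folds = folds)
}

#' End-to-end planted-signal benchmark
#'
#' Generates a universe per seed, runs the full leakage-controlled
#' cross-validation, and reports the mean rank ratio and mean AUC per seed
#' and averaged over seeds.
#'
#' @param cfg a [universeConfig()]; its `seed` field is replaced by each
#'   element of `seeds`.
#' @param seeds integer vector of universe seeds (default 1:5).
#' @param ... passed to [runCrossValidation()].
#' @return A list with `perSeed` (data.frame: seed, mrr, meanAuc), `mrr`,
#'   and `meanAuc` (averages over seeds).
#' @export
plantedSignalBenchmark <- function(cfg = universeConfig(), seeds = 1:5,
                                   ...) {
    rows <- lapply(seeds, function(sd) {
        cfg$seed <- sd
        u <- generateUniverse(cfg)
        cv <- runCrossValidation(u, seed = sd, ...)
        data.frame(seed = sd, mrr = cv$mrr, meanAuc = cv$meanAuc)
    })
    perSeed <- do.call(rbind, rows)
    list(perSeed = perSeed, mrr = mean(perSeed$mrr),
         meanAuc = mean(perSeed$meanAuc))
}
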