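## Training-pair construction, leakage elimination, random-forest training
## and candidate prioritization.

.variantKey <- function(v)
    paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")

.pairKey <- function(p)
    paste(p$disease, .variantKey(p), sep = "|")

#' Build positive disease-variant training pairs
#'
#' One positive pair per known (disease, causative variant) association;
#' duplicate rows are collapsed.  A variant causative for several diseases
#' yields one pair per disease.
#'
#' @param assoc data.frame with columns `disease, chrom, pos, ref, alt,
#'   gene` listing causative variants per disease.
#' @return data.frame of pairs with a `label` column set to "positive".
#' @export
buildPositivePairs <- function(assoc) {
    need <- c("disease", "chrom", "pos", "ref", "alt", "gene")
    if (!all(need %in% names(assoc)))
        stop("buildPositivePairs: need columns ", paste(need, collapse = ", "))
    out <- unique(assoc[, need])
    if (any(is.na(out$gene)))
        stop("buildPositivePairs: every variant needs a host gene")
    out$label <- "positive"
    rownames(out) <- NULL
    out
}

#' Enumerate the pool of negative disease-variant pairs
#'
#' The Cartesian product of the training diseases with the neutral training
#' variants, every pair labeled negative.  Negative training data are later
#' sampled from this pool.
#'
#' @param neutralVariants data.frame of neutral variants (chrom, pos, ref,
#'   alt, gene).
#' @param diseases character vector of training disease ids.
#' @return data.frame of pairs with `label` = "negative".
#' @export
buildNegativePool <- function(neutralVariants, diseases) {
    if (!nrow(neutralVariants) || !length(diseases))
        return(data.frame(disease = character(), chrom = character(),
                          pos = integer(), ref = character(),
                          alt = character(), gene = character(),
                          label = character()))
    idx <- expand.grid(v = seq_len(nrow(neutralVariants)),
                       d = seq_along(diseases))
    out <- neutralVariants[idx$v, c("chrom", "pos", "ref", "alt", "gene")]
    out <- cbind(disease = diseases[idx$d], out)
    out$label <- "negative"
    rownames(out) <- NULL
    out
}

#' Sample negative training pairs from the pool
#'
#' Uniform sample without replacement of exactly `n` pairs, reproducible
#' for a fixed seed.
#'
#' @param pool negative pair pool from [buildNegativePool()].
#' @param n number of pairs to draw (the number of positive pairs).
#' @param seed integer RNG seed.
#' @return data.frame of `n` negative pairs.
#' @export
sampleNegativePairs <- function(pool, n, seed) {
    if (nrow(pool) < n)
        stop("sampleNegativePairs: pool (", nrow(pool),
             ") smaller than requested sample (", n, ")")
    rng <- .seededRNG(seed)
    take <- sample(nrow(pool), n)
    .restoreRNG(rng)
    out <- pool[sort(take), , drop = FALSE]
    rownames(out) <- NULL
    out
}

## Scoped RNG helpers: set a local seed and restore the caller's state.
.seededRNG <- function(seed) {
    old <- if (exists(".Random.seed", .GlobalEnv))
        get(".Random.seed", .GlobalEnv) else NULL
    set.seed(seed)
    old
}
.restoreRNG <- function(old) {
    if (is.null(old)) {
        if (exists(".Random.seed", .GlobalEnv))
            rm(".Random.seed", envir = .GlobalEnv)
    } else assign(".Random.seed", old, .GlobalEnv)
    invisible()
}

#' Remove training pairs that share a gene with any test variant
#'
#' Gene-level holdout: any training pair whose variant lies in a gene that
#' hosts a test variant is discarded, so no gene-level information flows
#' from training into test.  (The companion rule for seed genes is
#' [filterSeedsUnbiased()].)
#'
#' @param trainPairs data.frame of training pairs (with `gene`).
#' @param testVariants data.frame of test variants (with `gene`), or a
#'   character vector of test genes.
#' @return The filtered training pairs; warns if nothing survives.
#' @export
eliminateLeakage <- function(trainPairs, testVariants) {
    testGenes <- if (is.data.frame(testVariants)) testVariants$gene
                 else testVariants
    keep <- !(trainPairs$gene %in% testGenes)
    out <- trainPairs[keep, , drop = FALSE]
    if (!nrow(out) && nrow(trainPairs))
        warning("eliminateLeakage: all training pairs removed; ",
                "every training gene hosts a test variant")
    rownames(out) <- NULL
    out
}

#' Train the random-forest disease-variant classifier
#'
#' Fits a probability random forest on labeled 19-dimensional feature
#' vectors.  The predicted probability of the positive class is the
#' prediction score.  With a fixed seed (and single-threaded growing) the
#' fit and its predictions are reproducible.
#'
#' @param features numeric matrix from [assembleFeatureMatrix()], one row
#'   per pair, 19 columns.
#' @param labels character or factor: "positive" / "negative" per row.
#' @param numTrees number of trees (default 500).
#' @param mtry features tried per split (default `floor(sqrt(19))` = 4).
#' @param seed integer seed for the forest.
#' @return A [VariantForestModel-class].
#' @export
trainModel <- function(features, labels, numTrees = 500,
                       mtry = floor(sqrt(length(featureNames()))),
                       seed = 1L) {
    labels <- factor(as.character(labels), levels = c("negative", "positive"))
    if (length(unique(labels)) < 2)
        stop("trainModel: training data must contain both classes")
    if (!identical(colnames(features), featureNames()))
        stop("trainModel: feature columns must be the canonical 19 features")
    df <- data.frame(features, check.names = FALSE)
    df$.label <- labels
    fit <- ranger::ranger(
        dependent.variable.name = ".label", data = df,
        num.trees = numTrees, mtry = mtry, probability = TRUE,
        seed = seed, num.threads = 1, respect.unordered.factors = TRUE)
    fp <- sprintf("n=%d;pos=%d;sum=%.6f", nrow(features),
                  sum(labels == "positive"), sum(features))
    new("VariantForestModel", forest = fit, featureOrder = featureNames(),
        params = list(num.trees = numTrees, mtry = mtry, seed = seed),
        trainingFingerprint = fp)
}

#' Score disease-variant feature vectors with a trained model
#'
#' @param model a [VariantForestModel-class].
#' @param features numeric matrix with the model's feature layout.
#' @return Numeric vector of prediction scores in \[0, 1\].
#' @export
scorePairs <- function(model, features) {
    if (!identical(colnames(features), model@featureOrder))
        stop("scorePairs: feature layout does not match the model's ",
             "feature-order fingerprint")
    p <- stats::predict(model@forest,
                        data = data.frame(features, check.names = FALSE),
                        num.threads = 1)$predictions
    unname(p[, "positive"])
}

#' Prioritize candidate variants for a query disease
#'
#' Scores each candidate and orders them by decreasing score.  Tied scores
#' receive the average of the ranks they span; the rank ratio is rank
#' divided by the number of candidates.
#'
#' @param model a [VariantForestModel-class].
#' @param disease query disease id.
#' @param candidates data.frame of candidate variants (chrom, pos, ref,
#'   alt, gene).
#' @param features pre-assembled feature matrix for the candidates (rows
#'   aligned with `candidates`).
#' @return A [VariantRanking-class].
#' @export
prioritize <- function(model, disease, candidates, features) {
    if (!nrow(candidates))
        stop("prioritize: no candidates supplied")
    score <- scorePairs(model, features)
    rk <- rank(-score, ties.method = "average")
    ord <- order(rk, .variantKey(candidates))
    tab <- data.frame(candidates[ord, c("chrom", "pos", "ref", "alt",
                                        "gene")],
                      score = score[ord], rank = rk[ord],
                      rank_ratio = rk[ord] / nrow(candidates),
                      row.names = NULL)
    new("VariantRanking", disease = disease, ranking = tab)
}
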