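#' @import methods
NULL

#' Canonical score and source names
#'
#' The eleven variant-level deleteriousness scores and the eight gene-level
#' genomic similarity sources, in the fixed order used by every feature
#' vector in the package. The full 19-dimensional feature layout is the
#' concatenation of the two: variant scores first, then association scores.
#'
#' @return A character vector of names.
#' @examples
#' variantScoreNames()
#' geneSourceNames()
#' featureNames()
#' @export
variantScoreNames <- function() {
    c("SIFT", "PolyPhen2", "LRT", "MutationTaster", "MutationAccessor",
      "MSRV", "GERP", "Phylop", "SiPhy", "CADD", "SInBaD")
}

#' @rdname variantScoreNames
#' @export
geneSourceNames <- function() {
    c("Exp", "GO", "KEGG", "Seq", "Pfam", "PPI", "TSFC", "miRNA")
}

#' @rdname variantScoreNames
#' @export
featureNames <- function() {
    c(variantScoreNames(), geneSourceNames())
}

## Scores for which "smaller is more deleterious": flipped to 1 - x before
## min-max normalization.
flippedScoreNames <- function() c("SIFT", "LRT")

.checkSquareSymmetric <- function(m, lo = 0, hi = 1, tol = 1e-8) {
    msg <- character()
    if (!is.matrix(m) || !is.numeric(m))
        msg <- c(msg, "'sim' must be a numeric matrix")
    else {
        if (nrow(m) != ncol(m))
            msg <- c(msg, "'sim' must be square")
        if (is.null(rownames(m)) || is.null(colnames(m)) ||
            !identical(rownames(m), colnames(m)))
            msg <- c(msg, "'sim' must have identical row and column names")
        if (anyNA(m) || any(!is.finite(m)))
            msg <- c(msg, "'sim' must be finite")
        else {
            if (any(m < lo - tol) || any(m > hi + tol))
                msg <- c(msg, sprintf("'sim' values must lie in [%g, %g]", lo, hi))
            if (nrow(m) > 0 && max(abs(m - t(m))) > tol)
                msg <- c(msg, "'sim' must be symmetric")
        }
    }
    msg
}

#' GeneSimilarityMatrix
#'
#' A symmetric gene-by-gene functional similarity matrix derived from one
#' genomic data source, after the exponential transformation
#' \eqn{S = \exp((r - 1)/\sigma)} of raw similarities \eqn{r}.  Genes not
#' covered by the source carry zero rows/columns (coverage convention), so
#' values lie in \eqn{[0, 1]} with 1 on the diagonal of covered genes.
#'
#' @slot source single character, one of [geneSourceNames()].
#' @slot sigma standard deviation of the off-diagonal raw similarities used
#'   by the exponential transform.
#' @slot sim numeric matrix with gene ids as dimnames.
#' @slot covered character vector of gene ids covered by the source.
#'
#' @seealso [buildSimilarityMatrix()], [exponentialTransform()]
#' @export
setClass("GeneSimilarityMatrix",
    representation(source = "character", sigma = "numeric",
                   sim = "matrix", covered = "character"),
    validity = function(object) {
        msg <- character()
        if (length(object@source) != 1L)
            msg <- c(msg, "'source' must be a single string")
        if (length(object@sigma) != 1L || !is.finite(object@sigma) ||
            object@sigma <= 0)
            msg <- c(msg, "'sigma' must be a single positive number")
        msg <- c(msg, .checkSquareSymmetric(object@sim))
        if (!all(object@covered %in% rownames(object@sim)))
            msg <- c(msg, "'covered' genes must appear in 'sim'")
        if (length(msg)) msg else TRUE
    })

#' PhenotypeSimilarityMatrix
#'
#' Disease-by-disease phenotype similarity: the cosine of the angle between
#' TF-IDF weighted term vectors of the disease records.  Diseases with empty
#' records have zero vectors and similarity 0 to everything (including
#' themselves).
#'
#' @slot sim numeric symmetric matrix with disease ids as dimnames.
#' @seealso [phenotypeSimilarity()], [topSimilarDiseases()]
#' @export
setClass("PhenotypeSimilarityMatrix",
    representation(sim = "matrix"),
    validity = function(object) {
        msg <- .checkSquareSymmetric(object@sim)
        if (length(msg)) msg else TRUE
    })

#' SeedGeneSet
#'
#' The seed genes anchoring guilt-by-association scoring for one query
#' disease: genes known to be associated with the query disease or with one
#' of its most phenotypically similar diseases.  \code{provenance} maps each
#' seed gene to the disease(s) that contributed it.
#'
#' @slot query query disease id.
#' @slot seeds character vector of unique gene ids.
#' @slot provenance named list, gene id -> character vector of disease ids.
#' @seealso [collectSeedGenes()], [filterSeedsUnbiased()]
#' @export
setClass("SeedGeneSet",
    representation(query = "character", seeds = "character",
                   provenance = "list"),
    validity = function(object) {
        msg <- character()
        if (length(object@query) != 1L)
            msg <- c(msg, "'query' must be a single disease id")
        if (anyDuplicated(object@seeds))
            msg <- c(msg, "'seeds' must be unique")
        if (length(object@seeds) && !setequal(names(object@provenance),
                                              object@seeds))
            msg <- c(msg, "'provenance' must be named by the seed genes")
        if (length(msg)) msg else TRUE
    })

#' VariantForestModel
#'
#' A trained random-forest classifier over 19-dimensional disease-variant
#' feature vectors.  The out-of-bag probability of the positive class is the
#' prediction score.  \code{featureOrder} records the feature layout the
#' model was trained on; scoring refuses a mismatching layout.
#'
#' @slot forest the fitted \pkg{ranger} probability forest.
#' @slot featureOrder character vector, the feature layout fingerprint.
#' @slot params list of hyperparameters (num.trees, mtry, seed).
#' @slot trainingFingerprint single character digest of the training set.
#' @seealso [trainModel()], [scorePairs()], [prioritize()]
#' @export
setClass("VariantForestModel",
    representation(forest = "ANY", featureOrder = "character",
                   params = "list", trainingFingerprint = "character"),
    validity = function(object) {
        msg <- character()
        if (!inherits(object@forest, "ranger"))
            msg <- c(msg, "'forest' must be a ranger fit")
        if (!identical(object@featureOrder, featureNames()))
            msg <- c(msg, "'featureOrder' must be the canonical 19 features")
        if (length(msg)) msg else TRUE
    })

#' VariantRanking
#'
#' A ranked candidate list for one query disease.  Candidates are ordered by
#' decreasing prediction score; tied scores receive the average of the ranks
#' they span, and the rank ratio is rank divided by the number of candidates.
#'
#' @slot disease query disease id.
#' @slot ranking data.frame with columns chrom, pos, ref, alt, gene, score,
#'   rank, rank_ratio, ordered by increasing rank.
#' @seealso [prioritize()]
#' @export
setClass("VariantRanking",
    representation(disease = "character", ranking = "data.frame"),
    validity = function(object) {
        msg <- character()
        need <- c("chrom", "pos", "ref", "alt", "gene", "score",
                  "rank", "rank_ratio")
        if (!all(need %in% names(object@ranking)))
            msg <- c(msg, paste("'ranking' must have columns",
                                paste(need, collapse = ", ")))
        else {
            if (any(object@ranking$score < -1e-9 | object@ranking$score > 1 + 1e-9))
                msg <- c(msg, "scores must lie in [0, 1]")
            if (is.unsorted(object@ranking$rank))
                msg <- c(msg, "'ranking' must be ordered by rank")
        }
        if (length(msg)) msg else TRUE
    })

#' SyntheticUniverse
#'
#' A self-contained synthetic study universe: genes, diseases, truth
#' disease-gene associations, causative and neutral variants with raw
#' functional scores, the eight raw genomic source tables, and a disease
#' phenotype term-count matrix.  Generated deterministically from a
#' [universeConfig()] by [generateUniverse()].
#'
#' @slot config the generating configuration (list).
#' @slot genes character vector of gene ids.
#' @slot diseases character vector of disease ids.
#' @slot associations data.frame(disease, gene): truth associations.
#' @slot variants data.frame(chrom, pos, ref, alt, gene, class, disease)
#'   where class is "causative" or "neutral" and disease is NA for neutral
#'   variants.
#' @slot scores data.frame keyed by chrom, pos, ref, alt, gene with one
#'   column per variant score (NA = missing).
#' @slot sources named list of raw source tables (expression matrix, gene
#'   sets, annotations, edge lists, count matrix).
#' @slot termCounts integer matrix diseases x phenotype terms.
#' @seealso [generateUniverse()], [writeUniverse()]
#' @export
setClass("SyntheticUniverse",
    representation(config = "list", genes = "character",
                   diseases = "character", associations = "data.frame",
                   variants = "data.frame", scores = "data.frame",
                   sources = "list", termCounts = "matrix"),
    validity = function(object) {
        msg <- character()
        if (!all(c("disease", "gene") %in% names(object@associations)))
            msg <- c(msg, "'associations' needs disease and gene columns")
        need <- c("chrom", "pos", "ref", "alt", "gene", "class", "disease")
        if (!all(need %in% names(object@variants)))
            msg <- c(msg, "'variants' missing required columns")
        else {
            caus <- object@variants[object@variants$class == "causative", ]
            key <- paste(caus$disease, caus$gene)
            truth <- paste(object@associations$disease,
                           object@associations$gene)
            if (!all(key %in% truth))
                msg <- c(msg,
                    "every causative variant must lie in a truth-associated gene")
        }
        if (length(msg)) msg else TRUE
    })
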