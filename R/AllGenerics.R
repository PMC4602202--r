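#' Accessors for similarity matrices and models
#'
#' `simSource()` returns the genomic source tag of a
#' [GeneSimilarityMatrix-class]; `simSigma()` the standard deviation used by
#' its exponential transform; `coveredGenes()` the genes the source covers.
#' `as.matrix()` returns the underlying numeric matrix for both similarity
#' classes.  `seedGenes()` returns the gene ids of a [SeedGeneSet-class] and
#' `seedProvenance()` their contributing diseases.  `rankingTable()` extracts
#' the ordered candidate table of a [VariantRanking-class].
#'
#' @param object,x an object of the documented class.
#' @param ... ignored.
#' @return See details above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("simSource", function(object) standardGeneric("simSource"))

#' @rdname accessors
#' @export
setGeneric("simSigma", function(object) standardGeneric("simSigma"))

#' @rdname accessors
#' @export
setGeneric("coveredGenes", function(object) standardGeneric("coveredGenes"))

#' @rdname accessors
#' @export
setGeneric("seedGenes", function(object) standardGeneric("seedGenes"))

#' @rdname accessors
#' @export
setGeneric("seedProvenance",
           function(object) standardGeneric("seedProvenance"))

#' @rdname accessors
#' @export
setGeneric("rankingTable", function(object) standardGeneric("rankingTable"))

#' @rdname accessors
#' @export
setMethod("simSource", "GeneSimilarityMatrix", function(object) object@source)

#' @rdname accessors
#' @export
setMethod("simSigma", "GeneSimilarityMatrix", function(object) object@sigma)

#' @rdname accessors
#' @export
setMethod("coveredGenes", "GeneSimilarityMatrix",
          function(object) object@covered)

#' @rdname accessors
#' @export
setMethod("as.matrix", "GeneSimilarityMatrix", function(x, ...) x@sim)

#' @rdname accessors
#' @export
setMethod("as.matrix", "PhenotypeSimilarityMatrix", function(x, ...) x@sim)

#' @rdname accessors
#' @export
setMethod("seedGenes", "SeedGeneSet", function(object) object@seeds)

#' @rdname accessors
#' @export
setMethod("seedProvenance", "SeedGeneSet", function(object) object@provenance)

#' @rdname accessors
#' @export
setMethod("rankingTable", "VariantRanking", function(object) object@ranking)

setMethod("show", "GeneSimilarityMatrix", function(object) {
    cat("GeneSimilarityMatrix [", object@source, "]\n", sep = "")
    cat("  genes:", nrow(object@sim),
        " covered:", length(object@covered), "\n")
    cat("  sigma:", format(object@sigma, digits = 4), "\n")
})

setMethod("show", "PhenotypeSimilarityMatrix", function(object) {
    cat("PhenotypeSimilarityMatrix\n")
    cat("  diseases:", nrow(object@sim), "\n")
})

setMethod("show", "SeedGeneSet", function(object) {
    cat("SeedGeneSet for disease", object@query, "\n")
    cat("  seeds:", length(object@seeds), "\n")
    if (length(object@seeds))
        cat("  ", paste(utils::head(object@seeds, 8), collapse = ", "),
            if (length(object@seeds) > 8) ", ..." else "", "\n", sep = "")
})

setMethod("show", "VariantForestModel", function(object) {
    cat("VariantForestModel (random forest, probability)\n")
    cat("  trees:", object@params$num.trees,
        " mtry:", object@params$mtry, "\n")
    cat("  features:", length(object@featureOrder), "\n")
    cat("  training fingerprint:", object@trainingFingerprint, "\n")
})

setMethod("show", "VariantRanking", function(object) {
    cat("VariantRanking for disease", object@disease, "-",
        nrow(object@ranking), "candidates\n")
    print(utils::head(object@ranking, 5))
    if (nrow(object@ranking) > 5) cat("  ...\n")
})

setMethod("show", "SyntheticUniverse", function(object) {
    v <- object@variants
    cat("SyntheticUniverse\n")
    cat("  genes:", length(object@genes),
        " diseases:", length(object@diseases), "\n")
    cat("  causative variants:", sum(v$class == "causative"),
        " neutral:", sum(v$class == "neutral"), "\n")
    cat("  signal strength:", object@config$signal_strength,
        " seed:", object@config$seed, "\n")
})
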