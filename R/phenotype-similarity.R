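## Disease phenotype similarity from standardized term counts.
##
## Disease records arrive as a disease x term count matrix (the product of
## an upstream text-mining step mapping record text onto standardized
## vocabulary terms).  Records are TF-IDF weighted and compared by cosine.

#' TF-IDF weighted disease term vectors
#'
#' For each disease record, the coordinate of term t is
#' \eqn{TF(t, d) \cdot IDF(t)} with
#' \eqn{TF(t,d) = count(t,d) / \sum_{t'} count(t',d)} (relative occurrence
#' frequency within the record) and
#' \eqn{IDF(t) = -\log(n_d(t) / N)} (negative log of the fraction of
#' records containing the term).  An all-zero record yields a zero vector
#' with a warning.  The IDF logarithm base rescales all coordinates
#' uniformly and so cannot affect downstream cosines.
#'
#' @param counts numeric matrix, diseases x terms, non-negative counts,
#'   with disease ids as rownames.
#' @param logBase base of the IDF logarithm (default natural).
#' @return A numeric matrix of the same shape holding TF-IDF weights.
#' @examples
#' m <- rbind(d1 = c(a = 2, b = 1, c = 0), d2 = c(1, 0, 1), d3 = c(0, 0, 3))
#' tfidfVectors(m)
#' @export
tfidfVectors <- function(counts, logBase = exp(1)) {
    counts <- as.matrix(counts)
    if (nrow(counts) == 0 || ncol(counts) == 0)
        stop("tfidfVectors: empty corpus")
    if (any(counts < 0)) stop("tfidfVectors: negative counts")
    tot <- rowSums(counts)
    if (any(tot == 0))
        warning("tfidfVectors: ", sum(tot == 0),
                " empty disease record(s) produce zero vectors")
    tf <- counts / ifelse(tot == 0, 1, tot)
    df <- colSums(counts > 0)
    idf <- ifelse(df > 0, -log(df / nrow(counts)) / log(logBase), 0)
    sweep(tf, 2, idf, `*`)
}

#' Disease-by-disease phenotype similarity matrix
#'
#' Cosine similarity between TF-IDF disease vectors.  Diseases whose
#' vectors are all zero (empty records, or records made only of ubiquitous
#' terms with IDF 0) have similarity 0 to every disease including
#' themselves.
#'
#' @param vectors TF-IDF matrix from [tfidfVectors()], or a raw count
#'   matrix which is TF-IDF weighted first.
#' @param weighted set to `FALSE` if `vectors` is already weighted.
#' @return A [PhenotypeSimilarityMatrix-class].
#' @examples
#' m <- rbind(d1 = c(2, 1, 0), d2 = c(1, 0, 1), d3 = c(0, 0, 3))
#' phenotypeSimilarity(m)
#' @export
phenotypeSimilarity <- function(vectors, weighted = FALSE) {
    v <- as.matrix(vectors)
    if (!weighted) v <- tfidfVectors(v)
    nrm <- sqrt(rowSums(v^2))
    ok <- nrm > 0
    sim <- matrix(0, nrow(v), nrow(v),
                  dimnames = list(rownames(v), rownames(v)))
    if (any(ok)) {
        x <- v[ok, , drop = FALSE] / nrm[ok]
        sim[ok, ok] <- pmin(tcrossprod(x), 1)
        diag(sim)[!ok] <- 0
    }
    diag(sim)[ok] <- 1
    sim <- (sim + t(sim)) / 2
    new("PhenotypeSimilarityMatrix", sim = sim)
}

#' Most phenotypically similar diseases to a query
#'
#' Returns the `k` diseases with the highest phenotype similarity to the
#' query, excluding the query itself.  Ties at the cutoff are broken by
#' lexicographic disease id so the output is deterministic.  If fewer than
#' `k` other diseases exist, all are returned.
#'
#' @param query disease id present in `M`.
#' @param M a [PhenotypeSimilarityMatrix-class].
#' @param k number of diseases to return (default 10).
#' @return Character vector of disease ids, most similar first.
#' @export
topSimilarDiseases <- function(query, M, k = 10) {
    sim <- as.matrix(M)
    if (!query %in% rownames(sim))
        stop("topSimilarDiseases: unknown query disease '", query, "'")
    s <- sim[query, setdiff(rownames(sim), query)]
    if (!length(s)) return(character())
    ord <- order(-s, names(s))
    names(s)[ord][seq_len(min(k, length(s)))]
}

#' Collect seed genes for a query disease
#'
#' Seed genes are the union of genes known to be associated with the query
#' disease or with any of the supplied phenotypically similar diseases.
#' Each seed records which disease(s) contributed it.
#'
#' @param query query disease id.
#' @param similar character vector of similar disease ids (typically from
#'   [topSimilarDiseases()]).
#' @param assoc data.frame with columns `disease` and `gene`.
#' @return A [SeedGeneSet-class]; possibly empty.
#' @export
collectSeedGenes <- function(query, similar, assoc) {
    if (!all(c("disease", "gene") %in% names(assoc)))
        stop("collectSeedGenes: 'assoc' needs columns disease, gene")
    use <- assoc[assoc$disease %in% c(query, similar), , drop = FALSE]
    seeds <- sort(unique(use$gene))
    prov <- lapply(seeds, function(g)
        sort(unique(use$disease[use$gene == g])))
    names(prov) <- seeds
    new("SeedGeneSet", query = query, seeds = seeds, provenance = prov)
}

#' Remove seed genes that would leak test information
#'
#' Training-side seed sets must not carry information about held-out data:
#' a seed gene is dropped if it is associated with any test disease or if
#' it hosts any test variant.
#'
#' @param seeds a [SeedGeneSet-class].
#' @param testDiseases character vector of held-out disease ids.
#' @param testVariants data.frame of held-out variants with a `gene`
#'   column, or a character vector of their host genes.
#' @param assoc data.frame(disease, gene) of known associations, used to
#'   find genes tied to the test diseases.
#' @return The filtered [SeedGeneSet-class].
#' @export
filterSeedsUnbiased <- function(seeds, testDiseases = character(),
                                testVariants = NULL, assoc = NULL) {
    banned <- character()
    if (length(testDiseases) && !is.null(assoc))
        banned <- c(banned,
                    assoc$gene[assoc$disease %in% testDiseases])
    if (!is.null(testVariants)) {
        banned <- c(banned, if (is.data.frame(testVariants))
            testVariants$gene else testVariants)
    }
    keep <- setdiff(seedGenes(seeds), banned)
    new("SeedGeneSet", query = seeds@query, seeds = keep,
        provenance = seedProvenance(seeds)[keep])
}
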