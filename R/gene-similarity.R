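## Gene functional similarity matrices.
##
## Eight genomic sources, one raw similarity measure each:
##   Exp           |Pearson correlation| of expression profiles
##   GO            cosine over information-content weighted term vectors
##   KEGG/Pfam/miRNA  cosine over binary membership vectors
##   TSFC          cosine over binding-site count vectors
##   Seq/PPI       linear transform of shortest-path distances in a network
## followed, in every case, by the exponential transform
## S = exp((r - 1) / sigma), sigma = sd of all off-diagonal raw values.

#' Cosine similarity between two non-negative profile vectors
#'
#' Raw similarity used for ontology, pathway, domain, regulation and
#' microRNA profiles: the cosine of the angle between two vectors.  Profiles
#' here are non-negative, so the value lies in \[0, 1\].  A zero vector has
#' cosine 0 with everything.
#'
#' @param u,v numeric vectors of equal length.
#' @return A single value in \[0, 1\].
#' @examples
#' cosineSimilarity(c(1, 1, 0), c(1, 0, 0))  # 1/sqrt(2)
#' @export
cosineSimilarity <- function(u, v) {
    if (length(u) != length(v))
        stop("cosineSimilarity: vectors differ in length (",
             length(u), " vs ", length(v), ")")
    nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
    if (nu == 0 || nv == 0) return(0)
    min(1, sum(u * v) / (nu * nv))
}

#' Expression raw similarity: absolute Pearson correlation
#'
#' The raw similarity between two gene expression profiles is the absolute
#' value of the Pearson correlation coefficient, so strong anticorrelation
#' counts as strong similarity.  A constant profile (correlation undefined)
#' yields 0.
#'
#' @param u,v numeric expression profiles of equal length >= 2.
#' @return A single value in \[0, 1\].
#' @examples
#' expressionRawSimilarity(c(1, 2, 3), c(3, 2, 1))  # 1: anticorrelated
#' @export
expressionRawSimilarity <- function(u, v) {
    if (length(u) != length(v) || length(u) < 2)
        stop("expressionRawSimilarity: profiles must have equal length >= 2")
    if (stats::sd(u) == 0 || stats::sd(v) == 0) return(0)
    min(1, abs(stats::cor(u, v)))
}

#' Information-content weighted term profiles
#'
#' Represents each gene as a vector over ontology terms, where the
#' coordinate for term t is its information content
#' \eqn{IC(t) = -\log(n_t / N)} (relative annotation frequency among the N
#' annotated genes) if the gene carries the annotation, else 0.  The
#' logarithm base only rescales all coordinates by a constant, so downstream
#' cosine similarities are base-invariant; the natural logarithm is used.
#'
#' @param annotations data.frame with columns `gene` and `term`.
#' @param terms optional character vector fixing the term order; defaults to
#'   the sorted unique annotated terms.
#' @param logBase base of the logarithm (default `exp(1)`).
#' @return A numeric matrix, genes x terms.
#' @examples
#' ann <- data.frame(gene = c("g1", "g2", "g2"), term = c("t1", "t1", "t2"))
#' informationContentProfile(ann)
#' @export
informationContentProfile <- function(annotations, terms = NULL,
                                      logBase = exp(1)) {
    if (!all(c("gene", "term") %in% names(annotations)))
        stop("informationContentProfile: need columns 'gene' and 'term'")
    if (nrow(annotations) == 0)
        stop("informationContentProfile: empty annotation corpus")
    annotations <- unique(annotations[, c("gene", "term")])
    genes <- sort(unique(annotations$gene))
    if (is.null(terms)) terms <- sort(unique(annotations$term))
    nGenes <- length(genes)
    termFreq <- table(factor(annotations$term, levels = terms))
    ic <- ifelse(termFreq > 0, -log(as.numeric(termFreq) / nGenes) /
                     log(logBase), 0)
    names(ic) <- terms
    prof <- matrix(0, nGenes, length(terms), dimnames = list(genes, terms))
    idx <- cbind(match(annotations$gene, genes),
                 match(annotations$term, terms))
    keep <- !is.na(idx[, 2])
    prof[idx[keep, , drop = FALSE]] <- ic[idx[keep, 2]]
    prof
}

#' Shortest-path raw similarity over an unweighted gene network
#'
#' Computes breadth-first shortest-path distances between all node pairs and
#' maps them linearly to similarities: \eqn{r = 1 - d / D} with D the
#' largest finite distance in the network.  Disconnected pairs get 0; every
#' node has self-similarity 1.
#'
#' @param edges data.frame with two columns of gene ids (undirected edges),
#'   or an \pkg{igraph} graph.
#' @param nodes optional character vector of node ids to include even when
#'   isolated.
#' @return A symmetric numeric matrix of raw similarities in \[0, 1\].
#' @examples
#' shortestPathRawSimilarity(data.frame(a = "g1", b = "g2"))
#' @export
shortestPathRawSimilarity <- function(edges, nodes = NULL) {
    if (inherits(edges, "igraph")) {
        g <- edges
    } else {
        em <- as.matrix(edges[, 1:2, drop = FALSE])
        storage.mode(em) <- "character"
        keep <- em[, 1] != em[, 2]           # drop self-loops
        g <- igraph::graph_from_edgelist(em[keep, , drop = FALSE],
                                         directed = FALSE)
        g <- igraph::simplify(g)
        if (!is.null(nodes)) {
            miss <- setdiff(nodes, igraph::V(g)$name)
            if (length(miss)) g <- igraph::add_vertices(g, length(miss),
                                                        name = miss)
        }
    }
    if (igraph::vcount(g) == 0)
        stop("shortestPathRawSimilarity: empty network")
    d <- igraph::distances(g, algorithm = "unweighted")
    finite <- d[is.finite(d)]
    D <- max(finite)
    if (D == 0) {                      # single nodes / no edges
        r <- diag(nrow(d))
        dimnames(r) <- dimnames(d)
        return(r)
    }
    r <- 1 - d / D
    r[!is.finite(d)] <- 0
    ord <- order(rownames(r))
    r[ord, ord, drop = FALSE]
}

#' Exponential transformation of a raw similarity matrix
#'
#' Sharpens raw similarities with \eqn{S = \exp((r - 1)/\sigma)}, where
#' \eqn{\sigma} is the standard deviation of all off-diagonal raw values.
#' The transform maps r = 1 to 1, is strictly increasing in r, and
#' amplifies the gap between large and small similarities, which suppresses
#' weak background similarity.  The structurally-1 diagonal is excluded from
#' \eqn{\sigma} so it does not shrink the spread.
#'
#' @param raw symmetric numeric matrix of raw similarities in \[0, 1\] with
#'   gene ids as dimnames.
#' @param source source tag for the result, one of [geneSourceNames()].
#' @param covered gene ids regarded as covered by the source (defaults to
#'   all rows of `raw`).
#' @return A [GeneSimilarityMatrix-class].
#' @examples
#' r <- matrix(c(1, .5, .5, 1), 2, dimnames = list(c("a","b"), c("a","b")))
#' ## needs >= 2 distinct off-diagonal values in practice:
#' r3 <- matrix(c(1, .2, .8, .2, 1, .5, .8, .5, 1), 3,
#'              dimnames = rep(list(c("a","b","c")), 2))
#' exponentialTransform(r3, "PPI")
#' @export
exponentialTransform <- function(raw, source = "PPI",
                                 covered = rownames(raw)) {
    stopifnot(is.matrix(raw), nrow(raw) == ncol(raw))
    off <- raw[row(raw) != col(raw)]
    sigma <- stats::sd(off)
    if (!length(off) || is.na(sigma) || sigma == 0)
        stop("exponentialTransform: off-diagonal raw similarities are ",
             "constant (sigma = 0); the transform is undefined")
    s <- exp((raw - 1) / sigma)
    s <- (s + t(s)) / 2                 # exact symmetry under fp noise
    new("GeneSimilarityMatrix", source = source, sigma = sigma, sim = s,
        covered = covered)
}

.pairwiseRaw <- function(profiles, fun) {
    n <- nrow(profiles)
    r <- diag(1, n)
    dimnames(r) <- list(rownames(profiles), rownames(profiles))
    if (n < 2) return(r)
    for (i in seq_len(n - 1)) {
        for (j in seq(i + 1, n)) {
            r[i, j] <- r[j, i] <- fun(profiles[i, ], profiles[j, ])
        }
    }
    ## self-similarity of an all-zero profile is undefined; keep diag 1
    r
}

## Fast cosine of all row pairs; zero rows get similarity 0 everywhere
## (their self-similarity is kept at 1 for presence in the source).
.cosineMatrix <- function(profiles) {
    nrm <- sqrt(rowSums(profiles^2))
    ok <- nrm > 0
    r <- matrix(0, nrow(profiles), nrow(profiles),
                dimnames = list(rownames(profiles), rownames(profiles)))
    if (any(ok)) {
        x <- profiles[ok, , drop = FALSE] / nrm[ok]
        r[ok, ok] <- pmin(tcrossprod(x), 1)
    }
    diag(r) <- 1
    (r + t(r)) / 2
}

.absCorMatrix <- function(profiles) {
    ok <- apply(profiles, 1, stats::sd) > 0
    r <- matrix(0, nrow(profiles), nrow(profiles),
                dimnames = list(rownames(profiles), rownames(profiles)))
    if (sum(ok) >= 2)
        r[ok, ok] <- pmin(abs(stats::cor(t(profiles[ok, , drop = FALSE]))), 1)
    diag(r) <- 1
    (r + t(r)) / 2
}

.membershipProfiles <- function(sets, genes) {
    prof <- matrix(0, length(genes), length(sets),
                   dimnames = list(genes, names(sets)))
    for (s in seq_along(sets)) {
        hit <- intersect(sets[[s]], genes)
        prof[hit, s] <- 1
    }
    prof
}

#' Build the gene functional similarity matrix for one genomic source
#'
#' Dispatches to the raw similarity measure appropriate for the source,
#' then applies [exponentialTransform()]:
#' \describe{
#'   \item{Exp}{`inputs` is a numeric expression matrix (genes x tissues);
#'     raw = absolute Pearson correlation.}
#'   \item{GO}{`inputs` is a data.frame(gene, term); raw = cosine over
#'     information-content weighted vectors.}
#'   \item{KEGG, Pfam, miRNA}{`inputs` is a named list of gene sets; raw =
#'     cosine over binary membership vectors.}
#'   \item{TSFC}{`inputs` is a count matrix (genes x transcription factors);
#'     raw = cosine over count vectors.}
#'   \item{Seq, PPI}{`inputs` is an undirected edge list (two-column
#'     data.frame) or igraph graph; raw = linear transform of shortest-path
#'     distances.}
#' }
#' Genes listed in `genes` but absent from the source are retained with
#' similarity 0 to all other genes (and 0 self-similarity), so downstream
#' association scores treat them as uninformative.
#'
#' @param source one of [geneSourceNames()].
#' @param inputs source-specific raw data, see Details.
#' @param genes optional character vector: the gene universe over which the
#'   matrix is laid out.  Defaults to the genes present in the source.
#' @return A [GeneSimilarityMatrix-class].
#' @examples
#' sets <- list(p1 = c("g1", "g2"), p2 = c("g2", "g3"), p3 = "g3")
#' buildSimilarityMatrix("KEGG", sets)
#' @export
buildSimilarityMatrix <- function(source, inputs, genes = NULL) {
    source <- match.arg(source, geneSourceNames())
    raw <- switch(source,
        Exp = {
            m <- as.matrix(inputs)
            .absCorMatrix(m)
        },
        GO = {
            prof <- informationContentProfile(inputs)
            .cosineMatrix(prof)
        },
        KEGG = , Pfam = , miRNA = {
            srcGenes <- sort(unique(unlist(inputs)))
            .cosineMatrix(.membershipProfiles(inputs, srcGenes))
        },
        TSFC = {
            m <- as.matrix(inputs)
            .cosineMatrix(m)
        },
        Seq = , PPI = shortestPathRawSimilarity(inputs)
    )
    covered <- rownames(raw)
    out <- exponentialTransform(raw, source = source, covered = covered)
    if (!is.null(genes)) {
        genes <- unique(c(genes, covered))
        full <- matrix(0, length(genes), length(genes),
                       dimnames = list(genes, genes))
        full[covered, covered] <- out@sim
        out <- new("GeneSimilarityMatrix", source = source,
                   sigma = out@sigma, sim = full, covered = covered)
    }
    out
}
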