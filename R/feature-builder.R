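## Assembly of the 19-dimensional disease-variant feature vector:
## 11 min-max normalized variant deleteriousness scores followed by 8
## min-max normalized gene-level guilt-by-association scores.

#' Guilt-by-association score of a gene for a query disease
#'
#' The raw association score of a candidate gene under one genomic source
#' is the summation of gene functional similarities between the candidate
#' and every seed gene of the query disease.  Pairs absent from the matrix
#' contribute 0; an empty seed set scores 0.
#'
#' @param gene candidate gene id.
#' @param seeds a [SeedGeneSet-class] or character vector of seed genes.
#' @param M a [GeneSimilarityMatrix-class].
#' @return A single non-negative number.
#' @export
associationScore <- function(gene, seeds, M) {
    s <- if (is(seeds, "SeedGeneSet")) seedGenes(seeds) else seeds
    if (!length(s)) return(0)
    sim <- as.matrix(M)
    if (!gene %in% rownames(sim)) return(0)
    s <- intersect(s, colnames(sim))
    if (!length(s)) return(0)
    sum(sim[gene, s])
}

## Vectorized form over many genes, used by the pipeline.
.associationScores <- function(genes, seeds, M) {
    s <- if (is(seeds, "SeedGeneSet")) seedGenes(seeds) else seeds
    out <- stats::setNames(numeric(length(genes)), genes)
    if (!length(s)) return(out)
    sim <- as.matrix(M)
    s <- intersect(s, colnames(sim))
    g <- intersect(unique(genes), rownames(sim))
    if (length(s) && length(g)) {
        sums <- rowSums(sim[g, s, drop = FALSE])
        out[genes %in% g] <- sums[genes[genes %in% g]]
    }
    out
}

#' Score bounds for min-max normalization
#'
#' Computes, for every variant score column of a reference score table, the
#' minimum and maximum used for min-max normalization.  For scores where a
#' smaller value means more deleterious (SIFT, LRT) the bounds are computed
#' on the flipped scale `1 - x`, matching how the scores are normalized.
#'
#' @param scoreTable data.frame with the 11 score columns (NAs allowed).
#' @param scoreNames which columns to bound (default all 11).
#' @return data.frame(score, min, max).
#' @export
computeScoreBounds <- function(scoreTable, scoreNames = variantScoreNames()) {
    rows <- lapply(scoreNames, function(nm) {
        x <- scoreTable[[nm]]
        x <- x[!is.na(x)]
        if (nm %in% flippedScoreNames()) x <- 1 - x
        if (!length(x)) return(data.frame(score = nm, min = NA_real_,
                                          max = NA_real_))
        data.frame(score = nm, min = min(x), max = max(x))
    })
    do.call(rbind, rows)
}

#' Min-max normalize a raw variant deleteriousness score
#'
#' Adjusts a raw score so it lies in \[0, 1\] with larger values meaning
#' stronger evidence of damage.  SIFT and LRT are flipped to `1 - x` first
#' (their raw convention is smaller-is-more-deleterious); all scores are
#' then mapped by `(x - min) / (max - min)` with the bounds taken from the
#' whole reference score database (on the flipped scale for SIFT/LRT).
#' Values beyond the recorded bounds are clipped; a missing value becomes 0.
#'
#' @param name score name, one of [variantScoreNames()].
#' @param raw raw score value(s); `NA` = missing.
#' @param bounds data.frame(score, min, max) from [computeScoreBounds()].
#' @return Normalized value(s) in \[0, 1\].
#' @export
normalizeVariantScore <- function(name, raw, bounds) {
    b <- bounds[bounds$score == name, , drop = FALSE]
    if (nrow(b) != 1 || is.na(b$min) || is.na(b$max))
        stop("normalizeVariantScore: no bounds recorded for '", name, "'")
    if (b$max <= b$min)
        stop("normalizeVariantScore: degenerate bounds for '", name, "'")
    if (name %in% flippedScoreNames()) raw <- 1 - raw
    out <- (raw - b$min) / (b$max - b$min)
    out <- pmin(1, pmax(0, out))
    out[is.na(out)] <- 0
    out
}

#' Min-max normalize a raw association score
#'
#' Gene-level association scores are mapped to \[0, 1\] per genomic source
#' with bounds taken over the full disease x gene association score table
#' for that source.  Genes not covered by the source (raw score 0 with no
#' similarity information) normalize to whatever 0 maps to under the
#' source's bounds, clipped to \[0, 1\]; missing values become 0.
#'
#' @param raw raw association score(s).
#' @param lo,hi bounds for the source (`hi > lo`).
#' @return Normalized value(s) in \[0, 1\].
#' @export
normalizeAssociationScore <- function(raw, lo, hi) {
    if (!is.finite(lo) || !is.finite(hi) || hi <= lo)
        stop("normalizeAssociationScore: degenerate bounds [", lo, ", ",
             hi, "]")
    out <- pmin(1, pmax(0, (raw - lo) / (hi - lo)))
    out[is.na(out)] <- 0
    out
}

#' Association-score bounds per source over a disease x gene score table
#'
#' Computes the reference min/max per genomic source by scoring every
#' (disease, gene) combination in the supplied universe: for each disease
#' its seed set, for each gene the summed similarity to the seeds.
#'
#' @param seedSets named list of [SeedGeneSet-class], one per disease.
#' @param matrices named list of [GeneSimilarityMatrix-class], one per
#'   source.
#' @param genes gene universe to score.
#' @return A list with one `c(lo, hi)` per source, plus the raw score
#'   matrices in attribute `"raw"` (diseases x genes per source).
#' @export
associationScoreBounds <- function(seedSets, matrices, genes) {
    rawAll <- lapply(matrices, function(M) {
        m <- vapply(seedSets, function(ss) .associationScores(genes, ss, M),
                    numeric(length(genes)))
        t(m)                                  # diseases x genes
    })
    bounds <- lapply(rawAll, function(m) {
        lo <- min(m); hi <- max(m)
        if (hi <= lo) hi <- lo + 1            # uninformative source: all -> 0
        c(lo = lo, hi = hi)
    })
    attr(bounds, "raw") <- rawAll
    bounds
}

#' Assemble the 19-dimensional feature vector(s) for disease-variant pairs
#'
#' For each (disease, variant) pair: the 11 normalized variant
#' deleteriousness scores of the variant, followed by the 8 normalized
#' association scores of the variant's host gene for the disease, in the
#' canonical order of [featureNames()].  Scores or sources that are missing
#' contribute exactly 0.  Variants in the same gene always share their 8
#' association coordinates for a given disease.
#'
#' @param pairs data.frame with columns `disease` and the variant key
#'   columns `chrom, pos, ref, alt, gene`.
#' @param scoreTable data.frame keyed by chrom, pos, ref, alt with the 11
#'   raw score columns.
#' @param seedSets named list of [SeedGeneSet-class] per disease (already
#'   leakage-filtered where required).
#' @param matrices named list of [GeneSimilarityMatrix-class] per source.
#' @param bounds variant-score bounds from [computeScoreBounds()].
#' @param assocBounds per-source association bounds from
#'   [associationScoreBounds()].
#' @return Numeric matrix, one row per pair, 19 named columns in \[0, 1\].
#' @export
assembleFeatureMatrix <- function(pairs, scoreTable, seedSets, matrices,
                                  bounds, assocBounds) {
    if (any(is.na(pairs$gene) | pairs$gene == ""))
        stop("assembleFeatureMatrix: every variant needs a host gene")
    key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt, sep = ":")
    idx <- match(key(pairs), key(scoreTable))
    feat <- matrix(0, nrow(pairs), length(featureNames()),
                   dimnames = list(NULL, featureNames()))
    for (nm in variantScoreNames()) {
        raw <- rep(NA_real_, nrow(pairs))
        hit <- !is.na(idx)
        raw[hit] <- scoreTable[[nm]][idx[hit]]
        feat[, nm] <- normalizeVariantScore(nm, raw, bounds)
    }
    for (src in names(matrices)) {
        b <- assocBounds[[src]]
        rawScores <- numeric(nrow(pairs))
        for (d in unique(pairs$disease)) {
            sel <- pairs$disease == d
            ss <- seedSets[[d]]
            if (is.null(ss)) next                 # unknown disease -> 0
            rawScores[sel] <- .associationScores(pairs$gene[sel], ss,
                                                 matrices[[src]])
        }
        feat[, src] <- normalizeAssociationScore(rawScores, b["lo"], b["hi"])
    }
    feat
}
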