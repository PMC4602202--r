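## Rank-based evaluation metrics: rank ratio, mean rank ratio (MRR),
## per-disease rank-ROC AUC, false positive rate at score thresholds,
## random-guess baselines and hypergeometric top-k enrichment.

#' Rank of a positive variant against a set of negatives
#'
#' The rank of a positive prediction score within the list formed by the
#' positive and all negatives, with ties resolved by average rank:
#' `1 + #\{negatives strictly greater\} + #\{ties\}/2`.
#'
#' @param posScore prediction score of the positive variant.
#' @param negScores numeric vector of negative scores (may be empty).
#' @return The (possibly fractional) rank, between 1 and
#'   `length(negScores) + 1`.
#' @export
rankOfPositive <- function(posScore, negScores) {
    1 + sum(negScores > posScore) + sum(negScores == posScore) / 2
}

#' Rank ratio
#'
#' A variant's rank divided by the total number of candidates in its list.
#' When one positive is ranked against n negatives the total is n + 1.
#'
#' @param rank rank in \[1, total\] (fractional allowed for ties).
#' @param total list length.
#' @return Value in (0, 1\].
#' @export
rankRatio <- function(rank, total) {
    if (any(rank < 1 - 1e-9) || any(rank > total + 1e-9))
        stop("rankRatio: rank must lie in [1, total]")
    rank / total
}

#' Mean rank ratio (MRR)
#'
#' Two-stage unweighted mean: rank ratios are averaged within each disease,
#' and the per-disease means are averaged across diseases.  Lower is
#' better; a random guess yields 0.5 in expectation.
#'
#' @param perDisease named list of numeric rank-ratio vectors, one per
#'   disease.
#' @return The MRR, in (0, 1\].
#' @export
meanRankRatio <- function(perDisease) {
    if (!length(perDisease) || any(!lengths(perDisease)))
        stop("meanRankRatio: every disease needs at least one rank ratio")
    mean(vapply(perDisease, mean, numeric(1)))
}

#' Rank-ROC area under the curve for one disease
#'
#' Traces an ROC curve over rank-ratio thresholds: at threshold t the
#' sensitivity is the fraction of positive rank ratios <= t and the
#' specificity the fraction of negative rank ratios > t.  Thresholds are
#' the distinct observed rank-ratio values together with the endpoints 0
#' and 1; the area is computed by trapezoidal integration.  The result
#' equals the Mann-Whitney statistic
#' `P(pos < neg) + P(pos == neg)/2`.
#'
#' @param posRatios rank ratios of the positive test variants.
#' @param negRatios rank ratios of the negative test variants.
#' @return AUC in \[0, 1\].
#' @export
rankRocAuc <- function(posRatios, negRatios) {
    if (!length(posRatios) || !length(negRatios))
        stop("rankRocAuc: both positive and negative ratios are required")
    th <- sort(unique(c(0, posRatios, negRatios, 1)))
    sens <- vapply(th, function(t) mean(posRatios <= t), numeric(1))
    fpr <- vapply(th, function(t) mean(negRatios <= t), numeric(1))
    ## trapezoid over (FPR, sensitivity), monotone in the threshold
    sum(diff(fpr) * (utils::head(sens, -1) + utils::tail(sens, -1)) / 2)
}

#' Mean AUC over diseases
#'
#' Unweighted mean of the per-disease rank-ROC AUC values.
#'
#' @param aucs numeric vector (or list) of per-disease AUCs.
#' @return Mean AUC in \[0, 1\].
#' @export
meanAuc <- function(aucs) {
    aucs <- unlist(aucs)
    if (!length(aucs)) stop("meanAuc: empty input")
    mean(aucs)
}

#' Overall false positive rate at a score threshold
#'
#' Per disease, the proportion of neutral variants whose prediction score
#' is greater than or equal to the threshold; the overall FPR is the
#' unweighted mean of the per-disease proportions.
#'
#' @param neutralScores named list of numeric score vectors, one per
#'   disease.
#' @param threshold score threshold in \[0, 1\].
#' @return Overall FPR in \[0, 1\].
#' @export
falsePositiveRate <- function(neutralScores, threshold) {
    if (threshold < 0 || threshold > 1)
        stop("falsePositiveRate: threshold must lie in [0, 1]")
    mean(vapply(neutralScores, function(s) mean(s >= threshold),
                numeric(1)))
}

#' Expected top-k count under random guessing
#'
#' When each of `nPos` positives is independently ranked uniformly among
#' `nNeg + 1` positions, the expected number of positives landing in the
#' top k is `nPos * min(k, nNeg + 1) / (nNeg + 1)`.
#'
#' @param nPos number of positive variants ranked.
#' @param nNeg number of negatives in each list.
#' @param k top-list size.
#' @return Expected count.
#' @export
randomGuessExpectedTopk <- function(nPos, nNeg, k) {
    if (k < 1 || nNeg < 0) stop("randomGuessExpectedTopk: invalid input")
    nPos * min(k, nNeg + 1) / (nNeg + 1)
}

#' One-sided hypergeometric enrichment of a top-k list
#'
#' Probability of observing `x` or more functional variants among the top
#' `n` of a ranked list of `N` candidates containing `K` functional ones,
#' i.e. the upper tail of the hypergeometric distribution — the one-sided
#' Fisher exact test for top-list enrichment.  Computed through the
#' log-space hypergeometric CDF, never via raw factorials.
#'
#' @param N total candidates.
#' @param K functional candidates among them.
#' @param n top-list size.
#' @param x functional candidates observed in the top list.
#' @return Tail probability `P(X >= x)` in \[0, 1\].
#' @export
hypergeomTopkEnrichment <- function(N, K, n, x) {
    if (any(c(N, K, n, x) != round(c(N, K, n, x))))
        stop("hypergeomTopkEnrichment: all inputs must be integers")
    if (x < 0 || K > N || n > N || x > min(K, n))
        stop("hypergeomTopkEnrichment: need 0 <= x <= min(K, n) <= N")
    if (x == 0) return(1)
    stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
}
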