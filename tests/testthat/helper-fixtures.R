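# Shared fixtures, all generated in code.

# 3-record disease-term corpus with hand-checkable TF-IDF values
toyCorpus <- function() {
    rbind(d1 = c(a = 2, b = 1, c = 0),
          d2 = c(a = 1, b = 0, c = 1),
          d3 = c(a = 0, b = 0, c = 3))
}

# path graph g1 - g2 - g3 plus isolated pair g4 - g5
toyNetwork <- function() {
    data.frame(a = c("g1", "g2", "g4"), b = c("g2", "g3", "g5"))
}

# small universe for structural / IO tests
smallConfig <- function(seed = 7, signal = 0.8) {
    universeConfig(n_genes = 60, n_diseases = 8, n_tissues = 10,
                   n_terms = 48, n_pathways = 12, n_domains = 12,
                   n_factors = 16, n_mirnas = 10,
                   n_causative_variants = 40, n_neutral_variants = 80,
                   n_clusters = 4, pool_size = 10, module_size = 3,
                   signal_strength = signal, seed = seed)
}

# linearly separable feature matrix: positives high on 3 informative dims
separableFeatures <- function(n, seed) {
    set.seed(seed)
    half <- n / 2
    feat <- matrix(runif(n * 19), n, 19,
                   dimnames = list(NULL, featureNames()))
    feat[seq_len(half), 1:3] <- runif(half * 3, 0.7, 1)     # positives
    feat[seq(half + 1, n), 1:3] <- runif(half * 3, 0, 0.3)  # negatives
    list(features = feat,
         labels = rep(c("positive", "negative"), each = half))
}

# independent Floyd-Warshall all-pairs distances (oracle for BFS)
floydWarshall <- function(nodes, edges) {
    n <- length(nodes)
    d <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
    diag(d) <- 0
    for (i in seq_len(nrow(edges))) {
        a <- edges[i, 1]; b <- edges[i, 2]
        d[a, b] <- d[b, a] <- 1
    }
    for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
    d
}

# brute-force Mann-Whitney AUC: P(pos < neg) + P(tie)/2 over all pairs
pairwiseAuc <- function(pos, neg) {
    tot <- 0
    for (p in pos) for (q in neg)
        tot <- tot + (p < q) + 0.5 * (p == q)
    tot / (length(pos) * length(neg))
}

# exhaustive hypergeometric tail by enumerating all draws of size n
enumTail <- function(N, K, n, x) {
    draws <- utils::combn(N, n)
    hits <- colSums(draws <= K)   # items 1..K are the "functional" ones
    mean(hits >= x)
}
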