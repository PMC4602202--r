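## Synthetic study universe with a planted disease -> gene -> variant
## causal signal.
##
## Structure: diseases come in phenotype clusters that share standardized
## terms; each cluster owns a gene pool, each disease a gene module drawn
## from its cluster's pool.  Module/pool genes are made coherent across the
## eight genomic sources in proportion to signal_strength; causative
## variants lie in module genes and draw deleteriousness scores from a
## damaging mode, again in proportion to signal_strength.  At
## signal_strength = 0 pools leave no trace in any source and causative
## scores are distributed exactly like neutral ones.

#' Configuration for a synthetic universe
#'
#' Defaults define the package's reference benchmark conditions: 300 genes,
#' 40 diseases in 8 phenotype clusters, 400 causative and 800 neutral
#' variants, planted signal strength 0.8, 20% of score values masked
#' missing.
#'
#' @param n_genes,n_diseases,n_tissues,n_terms,n_pathways,n_domains,n_factors,n_mirnas
#'   entity counts.
#' @param n_causative_variants,n_neutral_variants variant counts;
#'   causative variants are split evenly across diseases.
#' @param n_clusters number of phenotype clusters (diseases per cluster =
#'   `n_diseases / n_clusters`).
#' @param pool_size genes per cluster gene pool.
#' @param module_size genes in each disease's truth module.
#' @param signal_strength planted signal in \[0, 1\]; 0 = pure null.
#' @param missing_rate fraction of score values masked missing.
#' @param seed integer RNG seed; fixed seed gives an identical universe.
#' @return A named list (the config).
#' @export
universeConfig <- function(n_genes = 300, n_diseases = 40, n_tissues = 40,
                           n_terms = 120, n_pathways = 40, n_domains = 50,
                           n_factors = 30, n_mirnas = 40,
                           n_causative_variants = 400,
                           n_neutral_variants = 800, n_clusters = 8,
                           pool_size = 30, module_size = 5,
                           signal_strength = 0.8, missing_rate = 0.2,
                           seed = 1L) {
    cfg <- as.list(environment())
    if (cfg$n_clusters * cfg$pool_size > cfg$n_genes)
        stop("universeConfig: cluster gene pools exceed the gene universe")
    if (cfg$module_size > cfg$pool_size)
        stop("universeConfig: module larger than its gene pool")
    if (cfg$n_diseases %% cfg$n_clusters != 0)
        stop("universeConfig: n_diseases must be divisible by n_clusters")
    if (cfg$n_causative_variants %% cfg$n_diseases != 0)
        stop("universeConfig: causative variants must split evenly over diseases")
    if (cfg$signal_strength < 0 || cfg$signal_strength > 1)
        stop("universeConfig: signal_strength must lie in [0, 1]")
    cfg
}

## Native scales and orientation of the 11 deleteriousness scores.
## flip = TRUE means smaller raw value = more deleterious (SIFT, LRT).
.scoreMeta <- function() {
    data.frame(
        score = variantScoreNames(),
        lo   = c(0, 0, 0, 0, -5, 0, -12, -14, 0,  0, 0),
        hi   = c(1, 1, 1, 1,  5, 1,   6,  10, 30, 40, 1),
        flip = c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE,
                 FALSE, FALSE, FALSE))
}

.randAlleles <- function(n) {
    ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    alt <- vapply(ref, function(r)
        sample(setdiff(c("A", "C", "G", "T"), r), 1), character(1))
    cbind(ref, alt)
}

#' Generate a synthetic universe
#'
#' Deterministic for a fixed seed.  See [universeConfig()] for the knobs
#' and the class docs ([SyntheticUniverse-class]) for the slots.
#'
#' Causative variants draw each deleteriousness score from a damaging-mode
#' Beta(5, 2) (on the unit scale, mapped to the score's native range and
#' orientation) with probability `signal_strength`, otherwise from the
#' benign-mode Beta(2, 5) that neutral variants always use.  Source
#' coherence (expression co-clustering, shared memberships, network
#' proximity of pool genes) scales linearly with `signal_strength` and
#' vanishes at 0.
#'
#' @param cfg a [universeConfig()].
#' @return A [SyntheticUniverse-class].
#' @export
generateUniverse <- function(cfg = universeConfig()) {
    rng <- .seededRNG(cfg$seed)
    on.exit(.restoreRNG(rng))
    s <- cfg$signal_strength

    genes <- sprintf("G%03d", seq_len(cfg$n_genes))
    diseases <- sprintf("D%02d", seq_len(cfg$n_diseases))
    perClust <- cfg$n_diseases / cfg$n_clusters
    pools <- split(genes[seq_len(cfg$n_clusters * cfg$pool_size)],
                   rep(seq_len(cfg$n_clusters), each = cfg$pool_size))
    clusterOf <- rep(seq_len(cfg$n_clusters), each = perClust)

    ## disease modules and truth associations
    modules <- lapply(seq_along(diseases), function(i)
        sort(sample(pools[[clusterOf[i]]], cfg$module_size)))
    names(modules) <- diseases
    associations <- data.frame(
        disease = rep(diseases, lengths(modules)),
        gene = unlist(modules), row.names = NULL)

    ## variants: causative in module genes, neutral anywhere
    perDisease <- cfg$n_causative_variants / cfg$n_diseases
    causGene <- unlist(lapply(diseases, function(d)
        sample(modules[[d]], perDisease, replace = TRUE)))
    neutGene <- sample(genes, cfg$n_neutral_variants, replace = TRUE)
    allGene <- c(causGene, neutGene)
    geneIdx <- match(allGene, genes)
    chrom <- paste0("chr", (geneIdx - 1) %% 22 + 1)
    ## unique position: per-gene offset within the gene's 10kb window
    off <- stats::ave(seq_along(allGene), allGene, FUN = seq_along)
    pos <- geneIdx * 10000L + off * 3L
    al <- .randAlleles(length(allGene))
    variants <- data.frame(
        chrom = chrom, pos = as.integer(pos), ref = al[, "ref"],
        alt = al[, "alt"], gene = allGene,
        class = rep(c("causative", "neutral"),
                    c(length(causGene), length(neutGene))),
        disease = c(rep(diseases, each = perDisease),
                    rep(NA_character_, length(neutGene))),
        row.names = NULL)

    ## deleteriousness scores: damaging vs benign mode
    meta <- .scoreMeta()
    damaging <- variants$class == "causative" &
        stats::runif(nrow(variants)) < s
    scores <- variants[, c("chrom", "pos", "ref", "alt", "gene")]
    for (i in seq_len(nrow(meta))) {
        u <- ifelse(damaging, stats::rbeta(nrow(variants), 5, 2),
                    stats::rbeta(nrow(variants), 2, 5))
        if (meta$flip[i]) u <- 1 - u
        val <- meta$lo[i] + u * (meta$hi[i] - meta$lo[i])
        val[stats::runif(nrow(variants)) < cfg$missing_rate] <- NA
        scores[[meta$score[i]]] <- val
    }

    ## --- genomic sources -------------------------------------------------
    poolOf <- stats::setNames(rep(NA_integer_, length(genes)), genes)
    for (p in seq_along(pools)) poolOf[pools[[p]]] <- p

    ## expression: pool archetype + iid noise, mixed by sqrt(signal)
    arch <- matrix(stats::rnorm(cfg$n_clusters * cfg$n_tissues),
                   cfg$n_clusters)
    noise <- matrix(stats::rnorm(cfg$n_genes * cfg$n_tissues), cfg$n_genes)
    expr <- sqrt(1 - s) * noise
    inPool <- !is.na(poolOf)
    expr[inPool, ] <- expr[inPool, ] + sqrt(s) * arch[poolOf[inPool], ]
    dimnames(expr) <- list(genes, paste0("tissue", seq_len(cfg$n_tissues)))

    ## GO annotations: pool-specific terms at rate .8*s + random background
    nGo <- 10 * cfg$n_clusters + 20
    goTerms <- sprintf("GO%04d", seq_len(nGo))
    ann <- list()
    for (g in genes) {
        t1 <- character()
        if (!is.na(poolOf[g])) {
            poolTerms <- goTerms[(poolOf[g] - 1) * 10 + seq_len(10)]
            t1 <- poolTerms[stats::runif(10) < 0.8 * s]
        }
        t2 <- sample(goTerms, 2)
        ann[[g]] <- unique(c(t1, t2))
    }
    goAnn <- data.frame(gene = rep(genes, lengths(ann)),
                        term = unlist(ann), row.names = NULL)

    ## membership sources: per pool a few sets holding pool genes at rate
    ## .75*s, plus random background sets
    mkSets <- function(nSets, prefix, perPoolSets, bgSize) {
        sets <- list()
        k <- 1
        for (p in seq_len(cfg$n_clusters)) {
            for (j in seq_len(perPoolSets)) {
                memb <- pools[[p]][stats::runif(cfg$pool_size) < 0.75 * s]
                sets[[sprintf("%s%03d", prefix, k)]] <- memb
                k <- k + 1
            }
        }
        while (k <= nSets) {
            sets[[sprintf("%s%03d", prefix, k)]] <- sample(genes, bgSize)
            k <- k + 1
        }
        sets[lengths(sets) > 0]
    }
    kegg <- mkSets(cfg$n_pathways, "path", 2, 8)
    pfam <- mkSets(cfg$n_domains, "dom", 3, 5)
    mirna <- mkSets(cfg$n_mirnas, "mir", 2, 10)

    ## TSFC: Poisson counts, pool genes elevated on pool factors
    tsfc <- matrix(stats::rpois(cfg$n_genes * cfg$n_factors, 1),
                   cfg$n_genes,
                   dimnames = list(genes,
                                   paste0("TF", seq_len(cfg$n_factors))))
    fPerPool <- max(1, cfg$n_factors %/% (2 * cfg$n_clusters))
    for (p in seq_len(cfg$n_clusters)) {
        fac <- ((p - 1) * fPerPool) %% cfg$n_factors + seq_len(fPerPool)
        tsfc[pools[[p]], fac] <- tsfc[pools[[p]], fac] +
            stats::rpois(length(pools[[p]]) * fPerPool, 6 * s)
    }

    ## networks: within-pool edges at base + .25*s (PPI) / .2*s (Seq)
    mkNet <- function(pIn, pOut) {
        pairs <- t(utils::combn(genes, 2))
        p1 <- poolOf[pairs[, 1]]; p2 <- poolOf[pairs[, 2]]
        same <- !is.na(p1) & !is.na(p2) & p1 == p2
        keep <- stats::runif(nrow(pairs)) < ifelse(same, pIn, pOut)
        data.frame(a = pairs[keep, 1], b = pairs[keep, 2],
                   row.names = NULL)
    }
    ppi <- mkNet(0.02 + 0.25 * s, 0.02)
    seqNet <- mkNet(0.015 + 0.20 * s, 0.015)

    ## phenotype term counts: cluster signature + background
    sigPerClust <- cfg$n_terms %/% (2 * cfg$n_clusters)
    terms <- sprintf("T%04d", seq_len(cfg$n_terms))
    tc <- matrix(0L, cfg$n_diseases, cfg$n_terms,
                 dimnames = list(diseases, terms))
    for (i in seq_along(diseases)) {
        sig <- (clusterOf[i] - 1) * sigPerClust + seq_len(sigPerClust)
        tc[i, sig] <- stats::rpois(sigPerClust, 6)
        bg <- sample(cfg$n_terms, 10)
        tc[i, bg] <- tc[i, bg] + stats::rpois(10, 2L)
        if (sum(tc[i, ]) == 0) tc[i, sample(sig, 1)] <- 1L
    }

    new("SyntheticUniverse", config = cfg, genes = genes,
        diseases = diseases, associations = associations,
        variants = variants, scores = scores,
        sources = list(Exp = expr, GO = goAnn, KEGG = kegg, Seq = seqNet,
                       Pfam = pfam, PPI = ppi, TSFC = tsfc, miRNA = mirna),
        termCounts = tc)
}

#' Build all eight gene similarity matrices of a universe
#'
#' Convenience wrapper running [buildSimilarityMatrix()] on every raw
#' source table over the universe's full gene list.
#'
#' @param universe a [SyntheticUniverse-class].
#' @return Named list of [GeneSimilarityMatrix-class], one per source.
#' @export
universeSimilarityMatrices <- function(universe) {
    src <- universe@sources
    out <- lapply(geneSourceNames(), function(nm)
        buildSimilarityMatrix(nm, src[[nm]], genes = universe@genes))
    names(out) <- geneSourceNames()
    out
}
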