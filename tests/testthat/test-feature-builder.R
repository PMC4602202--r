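mkSim <- function(m, source = "PPI", sigma = 0.3) {
    new("GeneSimilarityMatrix", source = source, sigma = sigma, sim = m,
        covered = rownames(m))
}

test_that("association score sums similarities over seed genes", {
    m <- matrix(c(1, .3, .5, .3, 1, .2, .5, .2, 1), 3,
                dimnames = rep(list(c("g", "a", "b")), 2))
    M <- mkSim(m)
    expect_equal(associationScore("g", character(), M), 0)
    expect_equal(associationScore("g", c("a", "b"), M), 0.8)
    expect_equal(associationScore("zz", c("a", "b"), M), 0)  # unknown gene
    # adding a seed never decreases the score
    expect_gte(associationScore("g", c("a", "b"), M),
               associationScore("g", "a", M))
    # the gene itself as a seed contributes its self-similarity
    expect_equal(associationScore("g", c("g", "a"), M), 1.3)
})

test_that("variant score normalization flips SIFT/LRT, min-max scales, clips, zeroes NA", {
    tab <- data.frame(SIFT = c(0, 0.5, 1), CADD = c(0, 20, 40),
                      GERP = c(-12, 0, 6))
    b <- computeScoreBounds(tab, c("SIFT", "CADD", "GERP"))
    # SIFT bounds live on the flipped scale
    expect_equal(b$min[b$score == "SIFT"], 0)
    expect_equal(b$max[b$score == "SIFT"], 1)
    expect_equal(normalizeVariantScore("SIFT", 0, b), 1)   # most deleterious
    expect_equal(normalizeVariantScore("SIFT", 1, b), 0)
    expect_equal(normalizeVariantScore("CADD", 40, b), 1)  # database maximum
    expect_equal(normalizeVariantScore("CADD", 20, b), 0.5)
    expect_equal(normalizeVariantScore("GERP", -12, b), 0)
    expect_equal(normalizeVariantScore("CADD", NA, b), 0)  # missing -> 0
    expect_equal(normalizeVariantScore("CADD", 99, b), 1)  # clipped
    degen <- data.frame(score = "CADD", min = 3, max = 3)
    expect_error(normalizeVariantScore("CADD", 1, degen), "degenerate")
    expect_error(normalizeVariantScore("Phylop", 1, b), "no bounds")
})

test_that("association score normalization is plain min-max with clipping", {
    expect_equal(normalizeAssociationScore(5, 0, 10), 0.5)
    expect_equal(normalizeAssociationScore(10, 0, 10), 1)
    expect_equal(normalizeAssociationScore(-2, 0, 10), 0)
    expect_equal(normalizeAssociationScore(NA, 0, 10), 0)
    expect_error(normalizeAssociationScore(1, 2, 2), "degenerate")
})

test_that("feature vectors are length 19 in [0,1]; association block depends only on the gene", {
    u <- generateUniverse(smallConfig())
    mats <- universeSimilarityMatrices(u)
    phen <- phenotypeSimilarity(u@termCounts)
    seedSets <- lapply(u@diseases, function(d)
        collectSeedGenes(d, topSimilarDiseases(d, phen, 3),
                         u@associations))
    names(seedSets) <- u@diseases
    bounds <- computeScoreBounds(u@scores)
    ab <- associationScoreBounds(seedSets, mats, u@genes)

    v <- u@variants
    g <- v$gene[1]
    sameGene <- v[v$gene == g, ][1:min(2, sum(v$gene == g)), ]
    pairs <- data.frame(disease = u@diseases[1],
                        sameGene[, c("chrom", "pos", "ref", "alt", "gene")])
    feat <- assembleFeatureMatrix(pairs, u@scores, seedSets, mats, bounds, ab)
    expect_identical(colnames(feat), featureNames())
    expect_true(all(feat >= 0 & feat <= 1))
    if (nrow(feat) == 2)    # same gene, same disease -> same last 8 coords
        expect_equal(feat[1, geneSourceNames()], feat[2, geneSourceNames()])

    # a variant absent from the score table with empty seeds -> zero vector
    ghost <- data.frame(disease = u@diseases[1], chrom = "chrX",
                        pos = 1L, ref = "A", alt = "C", gene = "nope")
    emptySeeds <- lapply(seedSets, function(s)
        new("SeedGeneSet", query = s@query, seeds = character(),
            provenance = list()))
    zero <- assembleFeatureMatrix(ghost, u@scores, emptySeeds, mats,
                                  bounds, ab)
    expect_equal(unname(zero[1, ]), rep(0, 19))
    # missing host gene is an input error
    bad <- ghost; bad$gene <- NA
    expect_error(assembleFeatureMatrix(bad, u@scores, seedSets, mats,
                                       bounds, ab), "host gene")
})

test_that("assembled features match the composition of the scalar operations", {
    genes <- c("g1", "g2", "g3")
    m <- matrix(c(1, .4, .1, .4, 1, .6, .1, .6, 1), 3,
                dimnames = list(genes, genes))
    mats <- list(PPI = mkSim(m))
    seedSets <- list(q = new("SeedGeneSet", query = "q",
                             seeds = c("g2", "g3"),
                             provenance = list(g2 = "q", g3 = "q")))
    scoreTab <- data.frame(chrom = "chr1", pos = 100L, ref = "A",
                           alt = "G", gene = "g1", SIFT = 0.2,
                           PolyPhen2 = 0.9, LRT = NA, MutationTaster = 0.5,
                           MutationAccessor = 2, MSRV = 0.5, GERP = 3,
                           Phylop = 1, SiPhy = 10, CADD = 25, SInBaD = 0.4)
    ref <- data.frame(SIFT = c(0, 1), PolyPhen2 = c(0, 1), LRT = c(0, 1),
                      MutationTaster = c(0, 1),
                      MutationAccessor = c(-5, 5), MSRV = c(0, 1),
                      GERP = c(-12, 6), Phylop = c(-14, 10),
                      SiPhy = c(0, 30), CADD = c(0, 40), SInBaD = c(0, 1))
    bounds <- computeScoreBounds(ref)
    ab <- list(PPI = c(lo = 0, hi = 2))
    pairs <- data.frame(disease = "q", chrom = "chr1", pos = 100L,
                        ref = "A", alt = "G", gene = "g1")
    feat <- assembleFeatureMatrix(pairs, scoreTab, seedSets, mats,
                                  bounds, ab)[1, ]
    expect_equal(feat[["SIFT"]], 1 - 0.2)            # flip, identity bounds
    expect_equal(feat[["LRT"]], 0)                   # missing
    expect_equal(feat[["CADD"]], 25 / 40)
    expect_equal(feat[["GERP"]], (3 + 12) / 18)
    expect_equal(feat[["MutationAccessor"]], (2 + 5) / 10)
    # association: sum of similarities to seeds, min-max by [0, 2]
    expect_equal(feat[["PPI"]], (0.4 + 0.1) / 2)
})
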