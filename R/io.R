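## Readers and writers for the plain-text formats shared across modules.
## All tabular files are tab-separated, '#'-commented, with header rows;
## empty cells are missing values.  Windows line endings are accepted.

.readTsv <- function(path, ...) {
    utils::read.delim(path, sep = "\t", comment.char = "#",
                      stringsAsFactors = FALSE, check.names = FALSE, ...)
}

.writeTsv <- function(df, path, rowNames = FALSE) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = rowNames, col.names = TRUE)
}

.fmtNum <- function(x) {
    if (is.double(x)) ifelse(is.na(x), "", sprintf("%.15g", x))
    else ifelse(is.na(x), "", as.character(x))
}

#' Read candidate SNVs from a VCF file
#'
#' Parses a VCF (v4.x), keeping biallelic single-nucleotide records and
#' splitting multi-allelic records into one record per alternate allele.
#' Non-SNV alleles (indels, symbolic) are skipped and counted in a
#' message, as are records lacking the gene annotation tag.
#'
#' @param path VCF file path (plain text).
#' @param geneTag INFO key carrying the host gene id (default `"GENE"`).
#' @return data.frame(chrom, pos, ref, alt, gene), one row per SNV.
#' @export
readVcfCandidates <- function(path, geneTag = "GENE") {
    if (!requireNamespace("vcfR", quietly = TRUE))
        stop("readVcfCandidates requires the vcfR package")
    vcf <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
    fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
    if (!nrow(fix)) return(data.frame(chrom = character(),
                                      pos = integer(), ref = character(),
                                      alt = character(), gene = character()))
    gene <- vcfR::extract.info(vcf, element = geneTag)
    rows <- list()
    skippedNonSnv <- 0L; skippedNoGene <- 0L
    for (i in seq_len(nrow(fix))) {
        ref <- fix$REF[i]
        alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
        for (alt in alts) {
            if (nchar(ref) != 1 || nchar(alt) != 1 ||
                !alt %in% c("A", "C", "G", "T")) {
                skippedNonSnv <- skippedNonSnv + 1L
                next
            }
            if (is.na(gene[i]) || gene[i] == "") {
                skippedNoGene <- skippedNoGene + 1L
                next
            }
            rows[[length(rows) + 1L]] <- data.frame(
                chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
                ref = ref, alt = alt, gene = gene[i])
        }
    }
    if (skippedNonSnv)
        message("readVcfCandidates: skipped ", skippedNonSnv,
                " non-SNV allele(s)")
    if (skippedNoGene)
        message("readVcfCandidates: rejected ", skippedNoGene,
                " allele(s) lacking the '", geneTag, "' tag")
    out <- do.call(rbind, rows)
    if (is.null(out)) out <- data.frame(chrom = character(),
                                        pos = integer(), ref = character(),
                                        alt = character(), gene = character())
    rownames(out) <- NULL
    out
}

#' Write variants as a minimal VCF
#'
#' Records are sorted by chromosome (natural order) and position; the host
#' gene goes into the INFO field under `geneTag`.
#'
#' @param variants data.frame(chrom, pos, ref, alt, gene).
#' @param path output path.
#' @param geneTag INFO key for the gene id.
#' @export
writeVcf <- function(variants, path, geneTag = "GENE") {
    chromNum <- suppressWarnings(as.numeric(sub("^chr", "", variants$chrom)))
    ord <- order(chromNum, variants$chrom, variants$pos)
    v <- variants[ord, , drop = FALSE]
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("##fileformat=VCFv4.2",
                 sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"Host gene\">",
                         geneTag),
                 "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t%s=%s", v$chrom, v$pos,
                       v$ref, v$alt, geneTag, v$gene), con)
    invisible(path)
}

#' Read a per-variant functional score table
#'
#' TSV with key columns chrom, pos, ref, alt, gene followed by the 11
#' score columns; empty cells are missing.  Duplicate variant keys are an
#' error.
#'
#' @param path file path.
#' @return data.frame with NA for missing scores.
#' @export
readScoreTable <- function(path) {
    df <- .readTsv(path)
    need <- c("chrom", "pos", "ref", "alt", "gene")
    if (!all(need %in% names(df)))
        stop("readScoreTable: missing key columns in ", path)
    key <- paste(df$chrom, df$pos, df$ref, df$alt)
    if (anyDuplicated(key))
        stop("readScoreTable: duplicate variant key at line ",
             which(duplicated(key))[1] + 1L, " of ", path)
    for (nm in setdiff(names(df), need))
        df[[nm]] <- suppressWarnings(as.numeric(df[[nm]]))
    df
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then tab-separated member ids.
#'
#' @param path file path.
#' @return Named list of character vectors.
#' @export
readGmt <- function(path) {
    lines <- readLines(path)
    lines <- sub("\r$", "", lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    sets <- list()
    for (i in seq_along(lines)) {
        parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
        if (length(parts) < 3)
            stop("readGmt: line ", i, " of ", path,
                 " has fewer than 3 fields")
        sets[[parts[1]]] <- parts[-(1:2)]
    }
    sets
}

#' Write gene sets in GMT format
#' @param sets named list of character vectors.
#' @param path output path.
#' @export
writeGmt <- function(sets, path) {
    writeLines(vapply(names(sets), function(nm)
        paste(c(nm, "na", sets[[nm]]), collapse = "\t"), character(1)),
        path)
    invisible(path)
}

#' Read an undirected edge list
#'
#' Two-column TSV of node ids; '#' comments allowed.
#'
#' @param path file path.
#' @return data.frame(a, b).
#' @export
readEdgeList <- function(path) {
    df <- .readTsv(path)
    if (ncol(df) < 2)
        stop("readEdgeList: ", path, " needs two columns")
    names(df)[1:2] <- c("a", "b")
    df[, 1:2]
}

#' Read a numeric matrix from TSV
#'
#' First column holds row ids, the header row column ids.
#'
#' @param path file path.
#' @param integer coerce to integer (for count matrices).
#' @return Numeric matrix with dimnames.
#' @export
readMatrixTsv <- function(path, integer = FALSE) {
    df <- .readTsv(path)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    storage.mode(m) <- if (integer) "integer" else "double"
    m
}

#' Write a numeric matrix as TSV
#' @param m matrix with dimnames.
#' @param path output path.
#' @param idColumn header name of the row-id column.
#' @export
writeMatrixTsv <- function(m, path, idColumn = "id") {
    df <- data.frame(rownames(m),
                     as.data.frame(apply(m, 2, .fmtNum)),
                     check.names = FALSE)
    names(df)[1] <- idColumn
    .writeTsv(df, path)
}

#' Write a gene similarity matrix with its metadata sidecar
#'
#' The matrix goes to `path` as TSV (gene ids in the header row and first
#' column); source tag, sigma and coverage go to `<path>.meta.json`.
#'
#' @param M a [GeneSimilarityMatrix-class].
#' @param path output TSV path.
#' @export
writeSimilarityMatrix <- function(M, path) {
    writeMatrixTsv(as.matrix(M), path, idColumn = "gene")
    jsonlite::write_json(
        list(source = simSource(M), sigma = simSigma(M),
             covered = coveredGenes(M)),
        paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' Read a gene similarity matrix written by [writeSimilarityMatrix()]
#' @param path TSV path (sidecar `<path>.meta.json` must exist).
#' @return A [GeneSimilarityMatrix-class].
#' @export
readSimilarityMatrix <- function(path) {
    m <- readMatrixTsv(path)
    colnames(m) <- rownames(m)
    meta <- jsonlite::read_json(paste0(path, ".meta.json"),
                                simplifyVector = TRUE)
    new("GeneSimilarityMatrix", source = meta$source, sigma = meta$sigma,
        sim = (m + t(m)) / 2, covered = meta$covered)
}

#' Serialize a synthetic universe to a directory of plain-text files
#'
#' Writes the formats every other module reads: a VCF of all variants
#' (with the truth class/disease in a companion TSV), the score table,
#' expression and binding-site matrices, GMT gene sets, annotation and
#' edge-list TSVs, the disease term-count matrix, truth associations, and
#' the generating config as JSON.  [readUniverse()] round-trips them.
#'
#' @param universe a [SyntheticUniverse-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeUniverse <- function(universe, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    fp <- function(nm) file.path(dir, nm)
    writeVcf(universe@variants, fp("variants.vcf"))
    .writeTsv(universe@variants, fp("variant_truth.tsv"))
    sc <- universe@scores
    for (nm in variantScoreNames()) sc[[nm]] <- .fmtNum(sc[[nm]])
    .writeTsv(sc, fp("scores.tsv"))
    writeMatrixTsv(universe@sources$Exp, fp("expression.tsv"), "gene")
    .writeTsv(universe@sources$GO, fp("go_annotations.tsv"))
    writeGmt(universe@sources$KEGG, fp("kegg.gmt"))
    writeGmt(universe@sources$Pfam, fp("pfam.gmt"))
    writeGmt(universe@sources$miRNA, fp("mirna.gmt"))
    .writeTsv(universe@sources$PPI, fp("ppi_edges.tsv"))
    .writeTsv(universe@sources$Seq, fp("seq_edges.tsv"))
    writeMatrixTsv(universe@sources$TSFC, fp("tsfc.tsv"), "gene")
    writeMatrixTsv(universe@termCounts, fp("term_counts.tsv"), "disease")
    .writeTsv(universe@associations, fp("associations.tsv"))
    jsonlite::write_json(universe@config, fp("config.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(dir)
}

#' Read a universe directory written by [writeUniverse()]
#' @param dir directory path.
#' @return A [SyntheticUniverse-class].
#' @export
readUniverse <- function(dir) {
    fp <- function(nm) file.path(dir, nm)
    cfg <- jsonlite::read_json(fp("config.json"), simplifyVector = TRUE)
    variants <- .readTsv(fp("variant_truth.tsv"))
    variants$disease <- as.character(variants$disease)
    variants$disease[variants$disease == "NA"] <- NA_character_
    scores <- readScoreTable(fp("scores.tsv"))
    tc <- readMatrixTsv(fp("term_counts.tsv"), integer = TRUE)
    assoc <- .readTsv(fp("associations.tsv"))
    expr <- readMatrixTsv(fp("expression.tsv"))
    new("SyntheticUniverse", config = cfg,
        genes = rownames(expr),
        diseases = rownames(tc), associations = assoc,
        variants = variants, scores = scores,
        sources = list(Exp = expr,
                       GO = .readTsv(fp("go_annotations.tsv")),
                       KEGG = readGmt(fp("kegg.gmt")),
                       Seq = readEdgeList(fp("seq_edges.tsv")),
                       Pfam = readGmt(fp("pfam.gmt")),
                       PPI = readEdgeList(fp("ppi_edges.tsv")),
                       TSFC = readMatrixTsv(fp("tsfc.tsv"), integer = TRUE),
                       miRNA = readGmt(fp("mirna.gmt"))),
        termCounts = tc)
}

#' Write a ranking table as TSV
#' @param ranking a [VariantRanking-class].
#' @param path output path.
#' @export
writeRanking <- function(ranking, path) {
    tab <- cbind(disease = ranking@disease, rankingTable(ranking))
    .writeTsv(tab, path)
    invisible(path)
}
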