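## Readers and writers for the standard text interchange formats of the
## pipeline: genotype TSV matrix and minimal VCF 4.2, gene models as BED /
## GFF3 (via rtracklayer), the long-format metabolite panel TSV, the wide
## accession-means dialect of the study's supplementary tables (rows =
## compounds keyed by id, columns = accessions), and the truth ledger.

#' @rdname metaboIO
#' @param gset a [GenotypeSet]; `path` a file path.
#' @export
writeGenotypesTsv <- function(gset, path) {
    G <- genotypeMatrix(gset)
    df <- data.frame(accession = rownames(G), G, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname metaboIO
#' @param genes optional gene `GRanges` to attach.
#' @export
readGenotypesTsv <- function(path, genes = GRanges()) {
    df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
    G <- as.matrix(df[, -1, drop = FALSE])
    rownames(G) <- df[[1]]
    ids <- colnames(G)
    parts <- strsplit(ids, ":", fixed = TRUE)
    snps <- GRanges(vapply(parts, `[`, "", 1),
                    IRanges(as.integer(vapply(parts, `[`, "", 2)),
                            width = 1L))
    names(snps) <- ids
    GenotypeSet(G, snps, genes)
}

#' @rdname metaboIO
#' @export
writeGenotypesVcf <- function(gset, path) {
    G <- genotypeMatrix(gset)
    snps <- snpRanges(gset)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("##fileformat=VCFv4.2",
                 paste0("##source=metaboGWA", packageVersion("metaboGWA")),
                 '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
                 paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                         "FILTER", "INFO", "FORMAT", rownames(G)),
                       collapse = "\t")), con)
    gt <- matrix("./.", ncol(G), nrow(G))
    gt[t(G) == 0L] <- "0|0"
    gt[t(G) == 1L] <- "1|1"
    lines <- paste(as.character(seqnames(snps)), start(snps), names(snps),
                   "A", "T", ".", "PASS", ".", "GT",
                   apply(gt, 1, paste, collapse = "\t"), sep = "\t")
    writeLines(lines, con)
    invisible(path)
}

#' @rdname metaboIO
#' @export
readGenotypesVcf <- function(path, genes = GRanges()) {
    if (!requireNamespace("vcfR", quietly = TRUE))
        stop("reading VCF requires the 'vcfR' package")
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(v)
    G <- matrix(NA_integer_, ncol(gt), nrow(gt),
                dimnames = list(colnames(gt), rownames(gt)))
    G[t(gt) %in% c("0|0", "0/0")] <- 0L
    G[t(gt) %in% c("1|1", "1/1")] <- 1L
    fix <- vcfR::getFIX(v)
    snps <- GRanges(fix[, "CHROM"], IRanges(as.integer(fix[, "POS"]),
                                            width = 1L))
    names(snps) <- rownames(gt)
    GenotypeSet(G, snps, genes)
}

#' @rdname metaboIO
#' @param bedPath,gffPath output paths for the two gene-model formats.
#' @export
writeGeneModels <- function(genes, bedPath = NULL, gffPath = NULL) {
    stopifnot(length(genes) > 0)
    g <- genes
    mcols(g)$name <- names(g)
    if (!is.null(bedPath))
        rtracklayer::export(g, bedPath, format = "BED")
    if (!is.null(gffPath)) {
        mcols(g)$type <- "gene"
        mcols(g)$ID <- names(g)
        rtracklayer::export(g, gffPath, format = "GFF3")
    }
    invisible(genes)
}

#' @rdname metaboIO
#' @export
readGeneModelsBed <- function(path) {
    g <- rtracklayer::import(path, format = "BED")
    names(g) <- mcols(g)$name
    mcols(g) <- NULL
    g
}

#' @rdname metaboIO
#' @param panel a [MetabolitePanel].
#' @export
writePanelTsv <- function(panel, path) {
    v <- panelValues(panel)
    meta <- sampleData(panel)
    long <- data.frame(
        sample_id = rep(colnames(v), each = nrow(v)),
        accession = rep(as.character(meta$accession), each = nrow(v)),
        experiment = rep(as.character(meta$experiment), each = nrow(v)),
        flat = rep(as.character(meta$flat), each = nrow(v)),
        replicate = rep(meta$replicate, each = nrow(v)),
        run_date = rep(as.character(meta$run_date), each = nrow(v)),
        compound_id = rep(rownames(v), ncol(v)),
        ion_count = as.vector(v))
    long <- long[!is.na(long$ion_count), ]
    write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname metaboIO
#' @param scale value scale of the stored panel.
#' @export
readPanelTsv <- function(path, scale = "count") {
    long <- read.table(path, header = TRUE, sep = "\t",
                       colClasses = c(run_date = "character"))
    samples <- unique(long[, c("sample_id", "accession", "experiment",
                               "flat", "replicate", "run_date")])
    cmps <- unique(long$compound_id)
    v <- matrix(NA_real_, length(cmps), nrow(samples),
                dimnames = list(cmps, samples$sample_id))
    v[cbind(match(long$compound_id, cmps),
            match(long$sample_id, samples$sample_id))] <- long$ion_count
    rownames(samples) <- samples$sample_id
    MetabolitePanel(v, samples[, -1], scale = scale)
}

#' Read/write the wide accession-means table dialect
#'
#' The dialect of the study's supplementary means tables: one row per
#' compound, first column the compound id, remaining columns one accession
#' each.
#'
#' @param means compounds x accessions matrix; `path` a file path.
#' @name metaboIO
#' @return readers return the corresponding object; writers return the
#'   path, invisibly.
#' @export
writeWideMeans <- function(means, path) {
    df <- data.frame(compound_id = rownames(means), means,
                     check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname metaboIO
#' @export
readWideMeans <- function(path) {
    df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- as.character(df[[1]])
    m
}

#' @rdname metaboIO
#' @param truth a `SimulationTruth` list.
#' @export
writeTruthTsv <- function(truth, path) {
    write.table(truth$causalMap, path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}

#' @rdname metaboIO
#' @param edges an edge table from [networkEdges()].
#' @export
writeEdgesTsv <- function(edges, path) {
    write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname metaboIO
#' @param graph an igraph object.
#' @export
writeGraphML <- function(graph, path) {
    igraph::write_graph(graph, path, format = "graphml")
    invisible(path)
}

#' @rdname metaboIO
#' @param hotspots hotspot table from [slidingHotspots()].
#' @export
writeHotspotsBed <- function(hotspots, path) {
    if (nrow(hotspots)) {
        bed <- data.frame(chrom = hotspots$chrom,
                          start = hotspots$start - 1L,   # 0-based half-open
                          end = hotspots$end,
                          name = sprintf("hotspot%02d",
                                         seq_len(nrow(hotspots))),
                          score = round(hotspots$mean_compounds, 3))
        write.table(bed, path, sep = "\t", quote = FALSE,
                    row.names = FALSE, col.names = FALSE)
    } else file.create(path)
    invisible(path)
}
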