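## Core data containers.
##
## MetabolitePanel holds replicate-level ion counts (or log2-normalized
## values) with the per-sample design metadata required by the downstream
## models: accession, experiment, flat, replicate and GC-TOF-MS run date.
## Compounds are rows, samples are columns (SummarizedExperiment convention).
##
## GenotypeSet holds a homozygous biallelic genotype matrix (accessions x
## SNPs, coded 0/1 with NA for missing) plus SNP coordinates and gene models
## as GRanges.

#' MetabolitePanel: replicate-level metabolite ion counts with design metadata
#'
#' A thin [SummarizedExperiment::SummarizedExperiment] subclass holding a
#' compounds x samples matrix of GC-TOF-MS ion counts (assay `"values"`) and,
#' per sample: `accession`, `experiment`, `flat`, `replicate` and `run_date`.
#' Missing entries (`NA`) mean the compound was not detected in that sample.
#' `metadata(x)$scale` records whether values are raw counts (`"count"`) or
#' normalized log2 units (`"log2"`).
#'
#' @param values numeric matrix, compounds (rows, named) x samples (columns).
#' @param sampleInfo data.frame with one row per sample and columns
#'   `accession`, `experiment`, `flat`, `replicate`, `run_date`.
#' @param scale `"count"` (raw ion counts) or `"log2"` (normalized).
#' @param x a `MetabolitePanel` (or `GenotypeSet` for the shared generics).
#'
#' @return `MetabolitePanel()` returns a validated object.  `panelValues()`
#'   the value matrix, `sampleData()` the sample metadata as a data.frame,
#'   `compoundIds()`/`accessionIds()` character vectors, `valueScale()` the
#'   scale string.
#' @examples
#' vals <- matrix(2^rexp(12, 1 / 9), 3, 4,
#'                dimnames = list(paste0("met", 1:3), paste0("s", 1:4)))
#' info <- data.frame(accession = rep(c("a1", "a2"), each = 2),
#'                    experiment = "A", flat = "F1",
#'                    replicate = rep(1:2, 2), run_date = "2009-01-01")
#' p <- MetabolitePanel(vals, info)
#' compoundIds(p)
#' @aliases accessionIds compoundIds sampleData panelValues valueScale
#' @export
MetabolitePanel <- function(values, sampleInfo, scale = c("count", "log2")) {
    scale <- match.arg(scale)
    values <- as.matrix(values)
    if (is.null(rownames(values)))
        stop("'values' must have compound ids as rownames")
    if (is.null(colnames(values)))
        colnames(values) <- if (!is.null(rownames(sampleInfo)) &&
                                !identical(rownames(sampleInfo),
                                           as.character(seq_len(nrow(sampleInfo)))))
            rownames(sampleInfo) else paste0("sample", seq_len(ncol(values)))
    sampleInfo <- as.data.frame(sampleInfo)
    se <- SummarizedExperiment(assays = list(values = values),
                               colData = DataFrame(sampleInfo))
    obj <- new("MetabolitePanel", se)
    metadata(obj)$scale <- scale
    validObject(obj)
    obj
}

#' @export
setClass("MetabolitePanel", contains = "SummarizedExperiment")

setValidity("MetabolitePanel", function(object) {
    msg <- character()
    need <- c("accession", "experiment", "flat", "replicate", "run_date")
    missing_cols <- setdiff(need, colnames(colData(object)))
    if (length(missing_cols))
        msg <- c(msg, paste("missing sample metadata column(s):",
                            paste(missing_cols, collapse = ", ")))
    else {
        if (anyNA(colData(object)$accession))
            msg <- c(msg, "every sample must have an accession")
        if (anyNA(colData(object)$run_date))
            msg <- c(msg, "every sample must have a run date")
    }
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "compound ids must be unique")
    if (length(msg)) msg else TRUE
})

#' @rdname MetabolitePanel-class
#' @export
setMethod("panelValues", "MetabolitePanel", function(x) assay(x, "values"))

#' @rdname MetabolitePanel-class
#' @export
setMethod("sampleData", "MetabolitePanel",
          function(x) as.data.frame(colData(x)))

#' @rdname MetabolitePanel-class
#' @export
setMethod("compoundIds", "MetabolitePanel", function(x) rownames(x))

#' @rdname MetabolitePanel-class
#' @export
setMethod("accessionIds", "MetabolitePanel",
          function(x) unique(as.character(colData(x)$accession)))

#' @rdname MetabolitePanel-class
#' @export
setMethod("valueScale", "MetabolitePanel",
          function(x) {
              sc <- metadata(x)$scale
              if (is.null(sc)) "count" else sc
          })

setMethod("show", "MetabolitePanel", function(object) {
    cat("MetabolitePanel:", nrow(object), "compounds x", ncol(object),
        "samples (", length(accessionIds(object)), "accessions,",
        length(unique(colData(object)$experiment)), "experiment(s),",
        length(unique(colData(object)$run_date)), "run batches;",
        valueScale(object), "scale )\n")
    det <- mean(.detected(object))
    cat(sprintf("  detected (non-missing, positive): %.1f%% of cells\n",
                100 * det))
})

## detection indicator: non-missing and, on the count scale, positive
.detected <- function(panel) {
    v <- panelValues(panel)
    if (valueScale(panel) == "count") !is.na(v) & v > 0 else !is.na(v)
}

#' GenotypeSet: homozygous biallelic genotypes with SNP and gene annotation
#'
#' Holds an accessions x SNPs matrix coded 0/1 (major/minor haploid allele of
#' an inbred line; `NA` = missing), SNP coordinates as a named
#' [GenomicRanges::GRanges] (ids `"chrom:pos"`), and gene models as a named
#' `GRanges` (1-based inclusive coordinates).
#'
#' @param genotypes integer/numeric matrix, accessions (rows, named) x SNPs
#'   (columns, named `"chrom:pos"`), values in \{0, 1, NA\}.
#' @param snps named `GRanges`, one range per SNP, aligned with the columns.
#' @param genes named `GRanges` of gene models.
#'
#' @return `GenotypeSet()` a validated object; `genotypeMatrix()` the matrix;
#'   `snpRanges()`/`geneModels()` the annotation; `snpMaf()` per-SNP minor
#'   allele frequencies; `accessionIds()` the accession names.
#' @examples
#' g <- matrix(c(0, 1, 0, 1, 1, 0), 3, 2,
#'             dimnames = list(paste0("acc", 1:3), c("Chr1:100", "Chr1:300")))
#' snps <- GenomicRanges::GRanges("Chr1", IRanges::IRanges(c(100, 300), width = 1))
#' names(snps) <- colnames(g)
#' genes <- GenomicRanges::GRanges("Chr1", IRanges::IRanges(1, 500))
#' names(genes) <- "gene1"
#' gs <- GenotypeSet(g, snps, genes)
#' snpMaf(gs)
#' @aliases genotypeMatrix snpRanges geneModels snpMaf
#' @export
GenotypeSet <- function(genotypes, snps, genes = GRanges()) {
    genotypes <- as.matrix(genotypes)
    storage.mode(genotypes) <- "integer"
    new("GenotypeSet", genotypes = genotypes, snps = snps, genes = genes)
}

#' @export
setClass("GenotypeSet",
         slots = c(genotypes = "matrix", snps = "GRanges", genes = "GRanges"))

setValidity("GenotypeSet", function(object) {
    msg <- character()
    g <- object@genotypes
    if (ncol(g) != length(object@snps))
        msg <- c(msg, "number of SNP ranges must match genotype columns")
    if (is.null(rownames(g)))
        msg <- c(msg, "genotype rows must be named by accession")
    if (length(object@snps) && is.null(names(object@snps)))
        msg <- c(msg, "SNP ranges must be named")
    bad <- g[!is.na(g)]
    if (length(bad) && !all(bad %in% c(0L, 1L)))
        msg <- c(msg, "genotypes must be coded 0/1 (homozygous inbred) or NA")
    if (length(msg)) msg else TRUE
})

#' @rdname GenotypeSet-class
#' @export
setMethod("genotypeMatrix", "GenotypeSet", function(x) x@genotypes)

#' @rdname GenotypeSet-class
#' @export
setMethod("snpRanges", "GenotypeSet", function(x) x@snps)

#' @rdname GenotypeSet-class
#' @export
setMethod("geneModels", "GenotypeSet", function(x) x@genes)

#' @rdname GenotypeSet-class
#' @export
setMethod("accessionIds", "GenotypeSet", function(x) rownames(x@genotypes))

#' @rdname GenotypeSet-class
#' @export
setMethod("snpMaf", "GenotypeSet", function(x) {
    f <- colMeans(x@genotypes, na.rm = TRUE)
    pmin(f, 1 - f)
})

setMethod("show", "GenotypeSet", function(object) {
    cat("GenotypeSet:", nrow(object@genotypes), "accessions x",
        ncol(object@genotypes), "SNPs on",
        length(unique(as.character(seqnames(object@snps)))), "chromosome(s);",
        length(object@genes), "gene models\n")
    if (ncol(object@genotypes))
        cat(sprintf("  MAF: min %.3f, median %.3f\n",
                    min(snpMaf(object)), median(snpMaf(object))))
})

## Subset a GenotypeSet by SNP index/id (keeps gene models).
.subsetSnps <- function(gset, idx) {
    GenotypeSet(gset@genotypes[, idx, drop = FALSE],
                gset@snps[idx], gset@genes)
}
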