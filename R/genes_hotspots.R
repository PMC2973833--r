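## Gene-level candidate calling and permutation-calibrated association
## hotspot detection.
##
## A gene-metabolite link is a candidate if >= minSnps distinct SNPs within
## `window` bp of the gene are significantly associated (q < qCutoff) with
## the metabolite.  Hotspots: per-gene counts of associated metabolites ->
## sliding averages over `windowGenes` consecutive genes (windows confined
## within a chromosome) -> genes whose covering-window average exceeds the
## permutation-derived null maximum -> isolated passing genes pruned ->
## maximal runs form intervals, retained if the average number of compounds
## per gene exceeds 2, or the interval has at least 8 genes averaging more
## than 1.

#' Assign SNPs to genes within a flanking window
#'
#' SNP s maps to gene g iff its position lies in
#' `[start(g) - window, end(g) + window]` (1-based inclusive); a SNP may map
#' to several genes.  SNPs on chromosomes absent from the gene annotation
#' are skipped with a warning.
#'
#' @param gset a [GenotypeSet] (or a named `GRanges` of SNPs via `snps`).
#' @param window flank in bp (default 1000).
#' @param genes optional gene `GRanges` overriding `geneModels(gset)`.
#' @return data.frame with columns `snp`, `gene`.
#' @export
assignSnpsToGenes <- function(gset, window = 1000L, genes = NULL) {
    snps <- snpRanges(gset)
    if (is.null(genes)) genes <- geneModels(gset)
    if (!length(genes)) return(data.frame(snp = character(),
                                          gene = character()))
    missingChrom <- setdiff(unique(as.character(seqnames(snps))),
                            unique(as.character(seqnames(genes))))
    if (length(missingChrom))
        warning("SNPs on chromosome(s) without gene models skipped: ",
                paste(missingChrom, collapse = ", "))
    ext <- GRanges(seqnames(genes),
                   IRanges(pmax(1L, start(genes) - window),
                           end(genes) + window))
    names(ext) <- names(genes)
    hits <- suppressWarnings(findOverlaps(snps, ext))
    data.frame(snp = names(snps)[S4Vectors::queryHits(hits)],
               gene = names(ext)[S4Vectors::subjectHits(hits)])
}

#' Call candidate gene-metabolite links
#'
#' @param assoc association table from [associationScan()] (needs `q`).
#' @param snpGeneMap SNP-to-gene map from [assignSnpsToGenes()].
#' @param qCutoff significance threshold on q (default 0.20).
#' @param minSnps minimum number of distinct significant SNPs mapped to the
#'   gene (default 2).
#' @return data.frame of candidate links: `gene`, `compound`,
#'   `n_significant_snps`, `min_q`.
#' @export
callCandidateGenes <- function(assoc, snpGeneMap, qCutoff = 0.2,
                               minSnps = 2L) {
    sig <- assoc[!is.na(assoc$q) & assoc$q < qCutoff, , drop = FALSE]
    empty <- data.frame(gene = character(), compound = character(),
                        n_significant_snps = integer(), min_q = numeric())
    if (!nrow(sig) || !nrow(snpGeneMap)) return(empty)
    mg <- merge(sig, snpGeneMap, by = "snp")
    if (!nrow(mg)) return(empty)
    keyed <- unique(mg[, c("gene", "compound", "snp")])
    agg <- aggregate(snp ~ gene + compound, data = keyed, FUN = length)
    names(agg)[3] <- "n_significant_snps"
    minq <- aggregate(q ~ gene + compound, data = mg, FUN = min)
    names(minq)[3] <- "min_q"
    out <- merge(agg, minq, by = c("gene", "compound"))
    out <- out[out$n_significant_snps >= minSnps, , drop = FALSE]
    out[order(out$gene, out$compound), , drop = FALSE]
}

#' Per-gene counts of associated compounds
#'
#' @param candidates candidate links from [callCandidateGenes()].
#' @param genes named gene `GRanges` (defines the full gene universe and
#'   genome order).
#' @return data.frame in genome order: `gene`, `chrom`, `start`, `end`,
#'   `n_compounds`.
#' @export
geneCompoundCounts <- function(candidates, genes) {
    ord <- order(as.character(seqnames(genes)), start(genes))
    genes <- genes[ord]
    counts <- table(factor(candidates$gene, levels = names(genes)))
    data.frame(gene = names(genes),
               chrom = as.character(seqnames(genes)),
               start = start(genes), end = end(genes),
               n_compounds = as.integer(counts), row.names = NULL)
}

## sliding means of length k over x, and the per-position maximum over all
## windows covering each position
.coveringWindowMax <- function(x, k) {
    m <- length(x)
    k <- min(k, m)
    cs <- c(0, cumsum(x))
    wmean <- (cs[(k + 1):(m + 1)] - cs[1:(m - k + 1)]) / k
    out <- numeric(m)
    for (i in seq_len(m)) {
        lo <- max(1L, i - k + 1L)
        hi <- min(i, m - k + 1L)
        out[i] <- max(wmean[lo:hi])
    }
    list(cover = out, windows = wmean)
}

#' Detect association hotspots by sliding averages against a null maximum
#'
#' @param candidates candidate links from [callCandidateGenes()].
#' @param genes named gene `GRanges` in any order (re-ordered by chromosome
#'   and position internally).
#' @param windowGenes sliding-window size in genes (default 100); windows do
#'   not span chromosome boundaries and are truncated (with a warning) on
#'   chromosomes with fewer genes.
#' @param nullMax the permutation-derived "maximum average number of false
#'   compounds per gene"; genes pass if any covering-window average strictly
#'   exceeds it.
#' @param minMeanCompounds,minGenesAlt,minMeanAlt retention rule: keep an
#'   interval if its mean compounds per gene is `> minMeanCompounds`
#'   (default 2), or it has at least `minGenesAlt` genes (default 8) with a
#'   mean `> minMeanAlt` (default 1).
#' @return data.frame of hotspot intervals: `chrom`, `start`, `end`,
#'   `n_genes`, `mean_compounds`, `genes` (comma-separated ids, consecutive
#'   in genome order).
#' @export
slidingHotspots <- function(candidates, genes, windowGenes = 100L, nullMax,
                            minMeanCompounds = 2, minGenesAlt = 8L,
                            minMeanAlt = 1) {
    counts <- geneCompoundCounts(candidates, genes)
    empty <- data.frame(chrom = character(), start = integer(),
                        end = integer(), n_genes = integer(),
                        mean_compounds = numeric(), genes = character())
    if (!nrow(counts)) return(empty)
    out <- list()
    for (ch in unique(counts$chrom)) {
        cc <- counts[counts$chrom == ch, , drop = FALSE]
        m <- nrow(cc)
        if (m < windowGenes)
            warning("chromosome ", ch, " has fewer than ", windowGenes,
                    " genes; window truncated to ", m)
        cw <- .coveringWindowMax(cc$n_compounds, windowGenes)
        pass <- cw$cover > nullMax
        ## prune genes with no passing immediate neighbor
        keep <- pass
        if (m >= 2) {
            nb <- cbind(c(FALSE, pass[-m]), c(pass[-1], FALSE))
            keep <- pass & (nb[, 1] | nb[, 2])
        } else keep <- rep(FALSE, m)
        r <- rle(keep)
        endIdx <- cumsum(r$lengths)
        startIdx <- endIdx - r$lengths + 1L
        for (j in which(r$values)) {
            idx <- startIdx[j]:endIdx[j]
            mc <- mean(cc$n_compounds[idx])
            if (mc > minMeanCompounds ||
                (length(idx) >= minGenesAlt && mc > minMeanAlt)) {
                out[[length(out) + 1]] <- data.frame(
                    chrom = ch, start = min(cc$start[idx]),
                    end = max(cc$end[idx]), n_genes = length(idx),
                    mean_compounds = mc,
                    genes = paste(cc$gene[idx], collapse = ","))
            }
        }
    }
    if (!length(out)) return(empty)
    do.call(rbind, out)
}

#' Permutation null for candidate calling and hotspot detection
#'
#' Per permutation round, accession labels are re-sampled without
#' replacement independently within each compound, the full scan ->
#' candidate calling -> sliding averages path is recomputed, and two null
#' summaries are collected: the number of candidate genes per metabolite
#' (expected false genes), and the maximum sliding-average number of
#' compounds per gene ("maximum average number of false compounds per
#' gene").  The identity permutation (`nPerm = 0` plus `includeObserved`)
#' reproduces the observed statistics exactly.
#'
#' @param means compounds x accessions matrix of accession means.
#' @param gset MAF-filtered [GenotypeSet].
#' @param K kinship matrix (computed when `NULL`).
#' @param nPerm number of permutation rounds (>= 1).
#' @param qCutoff,minSnps,window,windowGenes thresholds as in
#'   [callCandidateGenes()] / [slidingHotspots()].
#' @param seed integer seed for the permutation stream.
#' @return list with `nullMax` (max of the per-permutation maximum sliding
#'   averages), `perPermutation` (data.frame: `perm`,
#'   `max_sliding_average`, `mean_genes_per_metabolite`), and
#'   `meanFalseGenesPerMetabolite`.
#' @export
permutationNull <- function(means, gset, K = NULL, nPerm = 10L,
                            qCutoff = 0.2, minSnps = 2L, window = 1000L,
                            windowGenes = 100L, seed = 1L) {
    stopifnot(nPerm >= 1L)
    if (is.null(K)) K <- kinshipMatrix(gset)
    s2g <- assignSnpsToGenes(gset, window = window)
    genes <- geneModels(gset)
    set.seed(seed)
    res <- lapply(seq_len(nPerm), function(b) {
        perm <- means
        for (i in seq_len(nrow(perm)))
            perm[i, ] <- perm[i, sample.int(ncol(perm))]
        assoc <- associationScan(perm, gset, K = K)
        cand <- callCandidateGenes(assoc, s2g, qCutoff, minSnps)
        counts <- geneCompoundCounts(cand, genes)
        maxAvg <- 0
        for (ch in unique(counts$chrom)) {
            x <- counts$n_compounds[counts$chrom == ch]
            maxAvg <- max(maxAvg,
                          .coveringWindowMax(x, windowGenes)$windows)
        }
        gpm <- if (nrow(cand))
            mean(table(cand$compound)) else 0
        data.frame(perm = b, max_sliding_average = maxAvg,
                   mean_genes_per_metabolite = gpm)
    })
    per <- do.call(rbind, res)
    list(nullMax = max(per$max_sliding_average),
         perPermutation = per,
         meanFalseGenesPerMetabolite = mean(per$mean_genes_per_metabolite))
}
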