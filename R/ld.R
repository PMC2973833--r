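## Gene-level linkage disequilibrium.
##
## For gene-level LD each gene is collapsed into a biallelic locus: the
## empirically observed haplotype strings over the gene's SNPs are tallied,
## the most frequent string becomes the "major" allele (0) and all others
## the "minor" allele (1); ties are broken lexicographically.  r^2 between
## collapsed loci (or SNPs) is the squared Pearson correlation of the
## binary vectors, equivalently (p_ab - p_a p_b)^2 / (p_a(1-p_a) p_b(1-p_b)).
## The hotspot-vs-genome profile statistic is the "average maximum SNP-SNP
## r^2": all SNP-pair r^2 between two genes, per-SNP maxima taken from each
## gene's side, the two side-wise means averaged.

#' Collapse a gene into a biallelic locus
#'
#' @param gset a [GenotypeSet].
#' @param snpIds SNP ids (columns of the genotype matrix) belonging to the
#'   gene; accessions with any missing genotype among them are dropped.
#' @return list with `allele` (named 0/1 vector; 0 = major haplotype),
#'   `majorHaplotype` (the collapsed string), `majorFrequency`, and
#'   `nHaplotypes`.
#' @export
collapseGene <- function(gset, snpIds) {
    G <- genotypeMatrix(gset)[, snpIds, drop = FALSE]
    complete <- !apply(is.na(G), 1, any)
    if (!any(complete))
        stop("all accessions have missing genotypes for this gene")
    G <- G[complete, , drop = FALSE]
    haps <- apply(G, 1, paste, collapse = "")
    tab <- table(haps)
    top <- names(tab)[tab == max(tab)]
    major <- sort(top)[1]                     # lexicographic tie-break
    allele <- as.integer(haps != major)
    names(allele) <- rownames(G)
    list(allele = allele, majorHaplotype = major,
         majorFrequency = max(tab) / length(haps),
         nHaplotypes = length(tab))
}

#' Collapse all genes with mapped SNPs
#'
#' @param gset a [GenotypeSet].
#' @param snpGeneMap SNP-to-gene map from [assignSnpsToGenes()].
#' @param genes optional subset of gene ids.
#' @return accessions x genes matrix of collapsed 0/1 alleles (`NA` for
#'   accessions dropped from a gene's collapse).
#' @export
collapseLoci <- function(gset, snpGeneMap, genes = NULL) {
    if (is.null(genes)) genes <- unique(snpGeneMap$gene)
    accs <- accessionIds(gset)
    out <- matrix(NA_integer_, length(accs), length(genes),
                  dimnames = list(accs, genes))
    for (g in genes) {
        snps <- snpGeneMap$snp[snpGeneMap$gene == g]
        if (!length(snps)) next
        cl <- collapseGene(gset, snps)
        out[names(cl$allele), g] <- cl$allele
    }
    out
}

#' Squared-correlation linkage disequilibrium between two binary loci
#'
#' @param a,b equal-length 0/1 vectors (missing allowed; pairwise complete).
#' @return r^2 in `[0, 1]`, or `NA` if either locus is monomorphic on the
#'   complete observations.
#' @export
ldR2 <- function(a, b) {
    stopifnot(length(a) == length(b))
    ok <- !is.na(a) & !is.na(b)
    a <- a[ok]; b <- b[ok]
    if (length(a) < 2 || var(a) == 0 || var(b) == 0) return(NA_real_)
    cor(a, b)^2
}

#' Screen candidate gene pairs for non-syntenic (trans) LD
#'
#' Among gene pairs that are candidates for the same compound and lie on
#' different chromosomes, reports those whose collapsed-locus r^2 exceeds
#' `r2Threshold`.  Also reports the 99th percentile and maximum of the r^2
#' of all non-syntenic pairs among the collapsed loci (the empirical
#' background the threshold should be judged against).
#'
#' @param candidates candidate links from [callCandidateGenes()].
#' @param collapsed accessions x genes collapsed-allele matrix from
#'   [collapseLoci()].
#' @param genes named gene `GRanges` carrying chromosomes.
#' @param r2Threshold reporting threshold (default 0.4).
#' @return list with `pairs` (data.frame `gene_1`, `gene_2`, `compound`,
#'   `r2`), `q99`, `max`, and `nNonSyntenic` (background pair count).
#' @export
nonsyntenicLdScreen <- function(candidates, collapsed, genes,
                                r2Threshold = 0.4) {
    chrom <- setNames(as.character(seqnames(genes)), names(genes))
    ids <- intersect(colnames(collapsed), names(chrom))
    R2 <- suppressWarnings(cor(collapsed[, ids, drop = FALSE],
                               use = "pairwise.complete.obs"))^2
    diffChrom <- outer(chrom[ids], chrom[ids], "!=")
    bg <- R2[diffChrom & upper.tri(R2)]
    bg <- bg[!is.na(bg)]

    pairs <- data.frame(gene_1 = character(), gene_2 = character(),
                        compound = character(), r2 = numeric())
    for (cmp in unique(candidates$compound)) {
        gs <- intersect(candidates$gene[candidates$compound == cmp], ids)
        if (length(gs) < 2) next
        pr <- t(combn(gs, 2))
        for (k in seq_len(nrow(pr))) {
            g1 <- pr[k, 1]; g2 <- pr[k, 2]
            if (chrom[g1] == chrom[g2]) next
            r2 <- R2[g1, g2]
            if (!is.na(r2) && r2 > r2Threshold)
                pairs <- rbind(pairs, data.frame(gene_1 = g1, gene_2 = g2,
                                                 compound = cmp, r2 = r2))
        }
    }
    list(pairs = pairs,
         q99 = if (length(bg)) quantile(bg, 0.99, names = FALSE) else NA_real_,
         max = if (length(bg)) max(bg) else NA_real_,
         nNonSyntenic = length(bg))
}

## average maximum SNP-SNP r^2 between two SNP sets
.avgMaxR2 <- function(G1, G2) {
    R2 <- suppressWarnings(cor(G1, G2, use = "pairwise.complete.obs"))^2
    if (all(is.na(R2))) return(NA_real_)
    m1 <- mean(apply(R2, 1, max, na.rm = TRUE))
    m2 <- mean(apply(R2, 2, max, na.rm = TRUE))
    (m1 + m2) / 2
}

#' Gene-gene LD profile: average maximum SNP-SNP r^2
#'
#' For every (hotspot gene, genome gene) pair: (1) r^2 between all SNP-pair
#' combinations, (2) per-SNP maximum r^2 taken separately from each gene's
#' side, (3) the two side-wise means averaged.  A pair is called in
#' significant LD if its statistic exceeds the mean statistic over all
#' different-chromosome gene pairs of this profile (always recomputed from
#' the data, never hard-coded).
#'
#' @param hotspotGenes,allGenes character vectors of gene ids (must have
#'   mapped SNPs; genes without SNPs yield `NA` rows/columns).
#' @param gset a [GenotypeSet].
#' @param snpGeneMap SNP-to-gene map from [assignSnpsToGenes()].
#' @return list with `r2` (hotspot x genome statistic matrix),
#'   `threshold` (mean non-syntenic statistic), and `significant` (logical
#'   matrix `r2 > threshold`).
#' @export
hotspotGenomeLdProfile <- function(hotspotGenes, allGenes, gset,
                                   snpGeneMap) {
    G <- .meanImpute(genotypeMatrix(gset))
    chrom <- setNames(as.character(seqnames(geneModels(gset))),
                      names(geneModels(gset)))
    snpsOf <- split(snpGeneMap$snp, snpGeneMap$gene)
    stat <- matrix(NA_real_, length(hotspotGenes), length(allGenes),
                   dimnames = list(hotspotGenes, allGenes))
    for (h in hotspotGenes) {
        s1 <- snpsOf[[h]]
        if (is.null(s1)) next
        G1 <- G[, s1, drop = FALSE]
        for (g in allGenes) {
            s2 <- snpsOf[[g]]
            if (is.null(s2)) next
            stat[h, g] <- .avgMaxR2(G1, G[, s2, drop = FALSE])
        }
    }
    diffChrom <- outer(chrom[hotspotGenes], chrom[allGenes], "!=")
    nsVals <- stat[diffChrom & !is.na(stat)]
    threshold <- if (length(nsVals)) mean(nsVals) else NA_real_
    list(r2 = stat, threshold = threshold,
         significant = !is.na(stat) & stat > threshold)
}
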