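test_that("gene collapse tallies haplotypes with a lexicographic tie-break", {
    # 8 accessions over 2 SNPs: haplotypes 00 x4, 01 x3, 11 x1
    G <- rbind(a1 = c(0L, 0L), a2 = c(0L, 0L), a3 = c(0L, 0L),
               a4 = c(0L, 0L), a5 = c(0L, 1L), a6 = c(0L, 1L),
               a7 = c(0L, 1L), a8 = c(1L, 1L))
    gset <- toyGenotypes(G, "Chr1", c(100L, 200L))
    cl <- collapseGene(gset, names(snpRanges(gset)))
    expect_identical(cl$majorHaplotype, "00")
    expect_equal(unname(cl$allele), c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L))
    expect_equal(cl$majorFrequency, 0.5)
    # tie 4 vs 4: lexicographically smallest string becomes major
    G2 <- G; G2["a8", ] <- c(0L, 1L)
    gset2 <- toyGenotypes(G2, "Chr1", c(100L, 200L))
    ids2 <- names(snpRanges(gset2))
    cl2 <- collapseGene(gset2, ids2)
    expect_identical(cl2$majorHaplotype, "00")
    expect_identical(collapseGene(gset2, ids2)$allele, cl2$allele)
    # single-SNP gene: collapsed allele is the (relabeled) SNP genotype
    cl3 <- collapseGene(gset, "Chr1:200")
    expect_equal(unname(cl3$allele), unname(G[, 2]))
    # accessions with missing genotypes are dropped from the collapse
    G3 <- G; G3["a1", 1] <- NA
    cl4 <- collapseGene(toyGenotypes(G3, "Chr1", c(100L, 200L)),
                        c("Chr1:100", "Chr1:200"))
    expect_false("a1" %in% names(cl4$allele))
})

test_that("r2 matches its closed form and invariances", {
    expect_equal(ldR2(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
    expect_equal(ldR2(c(0, 0, 1, 1), c(1, 1, 0, 0)), 1)   # label swap
    expect_equal(ldR2(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0)   # independence
    expect_true(is.na(ldR2(c(0, 0, 0, 0), c(0, 1, 0, 1))))
    set.seed(12)
    for (i in 1:10) {
        a <- rbinom(30, 1, 0.4); b <- rbinom(30, 1, 0.4)
        if (var(a) == 0 || var(b) == 0) next
        r2 <- ldR2(a, b)
        expect_equal(ldR2(1 - a, b), r2)                  # allele relabeling
        ord <- sample(30)
        expect_equal(ldR2(a[ord], b[ord]), r2)            # accession order
        # closed form (p_ab - p_a p_b)^2 / (p_a(1-p_a) p_b(1-p_b))
        pa <- mean(a); pb <- mean(b); pab <- mean(a & b)
        expect_equal(r2, (pab - pa * pb)^2 /
                         (pa * (1 - pa) * pb * (1 - pb)),
                     tolerance = 1e-12)
    }
})

test_that("average-maximum SNP-SNP r2 matches brute force on a 2x3 toy pair", {
    set.seed(44)
    G <- matrix(rbinom(20 * 5, 1, 0.5), 20, 5)
    rownames(G) <- sprintf("a%02d", 1:20)
    gset <- toyGenotypes(G, "Chr1", 100L * (1:5))
    map <- data.frame(snp = names(snpRanges(gset)),
                      gene = c("gA", "gA", "gB", "gB", "gB"))
    prof <- hotspotGenomeLdProfile("gA", c("gA", "gB"), gset, map)
    # brute force over the 6 SNP pairs
    R2 <- cor(G[, 1:2], G[, 3:5])^2
    manual <- (mean(apply(R2, 1, max)) + mean(apply(R2, 2, max))) / 2
    expect_equal(prof$r2["gA", "gB"], manual, tolerance = 1e-12)
    # a gene against itself attains the maximum statistic 1
    expect_equal(prof$r2["gA", "gA"], 1)
    # two single-SNP genes: the statistic collapses to their plain r2
    map1 <- data.frame(snp = names(snpRanges(gset))[c(1, 3)],
                       gene = c("g1", "g2"))
    p1 <- hotspotGenomeLdProfile("g1", "g2", gset, map1)
    expect_equal(p1$r2["g1", "g2"], ldR2(G[, 1], G[, 3]))
    # statistic dominates the plain mean SNP-SNP r2
    expect_gte(prof$r2["gA", "gB"], mean(R2))
})

test_that("the trans-LD screen finds planted pairs and little else", {
    cfg <- smallSimConfig(nAccessions = 96L, nSnps = 400L,
                          nChromosomes = 2L, seed = 61L)
    gset <- mafFilter(simulateGenotypes(cfg), 0.05)
    s2g <- assignSnpsToGenes(gset)
    genes <- geneModels(gset)
    chrom <- as.character(GenomicRanges::seqnames(genes))
    g1 <- names(genes)[chrom == "Chr1"][2]
    g2 <- names(genes)[chrom == "Chr2"][2]
    collapsed <- collapseLoci(gset, s2g)
    # plant trans-LD: copy g1's collapsed alleles onto g2 with 5% noise
    set.seed(62)
    a <- collapsed[, g1]
    flip <- rbinom(length(a), 1, 0.05) == 1
    collapsed[, g2] <- ifelse(flip, 1L - a, a)
    cand <- data.frame(gene = c(g1, g2), compound = "m1",
                       n_significant_snps = 2L, min_q = 0.01)
    scr <- nonsyntenicLdScreen(cand, collapsed, genes, r2Threshold = 0.4)
    expect_equal(nrow(scr$pairs), 1)
    expect_setequal(unlist(scr$pairs[, c("gene_1", "gene_2")]), c(g1, g2))
    expect_lte(scr$q99, 0.5)
    # no cross-chromosome co-associated pairs -> empty list
    sameChrom <- data.frame(gene = names(genes)[chrom == "Chr1"][3:4],
                            compound = "m2", n_significant_snps = 2L,
                            min_q = 0.01)
    expect_equal(nrow(nonsyntenicLdScreen(sameChrom, collapsed,
                                          genes)$pairs), 0)
})

test_that("independent genomes rarely exceed the trans-LD threshold", {
    exceed <- vapply(1:25, function(r) {
        set.seed(300 + r)
        A <- matrix(rbinom(96 * 20, 1, runif(20, 0.1, 0.9)), 96, 20,
                    byrow = TRUE)
        r2 <- suppressWarnings(cor(A))^2
        sum(r2[upper.tri(r2)] > 0.4, na.rm = TRUE)
    }, numeric(1))
    expect_lte(mean(exceed), 0.2)
})
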