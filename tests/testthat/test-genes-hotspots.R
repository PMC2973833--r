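toyGeneLayout <- function() {
    # 5 genes on 2 chromosomes, two of them overlapping; 12 SNPs
    genes <- GenomicRanges::GRanges(
        c("Chr1", "Chr1", "Chr1", "Chr2", "Chr2"),
        IRanges::IRanges(start = c(2000, 6000, 6500, 1000, 9000),
                         end = c(3000, 7000, 7800, 2000, 9500)))
    names(genes) <- paste0("g", 1:5)
    pos <- c(999, 1000, 2000, 3000, 4001, 5600, 6700, 7900, 8801, 500,
             2900, 10500)
    chrom <- c(rep("Chr1", 9), rep("Chr2", 3))
    G <- matrix(rep(c(0L, 1L), 6 * 12), 12, 12)
    rownames(G) <- sprintf("a%02d", 1:12)
    toyGenotypes(G, chrom, as.integer(pos), genes = genes)
}

test_that("SNP-gene assignment respects the 1 kb inclusive window", {
    gset <- toyGeneLayout()
    map <- assignSnpsToGenes(gset, window = 1000)
    # SNP at gene start is assigned; window boundary is inclusive;
    # window + 1 bp past the end is not assigned
    expect_true(any(map$snp == "Chr1:2000" & map$gene == "g1"))
    expect_true(any(map$snp == "Chr1:1000" & map$gene == "g1"))  # start-1000
    expect_false(any(map$snp == "Chr1:999" & map$gene == "g1"))
    expect_true(any(map$snp == "Chr1:4000" & map$gene == "g1") == FALSE)
    expect_false(any(map$snp == "Chr1:8801"))   # 1001 bp past g3 end

    # brute-force interval check over all SNP x gene pairs
    snps <- snpRanges(gset); genes <- geneModels(gset)
    expected <- do.call(rbind, lapply(seq_along(snps), function(i) {
        hits <- vapply(seq_along(genes), function(j) {
            as.character(GenomicRanges::seqnames(snps)[i]) ==
                as.character(GenomicRanges::seqnames(genes)[j]) &&
                GenomicRanges::start(snps)[i] >=
                    GenomicRanges::start(genes)[j] - 1000 &&
                GenomicRanges::start(snps)[i] <=
                    GenomicRanges::end(genes)[j] + 1000
        }, logical(1))
        if (any(hits)) data.frame(snp = names(snps)[i],
                                  gene = names(genes)[hits])
    }))
    key <- function(d) sort(paste(d$snp, d$gene))
    expect_identical(key(map), key(expected))
    # a SNP shared by the two overlapping genes maps to both
    expect_setequal(map$gene[map$snp == "Chr1:6700"], c("g2", "g3"))
})

test_that("candidate calling needs at least minSnps distinct significant SNPs", {
    map <- data.frame(snp = c("s1", "s2", "s3"), gene = "g1")
    assoc1 <- data.frame(snp = "s1", compound = "m1", q = 0.01)
    expect_equal(nrow(callCandidateGenes(assoc1, map)), 0)
    assoc2 <- data.frame(snp = c("s1", "s2"), compound = "m1",
                         q = c(0.01, 0.1))
    cand <- callCandidateGenes(assoc2, map)
    expect_equal(nrow(cand), 1)
    expect_equal(cand$n_significant_snps, 2L)
    expect_equal(cand$min_q, 0.01)
    # q at the cutoff is not significant (strict inequality)
    assoc3 <- data.frame(snp = c("s1", "s2"), compound = "m1",
                         q = c(0.2, 0.01))
    expect_equal(nrow(callCandidateGenes(assoc3, map, qCutoff = 0.2)), 0)
})

test_that("candidate links are monotone in both thresholds", {
    set.seed(20)
    map <- data.frame(snp = paste0("s", 1:40),
                      gene = rep(paste0("g", 1:8), each = 5))
    assoc <- expand.grid(snp = paste0("s", 1:40),
                         compound = paste0("m", 1:6),
                         stringsAsFactors = FALSE)
    assoc$q <- runif(nrow(assoc))
    key <- function(d) paste(d$gene, d$compound)
    c1 <- callCandidateGenes(assoc, map, qCutoff = 0.1)
    c2 <- callCandidateGenes(assoc, map, qCutoff = 0.3)
    expect_true(all(key(c1) %in% key(c2)))       # raising q never removes
    c3 <- callCandidateGenes(assoc, map, qCutoff = 0.3, minSnps = 3L)
    expect_true(all(key(c3) %in% key(c2)))       # raising minSnps never adds
    # per-gene counts conserve the total number of links
    genes <- GenomicRanges::GRanges("Chr1",
                                    IRanges::IRanges(1:8 * 1000, width = 500))
    names(genes) <- paste0("g", 1:8)
    counts <- geneCompoundCounts(c2, genes)
    expect_equal(sum(counts$n_compounds), nrow(c2))
})

test_that("sliding hotspot detection prunes isolated genes", {
    genes <- GenomicRanges::GRanges("Chr1",
                                    IRanges::IRanges(1:20 * 1000, width = 500))
    names(genes) <- paste0("g", 1:20)
    # no candidates -> no hotspots
    none <- callCandidateGenes(data.frame(snp = "s", compound = "m",
                                          q = 1), data.frame(snp = "s",
                                                             gene = "g1"))
    expect_equal(nrow(suppressWarnings(
        slidingHotspots(none, genes, windowGenes = 1, nullMax = 0))), 0)
    # a single isolated passing gene is removed by the neighbor rule
    lone <- data.frame(gene = "g10", compound = paste0("m", 1:5),
                       n_significant_snps = 2L, min_q = 0.01)
    hs <- slidingHotspots(lone, genes, windowGenes = 1, nullMax = 0.5)
    expect_equal(nrow(hs), 0)
    # two adjacent passing genes survive and form one interval
    pairg <- rbind(lone, data.frame(gene = "g11",
                                    compound = paste0("m", 1:5),
                                    n_significant_snps = 2L, min_q = 0.01))
    hs2 <- slidingHotspots(pairg, genes, windowGenes = 1, nullMax = 0.5)
    expect_equal(nrow(hs2), 1)
    expect_equal(hs2$n_genes, 2L)
    expect_equal(hs2$mean_compounds, 5)
    expect_identical(hs2$genes, "g10,g11")
    # retention is strict: mean exactly 2 with < 8 genes is dropped
    two <- data.frame(gene = c("g10", "g11"),
                      compound = rep(paste0("m", 1:2), each = 2),
                      n_significant_snps = 2L, min_q = 0.01)
    expect_equal(nrow(slidingHotspots(two, genes, windowGenes = 1,
                                      nullMax = 0.5)), 0)
})

test_that("windows are confined within chromosomes and truncated with warning", {
    genes <- GenomicRanges::GRanges(rep(c("Chr1", "Chr2"), each = 3),
                                    IRanges::IRanges(rep(1:3 * 1000, 2),
                                                     width = 500))
    names(genes) <- paste0("g", 1:6)
    cand <- data.frame(gene = c("g1", "g2", "g3"),
                       compound = rep(paste0("m", 1:4), each = 3),
                       n_significant_snps = 2L, min_q = 0.01)
    ws <- capture_warnings(hs <- slidingHotspots(cand, genes,
                                                 windowGenes = 100,
                                                 nullMax = 0.1))
    expect_match(ws, "fewer than", all = TRUE)
    expect_length(ws, 2)                  # one truncation warning per chromosome
    expect_true(all(hs$chrom == "Chr1"))
})

test_that("the permutation null is deterministic and calibrated", {
    cfg <- smallSimConfig(nAccessions = 48L, nSnps = 300L,
                          nMetabolites = 8L, targetH2 = 0.5,
                          effectSize = 2, seed = 31L)
    gset <- mafFilter(simulateGenotypes(cfg), 0.05)
    sim <- simulateMetabolome(gset, cfg)
    means <- estimateAccessionMeans(log2MedianNormalize(sim$panel))
    K <- kinshipMatrix(gset)
    n1 <- permutationNull(means, gset, K = K, nPerm = 2, windowGenes = 5,
                          seed = 99)
    n2 <- permutationNull(means, gset, K = K, nPerm = 2, windowGenes = 5,
                          seed = 99)
    expect_identical(n1$perPermutation, n2$perPermutation)
    expect_gte(n1$nullMax, 0)
    # the unshuffled data through the same code path reproduces the
    # observed statistics exactly
    s2g <- assignSnpsToGenes(gset)
    a1 <- associationScan(means, gset, K = K)
    a2 <- associationScan(means, gset, K = K)
    expect_identical(callCandidateGenes(a1, s2g),
                     callCandidateGenes(a2, s2g))
})
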