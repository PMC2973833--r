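## Self-contained simulation studies that validate the pipeline's core
## statistical properties end-to-end: mixed-model calibration under
## population structure, heritability recovery, network edge recovery, and
## hotspot recovery/calibration.  These are the reproducible experiments
## reported in the package documentation; each runs in minutes on one CPU.

#' Mixed-model calibration under population structure
#'
#' Simulates a structured accession panel (no causal SNP, polygenic
#' background only) and compares the genomic inflation of the
#' kinship-corrected mixed-model scan with a naive (no-kinship) least
#' squares scan on the same traits.
#'
#' @param seed integer seed.
#' @param nTraits number of null traits (default 50).
#' @param nSnps SNPs before MAF filtering (default 2000).
#' @param fst structure divergence (default 0.2).
#' @param backgroundH2 polygenic variance share (default 0.5).
#' @param nAccessions panel size (default 96).
#' @return list with `gifMixed`, `gifOls`, and `nSnps` (SNPs scanned).
#' @export
mixedModelCalibrationStudy <- function(seed = 1L, nTraits = 50L,
                                       nSnps = 2000L, fst = 0.2,
                                       backgroundH2 = 0.5,
                                       nAccessions = 96L) {
    cfg <- simulationConfig(nAccessions = nAccessions, nSnps = nSnps,
                            fst = fst, seed = seed)
    gset <- mafFilter(simulateGenotypes(cfg), 0.05)
    traits <- simulatePolygenicTraits(gset, nTraits, h2 = backgroundH2,
                                      seed = seed + 1L)
    K <- kinshipMatrix(gset)
    Kid <- diag(nrow(K)); dimnames(Kid) <- dimnames(K)
    pMixed <- pOls <- numeric(0)
    eigK <- eigen(K, symmetric = TRUE); eigK$values <- pmax(eigK$values, 0)
    G <- genotypeMatrix(gset)
    GtK <- crossprod(eigK$vectors, G)
    for (i in seq_len(nTraits)) {
        y <- traits[i, ]
        pMixed <- c(pMixed, emmaScan(y, gset, K = K, eig = eigK,
                                     Gt = GtK)$p)
        pOls <- c(pOls, emmaScan(y, gset, K = Kid)$p)
    }
    list(gifMixed = genomicInflation(pMixed),
         gifOls = genomicInflation(pOls),
         nSnps = ncol(G))
}

#' Heritability recovery study
#'
#' Simulates replicated metabolite panels at given heritability targets and
#' reports the mean estimated broad-sense H2 per target.
#'
#' @param targets heritability targets (default `c(0.2, 0.45, 0.8)`).
#' @param nMetabolites metabolites per target (default 100).
#' @param seed integer seed.
#' @param nAccessions panel size (default 96).
#' @return data.frame: `target`, `mean_h2`, `sd_h2`, `n`.
#' @export
heritabilityRecoveryStudy <- function(targets = c(0.2, 0.45, 0.8),
                                      nMetabolites = 100L, seed = 1L,
                                      nAccessions = 96L) {
    out <- lapply(seq_along(targets), function(i) {
        cfg <- simulationConfig(nAccessions = nAccessions, nSnps = 500L,
                                nChromosomes = 2L,
                                nMetabolites = nMetabolites,
                                targetH2 = targets[i],
                                nCausalPerMetabolite = 2L,
                                seed = seed + i * 101L)
        gset <- simulateGenotypes(cfg)
        sim <- simulateMetabolome(gset, cfg)
        panel <- log2MedianNormalize(sim$panel)
        h <- estimateHeritability(panel,
                                  structure = sim$truth$groupAssignment)
        data.frame(target = targets[i], mean_h2 = mean(h$h2, na.rm = TRUE),
                   sd_h2 = sd(h$h2, na.rm = TRUE),
                   n = sum(!is.na(h$h2)))
    })
    do.call(rbind, out)
}

## area under the precision-recall curve for a ranking (best first)
.prAuc <- function(rankedTruth) {
    tp <- cumsum(rankedTruth)
    prec <- tp / seq_along(rankedTruth)
    rec <- tp / max(sum(rankedTruth), 1)
    ## step-wise integration over recall
    sum(diff(c(0, rec)) * prec)
}

#' Network edge recovery study
#'
#' Samples accession-level data from a sparse random precision matrix
#' (node degree capped at 2, so the planted graph contains chains whose
#' indirect marginal correlations penalize zero-order ranking) and compares
#' edge recovery when ranking by the local FDR of the shrinkage partial
#' correlation versus ranking by zero-order |Spearman rho|, averaged over
#' `nReps` replicates.  The default magnitude 0.45 is the largest partial
#' correlation for which degree-2 nodes keep the precision matrix safely
#' positive definite.
#'
#' @param seed integer seed.
#' @param p number of compounds.
#' @param nEdges number of planted edges.
#' @param pcor planted partial-correlation magnitude.
#' @param n number of accessions.
#' @param nReps replicates averaged over (default 10).
#' @return list with `prAucFdr`, `prAucRho` (means over replicates),
#'   `perRep` (per-replicate AUCs), and the last replicate's `edges` table
#'   with truth flags.
#' @export
edgeRecoveryStudy <- function(seed = 1L, p = 20L, nEdges = 10L, pcor = 0.45,
                              n = 96L, nReps = 10L) {
    edges <- NULL
    perRep <- lapply(seq_len(nReps), function(r) {
        set.seed(seed + r * 7717L)
        net <- randomNetworkPrecision(p, nEdges, pcor)
        sigma <- chol2inv(chol(net$omega))
        x <- matrix(rnorm(n * p), n, p) %*% chol(sigma)
        colnames(x) <- sprintf("met%03d", seq_len(p))
        e <- networkEdges(t(x))
        truthKey <- paste(sprintf("met%03d", net$edges$i),
                          sprintf("met%03d", net$edges$j), sep = "|")
        eKey <- paste(e$compound_i, e$compound_j, sep = "|")
        e$true_edge <- eKey %in% truthKey
        edges <<- e
        byFdr <- e$true_edge[order(e$local_fdr, -abs(e$pcor))]
        byRho <- e$true_edge[order(-abs(e$rho))]
        data.frame(rep = r, prAucFdr = .prAuc(byFdr),
                   prAucRho = .prAuc(byRho))
    })
    perRep <- do.call(rbind, perRep)
    list(prAucFdr = mean(perRep$prAucFdr), prAucRho = mean(perRep$prAucRho),
         perRep = perRep, edges = edges)
}

#' Hotspot recovery and calibration study
#'
#' Runs the scaled end-to-end hotspot experiment: a structured panel with a
#' planted pleiotropic gene affecting `hotspotMetabolites` of
#' `nMetabolites` metabolites is simulated, accession means are estimated
#' from the replicated panel, the kinship-corrected scan, candidate
#' calling, permutation null and sliding-window hotspot detection are run,
#' and recovery (planted gene inside a reported hotspot) is recorded.  A
#' within-compound accession shuffle of the same means is pushed through
#' the identical path to count false hotspots under the null.
#'
#' @param nRuns independent replicates (default 25).
#' @param seed integer seed.
#' @param nPerm permutation rounds for the null threshold (default 8).
#' @param nSnps,nMetabolites,hotspotMetabolites,windowGenes scaled study
#'   dimensions.
#' @param effectSize planted allele effect (default 3 sd: a strong, clearly
#'   detectable signal, as appropriate for a recovery experiment).
#' @return list with `recoveryRate`, `nullHotspotsPerRun`, and `runs`
#'   (per-run data.frame: `recovered`, `n_hotspots`, `null_hotspots`,
#'   `null_max`).
#' @export
hotspotRecoveryStudy <- function(nRuns = 25L, seed = 1L, nPerm = 8L,
                                 nSnps = 2000L, nMetabolites = 30L,
                                 hotspotMetabolites = 12L,
                                 windowGenes = 10L, effectSize = 3) {
    runs <- lapply(seq_len(nRuns), function(r) {
        cfg <- simulationConfig(nAccessions = 96L, nSnps = nSnps,
                                nChromosomes = 5L, ldBlockLength = 10L,
                                nMetabolites = nMetabolites,
                                nCausalPerMetabolite = 1L,
                                effectSize = effectSize,
                                targetH2 = 0.6,
                                hotspotMetabolites = hotspotMetabolites,
                                networkEdges = 5L,
                                seed = seed + r * 1009L)
        gset <- mafFilter(simulateGenotypes(cfg), 0.05)
        sim <- simulateMetabolome(gset, cfg)
        panel <- log2MedianNormalize(sim$panel)
        means <- estimateAccessionMeans(panel)
        K <- kinshipMatrix(gset)
        s2g <- assignSnpsToGenes(gset)
        genes <- geneModels(gset)

        null <- permutationNull(means, gset, K = K, nPerm = nPerm,
                                windowGenes = windowGenes,
                                seed = seed + r * 2003L)
        assoc <- associationScan(means, gset, K = K)
        cand <- callCandidateGenes(assoc, s2g)
        hs <- suppressWarnings(
            slidingHotspots(cand, genes, windowGenes = windowGenes,
                            nullMax = null$nullMax))
        recovered <- nrow(hs) > 0 &&
            any(vapply(strsplit(hs$genes, ","),
                       function(g) sim$truth$hotspotGene %in% g, logical(1)))

        ## calibration: an independent within-compound shuffle through the
        ## identical path, judged against the same permutation threshold
        set.seed(seed + r * 4001L)
        shuf <- means
        for (i in seq_len(nrow(shuf)))
            shuf[i, ] <- shuf[i, sample.int(ncol(shuf))]
        assocN <- associationScan(shuf, gset, K = K)
        candN <- callCandidateGenes(assocN, s2g)
        hsN <- suppressWarnings(
            slidingHotspots(candN, genes, windowGenes = windowGenes,
                            nullMax = null$nullMax))
        data.frame(run = r, recovered = recovered, n_hotspots = nrow(hs),
                   null_hotspots = nrow(hsN), null_max = null$nullMax)
    })
    runs <- do.call(rbind, runs)
    list(recoveryRate = mean(runs$recovered),
         nullHotspotsPerRun = mean(runs$null_hotspots),
         runs = runs)
}
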