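## Synthetic-data module.
##
## Emulates the statistical structure the analysis assumes: ~96 inbred
## accessions in ~8 structure groups (Balding-Nichols allele-frequency
## divergence), LD-blocked biallelic SNPs generated by block-wise haplotype
## copying from a small founder pool per group, gene models tiled along each
## chromosome, and replicated log-normal metabolite ion counts with planted
## causal genes, an optional pleiotropic hotspot gene, a latent
## precision-matrix metabolite network, flat effects, run-batch median
## shifts, and residual noise.

.SIM_MUTATION  <- 0.02   # per-SNP flip probability after block copying
.SIM_HAP_DIFF  <- 0.8    # prob. a SNP differentiates the two base haplotypes
.SIM_SNP_SPACE <- 200L   # bp between consecutive SNPs
.SIM_GENE_STEP <- 2000L  # bp between consecutive gene starts
.SIM_GENE_LEN  <- 1600L  # gene width in bp

#' Simulation configuration
#'
#' Bundles and validates all knobs of the synthetic-data generator.  The
#' defaults describe the emulated study design: 96 inbred accessions in 8
#' structure groups, LD-blocked SNPs with a minor-allele-frequency floor,
#' two flats with two replicates each (four plants per accession), and
#' log-normal ion counts whose accession component is calibrated to a target
#' broad-sense heritability.
#'
#' `targetH2` is on the scale of the sum-of-squares heritability the analysis
#' estimates: the expected share of the total (corrected) sum of squares of a
#' metabolite attributable to accession differences within structure groups.
#' With few replicates this share has a design floor
#' `(nAccessions - nStructureGroups) / (N - 1)` under the null, which the
#' generator respects (targets below the floor yield a zero genetic
#' component).
#'
#' @param nAccessions number of inbred accessions.
#' @param nStructureGroups number of population-structure groups.
#' @param nSnps total SNPs before the MAF filter.
#' @param nChromosomes chromosomes the SNPs are spread over.
#' @param ldBlockLength SNPs per haplotype-copying block (1 = no LD).
#' @param mafMin minor-allele-frequency floor in (0, 0.5); SNPs at or below
#'   it are dropped after simulation.
#' @param fst Balding-Nichols divergence of group allele frequencies.
#' @param nMetabolites number of simulated compounds.
#' @param nCausalPerMetabolite causal genes planted per metabolite.
#' @param effectSize absolute allele-substitution effect (standard-deviation
#'   units of the latent scale) of each planted causal SNP.
#' @param targetH2 target broad-sense heritability in `[0, 1]` (see Details).
#' @param hotspotMetabolites number of metabolites affected by one planted
#'   pleiotropic hotspot gene (0 disables the hotspot).
#' @param networkEdges number of edges of the latent metabolite
#'   partial-correlation network.
#' @param networkPcor absolute partial correlation on those edges.
#' @param nFlats,nReplicates flats per experiment and replicates per flat
#'   (each accession contributes `nFlats * nReplicates` samples).
#' @param nRunBatches GC-TOF-MS run dates the samples are spread over.
#' @param batchShiftSd sd (log2 units) of the per-run-date median shift.
#' @param flatSd sd (log2 units) of flat effects.
#' @param residualSd residual sd in log2 units.
#' @param baselineLog2,baselineSd per-metabolite baseline abundance (log2
#'   units): mean and sd across metabolites.
#' @param detectionLimit ion counts strictly below this are recorded as
#'   missing (0 disables missingness).
#' @param experimentLabel experiment tag stored in the sample metadata.
#' @param seed integer seed; identical configs give identical outputs.
#' @return a validated `SimulationConfig` (a named list).
#' @export
simulationConfig <- function(nAccessions = 96L, nStructureGroups = 8L,
                             nSnps = 2000L, nChromosomes = 5L,
                             ldBlockLength = 10L, mafMin = 0.05, fst = 0.1,
                             nMetabolites = 100L, nCausalPerMetabolite = 2L,
                             effectSize = 1, targetH2 = 0.45,
                             hotspotMetabolites = 0L, networkEdges = 0L,
                             networkPcor = 0.3, nFlats = 2L, nReplicates = 2L,
                             nRunBatches = 4L, batchShiftSd = 0.5,
                             flatSd = 0.25, residualSd = 1,
                             baselineLog2 = 9, baselineSd = 1.5,
                             detectionLimit = 0, experimentLabel = "A",
                             seed = 1L) {
    cfg <- list(nAccessions = as.integer(nAccessions),
                nStructureGroups = as.integer(nStructureGroups),
                nSnps = as.integer(nSnps),
                nChromosomes = as.integer(nChromosomes),
                ldBlockLength = as.integer(ldBlockLength),
                mafMin = mafMin, fst = fst,
                nMetabolites = as.integer(nMetabolites),
                nCausalPerMetabolite = as.integer(nCausalPerMetabolite),
                effectSize = effectSize, targetH2 = targetH2,
                hotspotMetabolites = as.integer(hotspotMetabolites),
                networkEdges = as.integer(networkEdges),
                networkPcor = networkPcor,
                nFlats = as.integer(nFlats),
                nReplicates = as.integer(nReplicates),
                nRunBatches = as.integer(nRunBatches),
                batchShiftSd = batchShiftSd, flatSd = flatSd,
                residualSd = residualSd, baselineLog2 = baselineLog2,
                baselineSd = baselineSd, detectionLimit = detectionLimit,
                experimentLabel = experimentLabel, seed = as.integer(seed))
    class(cfg) <- "SimulationConfig"
    counts <- c("nAccessions", "nStructureGroups", "nSnps", "nChromosomes",
                "ldBlockLength", "nMetabolites", "nFlats", "nReplicates",
                "nRunBatches")
    for (nm in counts)
        if (is.na(cfg[[nm]]) || cfg[[nm]] < 1L)
            stop("invalid config: '", nm, "' must be a count >= 1")
    if (cfg$targetH2 < 0 || cfg$targetH2 > 1)
        stop("invalid config: 'targetH2' must lie in [0, 1]")
    if (cfg$mafMin <= 0 || cfg$mafMin >= 0.5)
        stop("invalid config: 'mafMin' must lie in (0, 0.5)")
    if (cfg$nSnps < cfg$nChromosomes)
        stop("invalid config: 'nSnps' must be >= 'nChromosomes'")
    if (cfg$nStructureGroups > cfg$nAccessions)
        stop("invalid config: more structure groups than accessions")
    cfg
}

#' Simulate structured, LD-blocked inbred genotypes
#'
#' Each LD block carries two base haplotypes whose ancestral frequency is
#' diverged into group-specific frequencies with a Balding-Nichols model of
#' strength `fst`; every accession copies one base haplotype per block
#' (drawn at its group's frequency) and accumulates rare per-SNP flips, so
#' within-block LD is strong and decays to the structure-induced background
#' between blocks.  SNPs that end up monomorphic or at minor allele
#' frequency `<= mafMin` are removed.  Gene models are tiled along each
#' chromosome.
#'
#' @param config a [simulationConfig()].
#' @return a [GenotypeSet] with the structure-group assignment in
#'   `metadata`-style attribute `attr(x, "groups")` (a named integer vector).
#' @export
simulateGenotypes <- function(config) {
    stopifnot(inherits(config, "SimulationConfig"))
    set.seed(config$seed)
    nA <- config$nAccessions
    nG <- config$nStructureGroups
    accs <- sprintf("acc%03d", seq_len(nA))
    groups <- setNames(rep_len(seq_len(nG), nA), accs)

    perChrom <- diff(round(seq(0, config$nSnps,
                               length.out = config$nChromosomes + 1)))
    chromNames <- paste0("Chr", seq_len(config$nChromosomes))
    genoList <- list(); snpChrom <- character(); snpPos <- integer()
    for (ci in seq_len(config$nChromosomes)) {
        m <- perChrom[ci]
        if (m == 0L) next
        pos <- .SIM_SNP_SPACE * seq_len(m)
        blocks <- split(seq_len(m),
                        (seq_len(m) - 1L) %/% config$ldBlockLength)
        G <- matrix(0L, nA, m)
        for (idx in blocks) {
            len <- length(idx)
            ## two base haplotypes per block; their ancestral frequency is
            ## diverged across structure groups Balding-Nichols style
            q0 <- runif(1, 0.15, 0.85)
            qg <- if (nG > 1L && config$fst > 0)
                rbeta(nG, q0 * (1 - config$fst) / config$fst,
                      (1 - q0) * (1 - config$fst) / config$fst)
            else rep(q0, nG)
            differ <- rbinom(len, 1L, .SIM_HAP_DIFF)
            pol <- rbinom(len, 1L, 0.5)        # which allele tags haplotype 1
            base <- rbinom(len, 1L, 0.5)       # shared background allele
            hap1 <- ifelse(differ == 1L, pol, base)
            hap0 <- ifelse(differ == 1L, 1L - pol, base)
            cls <- rbinom(nA, 1L, qg[groups])  # copied haplotype per accession
            G[, idx] <- matrix(rep(hap0, each = nA), nA)
            if (any(cls == 1L))
                G[cls == 1L, idx] <- matrix(rep(hap1, each = sum(cls == 1L)),
                                            sum(cls == 1L))
        }
        flips <- matrix(rbinom(length(G), 1L, .SIM_MUTATION), nrow = nA)
        G <- abs(G - flips)
        genoList[[ci]] <- G
        snpChrom <- c(snpChrom, rep(chromNames[ci], m))
        snpPos <- c(snpPos, pos)
    }
    G <- do.call(cbind, genoList)
    rownames(G) <- accs
    colnames(G) <- paste0(snpChrom, ":", snpPos)

    maf <- pmin(colMeans(G), 1 - colMeans(G))
    keep <- maf > config$mafMin
    G <- G[, keep, drop = FALSE]
    snpChrom <- snpChrom[keep]; snpPos <- snpPos[keep]
    snps <- GRanges(snpChrom, IRanges(snpPos, width = 1L))
    names(snps) <- colnames(G)

    genes <- .tileGenes(chromNames, perChrom)
    gset <- GenotypeSet(G, snps, genes)
    attr(gset, "groups") <- groups
    gset
}

.tileGenes <- function(chromNames, snpsPerChrom) {
    gr <- GRanges()
    for (ci in seq_along(chromNames)) {
        if (snpsPerChrom[ci] == 0L) next
        chromLen <- .SIM_SNP_SPACE * (snpsPerChrom[ci] + 1L)
        starts <- seq(1L, max(1L, chromLen - .SIM_GENE_LEN),
                      by = .SIM_GENE_STEP)
        g <- GRanges(chromNames[ci],
                     IRanges(starts, width = .SIM_GENE_LEN))
        names(g) <- sprintf("gene_%s_%03d", chromNames[ci], seq_along(g))
        gr <- suppressWarnings(c(gr, g))
    }
    gr
}

#' Random sparse precision-matrix network
#'
#' Builds a p x p positive-definite precision matrix whose implied partial
#' correlations are exactly `+/-pcor` on `nEdges` randomly chosen pairs and 0
#' elsewhere.  Positive definiteness is guaranteed by capping the degree of
#' each node at `floor(0.9 / pcor)` (diagonal dominance).
#'
#' @param p number of variables; `nEdges` edges; `pcor` absolute partial
#'   correlation on each edge.
#' @param pairs optional 2-column matrix of prescribed edges (overrides the
#'   random choice); signs are still drawn at random.
#' @return list with `omega` (precision matrix), `pcor` (true
#'   partial-correlation matrix, unit diagonal), `edges` (data.frame i, j,
#'   pcor).
#' @export
randomNetworkPrecision <- function(p, nEdges, pcor = 0.3, pairs = NULL) {
    stopifnot(p >= 2, pcor > 0, pcor < 1)
    omega <- diag(p)
    degCap <- max(1L, floor(0.9 / pcor))
    if (is.null(pairs)) {
        deg <- integer(p)
        pairs <- matrix(0L, 0, 2)
        all_pairs <- t(combn(p, 2))
        all_pairs <- all_pairs[sample.int(nrow(all_pairs)), , drop = FALSE]
        for (k in seq_len(nrow(all_pairs))) {
            if (nrow(pairs) >= nEdges) break
            i <- all_pairs[k, 1]; j <- all_pairs[k, 2]
            if (deg[i] < degCap && deg[j] < degCap) {
                pairs <- rbind(pairs, c(i, j))
                deg[i] <- deg[i] + 1L; deg[j] <- deg[j] + 1L
            }
        }
        if (nrow(pairs) < nEdges)
            warning("degree cap allowed only ", nrow(pairs), " of ",
                    nEdges, " requested edges")
    }
    signs <- sample(c(-1, 1), nrow(pairs), replace = TRUE)
    for (k in seq_len(nrow(pairs))) {
        i <- pairs[k, 1]; j <- pairs[k, 2]
        omega[i, j] <- omega[j, i] <- -signs[k] * pcor
    }
    pc <- -cov2cor(omega); diag(pc) <- 1
    edges <- data.frame(i = pairs[, 1], j = pairs[, 2],
                        pcor = signs * pcor)
    list(omega = omega, pcor = pc, edges = edges)
}

#' Simulate a replicated metabolite panel with a truth ledger
#'
#' Builds replicate-level log-normal ion counts on top of simulated
#' genotypes.  Per metabolite, the accession-level component is the sum of
#' planted causal-gene allele effects (plus the shared hotspot-gene effect
#' for affected metabolites) and a latent Gaussian draw from the specified
#' precision-matrix network; it is centered within structure groups and
#' scaled so its expected share of the total sum of squares equals
#' `targetH2` (see [simulationConfig()]).  Flat effects, per-run-date median
#' shifts and Gaussian residual noise are added on the log2 scale and values
#' exponentiated to the count scale; counts below `detectionLimit` become
#' missing.
#'
#' @param gset a [GenotypeSet] from [simulateGenotypes()].
#' @param config the same [simulationConfig()] used for the genotypes.
#' @return list with `panel` (a [MetabolitePanel], count scale) and `truth`
#'   (a `SimulationTruth` list: `causalMap` data.frame (metabolite, gene,
#'   snp, effect), `hotspotGene`, `trueH2`, `truePcor`, `groupAssignment`,
#'   and `accessionValues`, the metabolites x accessions matrix of latent
#'   genetic values).
#' @export
simulateMetabolome <- function(gset, config) {
    stopifnot(inherits(config, "SimulationConfig"), is(gset, "GenotypeSet"))
    set.seed(config$seed + 1000003L)
    accs <- accessionIds(gset)
    nA <- length(accs)
    p <- config$nMetabolites
    groups <- attr(gset, "groups")
    if (is.null(groups))
        groups <- setNames(rep_len(seq_len(config$nStructureGroups), nA), accs)
    mets <- sprintf("met%03d", seq_len(p))

    ## SNPs available inside genes (1 kb assignment window)
    s2g <- assignSnpsToGenes(gset)
    genesWithSnps <- unique(s2g$gene)
    if (config$nCausalPerMetabolite > 0 && length(genesWithSnps) == 0)
        stop("configuration error: no gene model contains a SNP")

    ## latent network component
    if (config$networkEdges > 0) {
        net <- randomNetworkPrecision(p, config$networkEdges,
                                      config$networkPcor)
        sigma <- chol2inv(chol(net$omega))
        Z <- matrix(rnorm(nA * p), nA, p) %*% chol(sigma)
        truePcor <- net$pcor
    } else {
        Z <- matrix(rnorm(nA * p), nA, p)
        truePcor <- diag(p)
    }
    dimnames(truePcor) <- list(mets, mets)

    ## planted causal genes (and one pleiotropic hotspot gene)
    G <- genotypeMatrix(gset)
    causal <- list()
    hotspotGene <- NA_character_
    if (config$hotspotMetabolites > 0) {
        if (config$hotspotMetabolites > p)
            stop("configuration error: more hotspot metabolites than metabolites")
        hotspotGene <- genesWithSnps[ceiling(length(genesWithSnps) / 4)]
    }
    genetic <- matrix(0, nA, p)
    for (mi in seq_len(p)) {
        genes_mi <- character(); snps_mi <- character(); eff_mi <- numeric()
        if (config$nCausalPerMetabolite > 0) {
            genes_mi <- sample(genesWithSnps,
                               min(config$nCausalPerMetabolite,
                                   length(genesWithSnps)))
            snps_mi <- vapply(genes_mi, function(g) {
                cand <- s2g$snp[s2g$gene == g]
                cand[ceiling(length(cand) / 2)]
            }, character(1))
            eff_mi <- sample(c(-1, 1), length(genes_mi), TRUE) *
                config$effectSize
        }
        if (!is.na(hotspotGene) && mi <= config$hotspotMetabolites) {
            hs_snp <- {
                cand <- s2g$snp[s2g$gene == hotspotGene]
                cand[ceiling(length(cand) / 2)]
            }
            genes_mi <- c(genes_mi, hotspotGene)
            snps_mi <- c(snps_mi, hs_snp)
            eff_mi <- c(eff_mi, sample(c(-1, 1), 1) * config$effectSize)
        }
        if (length(genes_mi)) {
            genetic[, mi] <- G[, snps_mi, drop = FALSE] %*% eff_mi
            causal[[mi]] <- data.frame(metabolite = mets[mi],
                                       gene = unname(genes_mi),
                                       snp = unname(snps_mi),
                                       effect = eff_mi)
        }
    }
    causalMap <- if (length(causal)) do.call(rbind, causal) else
        data.frame(metabolite = character(), gene = character(),
                   snp = character(), effect = numeric())

    ## accession component: center within structure groups, scale so the
    ## expected SS share equals targetH2 (design floor respected)
    nRep <- config$nFlats * config$nReplicates
    N <- nA * nRep
    Q <- nA - config$nStructureGroups
    sigmaE2 <- config$residualSd^2
    sAlphaTarget <- sigmaE2 * (config$targetH2 * (N - 1) - Q) /
        (nRep * (1 - config$targetH2 + 1e-12))
    sAlphaTarget <- max(0, sAlphaTarget)
    A <- genetic + Z
    gidx <- groups[accs]
    for (mi in seq_len(p)) {
        a <- A[, mi]
        a <- a - ave(a, gidx)               # within-group centering
        ss <- sum(a^2)
        A[, mi] <- if (ss > 1e-12 && sAlphaTarget > 0)
            a * sqrt(sAlphaTarget / ss) else 0
    }
    expectedH2 <- (Q * sigmaE2 + nRep * sAlphaTarget) /
        ((N - 1) * sigmaE2 + nRep * sAlphaTarget)
    rownames(A) <- accs; colnames(A) <- mets

    ## replicate-level design
    design <- expand.grid(replicate = seq_len(config$nReplicates),
                          flat = seq_len(config$nFlats),
                          accession = accs, stringsAsFactors = FALSE)
    nS <- nrow(design)
    design$flat <- sprintf("F%d", design$flat)
    batch <- sample(rep_len(seq_len(config$nRunBatches), nS))
    design$run_date <- sprintf("2009-05-%02d", batch)
    design$experiment <- config$experimentLabel
    design$sample_id <- sprintf("%s_%s_%s_r%d", design$accession,
                                design$experiment, design$flat,
                                design$replicate)

    baseline <- rnorm(p, config$baselineLog2, config$baselineSd)
    flatEff <- matrix(rnorm(config$nFlats * p, 0, config$flatSd),
                      config$nFlats, p)
    batchEff <- rnorm(config$nRunBatches, 0, config$batchShiftSd)

    accIdx <- match(design$accession, accs)
    flatIdx <- as.integer(sub("F", "", design$flat))
    Y <- matrix(rnorm(nS * p, 0, config$residualSd), nS, p)
    Y <- Y + A[accIdx, , drop = FALSE] + flatEff[flatIdx, , drop = FALSE]
    Y <- sweep(Y, 2, baseline, "+") + batchEff[batch]
    counts <- 2^Y
    if (config$detectionLimit > 0)
        counts[counts < config$detectionLimit] <- NA
    values <- t(counts)                       # compounds x samples
    rownames(values) <- mets
    colnames(values) <- design$sample_id

    panel <- MetabolitePanel(values, design[, c("accession", "experiment",
                                                "flat", "replicate",
                                                "run_date")],
                             scale = "count")
    truth <- list(causalMap = causalMap, hotspotGene = hotspotGene,
                  trueH2 = setNames(rep(expectedH2, p), mets),
                  truePcor = truePcor,
                  groupAssignment = groups,
                  accessionValues = t(A))
    class(truth) <- "SimulationTruth"
    list(panel = panel, truth = truth)
}

#' Simulate polygenic accession-level traits
#'
#' Accession-mean traits with a genome-wide polygenic genetic component
#' (every SNP contributes a small random effect), used to study mixed-model
#' calibration under population structure.  The genetic component is scaled
#' so its variance share across accessions equals `h2`.
#'
#' @param gset a [GenotypeSet].
#' @param nTraits number of traits; `h2` polygenic variance share in `[0,1)`;
#'   `seed` integer seed.
#' @param h2 polygenic background variance fraction.
#' @param seed random seed.
#' @return traits x accessions matrix.
#' @export
simulatePolygenicTraits <- function(gset, nTraits, h2 = 0.5, seed = 1L) {
    set.seed(seed)
    G <- genotypeMatrix(gset)
    Gs <- scale(G)
    Gs[is.na(Gs)] <- 0
    nA <- nrow(G)
    Y <- matrix(0, nTraits, nA, dimnames = list(sprintf("trait%03d",
                                                        seq_len(nTraits)),
                                                rownames(G)))
    for (i in seq_len(nTraits)) {
        u <- as.vector(Gs %*% rnorm(ncol(Gs))) / sqrt(ncol(Gs))
        u <- (u - mean(u)) / max(sd(u), 1e-12)
        Y[i, ] <- sqrt(h2) * u + sqrt(1 - h2) * rnorm(nA)
    }
    Y
}
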