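## End-to-end orchestration: declarative config, staged execution with
## dependency checks, per-stage manifests (parameters + input/output
## checksums) and a summary report.  Outputs are deterministic given config
## + seed, so re-running a stage reproduces identical file hashes.

.STAGES <- c("simulate", "preprocess", "quantgen", "network", "gwas",
             "genes", "hotspots", "ld", "enrich")

#' Default pipeline configuration
#'
#' A nested list with one section per stage plus a global `seed`; any field
#' can be overridden via `modifyList()` semantics or a YAML file read with
#' [readPipelineConfig()].  The defaults describe a small synthetic
#' two-experiment study suitable for smoke runs.
#'
#' @return nested configuration list.
#' @export
defaultPipelineConfig <- function() {
    list(seed = 1L,
         simulate = list(nAccessions = 48L, nStructureGroups = 4L,
                         nSnps = 600L, nChromosomes = 3L,
                         ldBlockLength = 10L, nMetabolites = 20L,
                         nCausalPerMetabolite = 1L, effectSize = 2,
                         targetH2 = 0.6, hotspotMetabolites = 8L,
                         networkEdges = 5L, networkPcor = 0.35,
                         experiments = c("A", "B")),
         preprocess = list(withinAccessionFraction = 0.5,
                           predominantFraction = 0.7, sampleFraction = 0.5,
                           target = 9),
         quantgen = list(),
         network = list(fdrCutoff = 0.2),
         gwas = list(minMaf = 0.05),
         genes = list(qCutoff = 0.2, minSnps = 2L, window = 1000L),
         hotspots = list(windowGenes = 10L, nPerm = 3L),
         ld = list(r2Threshold = 0.4),
         enrich = list(alpha = 0.05))
}

#' @rdname defaultPipelineConfig
#' @param path YAML file with (partial) pipeline configuration.
#' @export
readPipelineConfig <- function(path) {
    user <- yaml::read_yaml(path)
    cfg <- defaultPipelineConfig()
    for (nm in names(user)) {
        cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(user[[nm]]))
            utils::modifyList(cfg[[nm]], user[[nm]]) else user[[nm]]
    }
    cfg
}

.stageFile <- function(outDir, ...) file.path(outDir, paste0(...))

.needs <- function(outDir, stage, files) {
    missing <- files[!file.exists(file.path(outDir, files))]
    if (length(missing))
        stop("stage dependency missing: run stage '", stage,
             "' first (expected ", paste(missing, collapse = ", "), ")")
}

.writeManifest <- function(outDir, stage, params, inputs, outputs) {
    hash <- function(files) {
        h <- md5sum(file.path(outDir, files))
        names(h) <- files
        as.list(h)
    }
    manifest <- list(stage = stage,
                     package_version = as.character(packageVersion("metaboGWA")),
                     parameters = params,
                     inputs = hash(inputs), outputs = hash(outputs))
    jsonlite::write_json(manifest,
                         .stageFile(outDir, "manifest_", stage, ".json"),
                         auto_unbox = TRUE, pretty = TRUE)
}

.expts <- function(config) config$simulate$experiments

#' Run one pipeline stage
#'
#' Stages (in dependency order): `simulate`, `preprocess`, `quantgen`,
#' `network`, `gwas`, `genes`, `hotspots`, `ld`, `enrich`.  Each stage
#' reads its upstream outputs from `outDir`, writes its own TSV outputs
#' there plus a JSON manifest recording parameters and input/output MD5
#' checksums, and fails with an actionable message naming the missing
#' upstream stage otherwise.
#'
#' @param stage one of the stage names.
#' @param config configuration list (see [defaultPipelineConfig()]).
#' @param outDir run directory (created if needed).
#' @return invisibly, the character vector of files the stage wrote.
#' @export
runStage <- function(stage, config, outDir) {
    stage <- match.arg(stage, .STAGES)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    expts <- .expts(config)
    wrote <- switch(stage,
        simulate = .stageSimulate(config, outDir),
        preprocess = {
            .needs(outDir, "simulate", "panel.tsv")
            .stagePreprocess(config, outDir)
        },
        quantgen = {
            .needs(outDir, "preprocess",
                   paste0("processed_", expts, ".tsv"))
            .stageQuantgen(config, outDir)
        },
        network = {
            .needs(outDir, "quantgen", paste0("means_", expts, ".tsv"))
            .stageNetwork(config, outDir)
        },
        gwas = {
            .needs(outDir, "simulate", "genotypes.tsv")
            .needs(outDir, "quantgen", paste0("means_", expts, ".tsv"))
            .stageGwas(config, outDir)
        },
        genes = {
            .needs(outDir, "gwas", paste0("associations_", expts, ".tsv"))
            .stageGenes(config, outDir)
        },
        hotspots = {
            .needs(outDir, "genes", paste0("candidates_", expts, ".tsv"))
            .stageHotspots(config, outDir)
        },
        ld = {
            .needs(outDir, "genes", paste0("candidates_", expts, ".tsv"))
            .stageLd(config, outDir)
        },
        enrich = {
            .needs(outDir, "genes", paste0("candidates_", expts, ".tsv"))
            .needs(outDir, "simulate", "annotation.tsv")
            .stageEnrich(config, outDir)
        })
    invisible(wrote)
}

#' Run the full pipeline
#'
#' @param config configuration list or path to a YAML file.
#' @param outDir run directory.
#' @param stages stages to run, in order (default: all).
#' @return invisibly, `outDir`.
#' @export
runPipeline <- function(config = defaultPipelineConfig(), outDir,
                        stages = .STAGES) {
    if (is.character(config)) config <- readPipelineConfig(config)
    for (s in stages) {
        message("[metaboGWA] stage: ", s)
        runStage(s, config, outDir)
    }
    invisible(outDir)
}

.readGset <- function(outDir) {
    genes <- readGeneModelsBed(file.path(outDir, "genes.bed"))
    readGenotypesTsv(file.path(outDir, "genotypes.tsv"), genes = genes)
}

.readGroups <- function(outDir) {
    df <- read.table(file.path(outDir, "groups.tsv"), header = TRUE,
                     sep = "\t")
    setNames(df$group, df$accession)
}

.stageSimulate <- function(config, outDir) {
    p <- config$simulate
    expts <- p$experiments
    simArgs <- p[setdiff(names(p), "experiments")]
    simArgs$seed <- config$seed
    scfg <- do.call(simulationConfig, simArgs)
    gset <- simulateGenotypes(scfg)
    writeGenotypesTsv(gset, file.path(outDir, "genotypes.tsv"))
    writeGenotypesVcf(gset, file.path(outDir, "genotypes.vcf"))
    writeGeneModels(geneModels(gset), file.path(outDir, "genes.bed"),
                    file.path(outDir, "genes.gff3"))
    groups <- attr(gset, "groups")
    write.table(data.frame(accession = names(groups),
                           group = as.integer(groups)),
                file.path(outDir, "groups.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    panels <- list()
    wrote <- c("genotypes.tsv", "genotypes.vcf", "genes.bed", "genes.gff3",
               "groups.tsv")
    for (i in seq_along(expts)) {
        args <- simArgs
        args$experimentLabel <- expts[i]
        args$seed <- config$seed + i
        sim <- simulateMetabolome(gset, do.call(simulationConfig, args))
        panels[[i]] <- sim$panel
        writeTruthTsv(sim$truth,
                      file.path(outDir, paste0("truth_", expts[i], ".tsv")))
        wrote <- c(wrote, paste0("truth_", expts[i], ".tsv"))
    }
    ## one long-format table spanning all experiments
    combined <- do.call(cbind, lapply(panels, panelValues))
    meta <- do.call(rbind, lapply(panels, sampleData))
    writePanelTsv(MetabolitePanel(combined, meta),
                  file.path(outDir, "panel.tsv"))
    ## synthetic class annotation for the enrichment stage
    set.seed(config$seed)
    cmps <- rownames(panelValues(panels[[1]]))
    classes <- c("amino_acid", "carbohydrate", "fatty_acid", "hydroxy_acid",
                 "unknown")
    ann <- data.frame(compound_id = cmps,
                      class = sample(classes, length(cmps), replace = TRUE))
    write.table(ann, file.path(outDir, "annotation.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    wrote <- c(wrote, "panel.tsv", "annotation.tsv")
    .writeManifest(outDir, "simulate", config$simulate, character(), wrote)
    wrote
}

.stagePreprocess <- function(config, outDir) {
    p <- config$preprocess
    panel <- readPanelTsv(file.path(outDir, "panel.tsv"))
    processed <- preprocessPanel(panel,
                                 withinAccessionFraction = p$withinAccessionFraction,
                                 predominantFraction = p$predominantFraction,
                                 sampleFraction = p$sampleFraction,
                                 target = p$target)
    wrote <- character()
    for (e in names(processed)) {
        f <- paste0("processed_", e, ".tsv")
        writePanelTsv(processed[[e]], file.path(outDir, f))
        wrote <- c(wrote, f)
    }
    .writeManifest(outDir, "preprocess", p, "panel.tsv", wrote)
    wrote
}

.stageQuantgen <- function(config, outDir) {
    expts <- .expts(config)
    groups <- .readGroups(outDir)
    wrote <- character(); inputs <- character()
    cvs <- list()
    for (e in expts) {
        f <- paste0("processed_", e, ".tsv")
        inputs <- c(inputs, f)
        panel <- readPanelTsv(file.path(outDir, f), scale = "log2")
        herit <- estimateHeritability(panel, structure = groups)
        means <- estimateAccessionMeans(panel)
        cv <- geneticCV(means)
        writeWideMeans(means, file.path(outDir, paste0("means_", e, ".tsv")))
        write.table(herit, file.path(outDir,
                                     paste0("heritability_", e, ".tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        write.table(data.frame(compound = names(cv), cv = unname(cv)),
                    file.path(outDir, paste0("cv_", e, ".tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        wrote <- c(wrote, paste0(c("means_", "heritability_", "cv_"), e,
                                 ".tsv"))
    }
    .writeManifest(outDir, "quantgen", config$quantgen, inputs, wrote)
    wrote
}

.stageNetwork <- function(config, outDir) {
    expts <- .expts(config)
    p <- config$network
    nets <- list(); wrote <- character(); inputs <- character()
    for (e in expts) {
        f <- paste0("means_", e, ".tsv")
        inputs <- c(inputs, f)
        means <- readWideMeans(file.path(outDir, f))
        edges <- networkEdges(means)
        net <- buildNetwork(edges, fdrCutoff = p$fdrCutoff)
        nets[[e]] <- net
        writeEdgesTsv(edges, file.path(outDir, paste0("edges_", e, ".tsv")))
        writeGraphML(net$graph,
                     file.path(outDir, paste0("network_", e, ".graphml")))
        s <- net$summary
        write.table(data.frame(experiment = e, nodes = s$nodes,
                               edges = s$edges,
                               average_degree = s$averageDegree),
                    file.path(outDir, paste0("network_summary_", e, ".tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        wrote <- c(wrote, paste0(c("edges_", "network_", "network_summary_"),
                                 e, c(".tsv", ".graphml", ".tsv")))
    }
    if (length(nets) >= 2) {
        cmpr <- compareNetworks(nets[[1]], nets[[2]], nPerm = 200)
        write.table(cmpr$connectivity,
                    file.path(outDir, "network_comparison.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        write.table(cmpr$sharedEdges,
                    file.path(outDir, "network_shared_edges.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        wrote <- c(wrote, "network_comparison.tsv",
                   "network_shared_edges.tsv")
    }
    .writeManifest(outDir, "network", p, inputs, wrote)
    wrote
}

.stageGwas <- function(config, outDir) {
    expts <- .expts(config)
    gset <- mafFilter(.readGset(outDir), config$gwas$minMaf)
    K <- kinshipMatrix(gset)
    wrote <- character(); inputs <- "genotypes.tsv"
    for (e in expts) {
        f <- paste0("means_", e, ".tsv")
        inputs <- c(inputs, f)
        means <- readWideMeans(file.path(outDir, f))
        assoc <- associationScan(means, gset, K = K)
        out <- paste0("associations_", e, ".tsv")
        write.table(assoc, file.path(outDir, out), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        wrote <- c(wrote, out)
    }
    .writeManifest(outDir, "gwas", config$gwas, inputs, wrote)
    wrote
}

.stageGenes <- function(config, outDir) {
    expts <- .expts(config)
    p <- config$genes
    gset <- mafFilter(.readGset(outDir), config$gwas$minMaf)
    s2g <- assignSnpsToGenes(gset, window = p$window)
    wrote <- character(); inputs <- character()
    for (e in expts) {
        f <- paste0("associations_", e, ".tsv")
        inputs <- c(inputs, f)
        assoc <- read.table(file.path(outDir, f), header = TRUE, sep = "\t")
        cand <- callCandidateGenes(assoc, s2g, qCutoff = p$qCutoff,
                                   minSnps = p$minSnps)
        out <- paste0("candidates_", e, ".tsv")
        write.table(cand, file.path(outDir, out), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        wrote <- c(wrote, out)
    }
    .writeManifest(outDir, "genes", p, inputs, wrote)
    wrote
}

.stageHotspots <- function(config, outDir) {
    expts <- .expts(config)
    p <- config$hotspots
    g <- config$genes
    gset <- mafFilter(.readGset(outDir), config$gwas$minMaf)
    K <- kinshipMatrix(gset)
    wrote <- character(); inputs <- character()
    for (e in expts) {
        means <- readWideMeans(file.path(outDir, paste0("means_", e,
                                                        ".tsv")))
        cand <- read.table(file.path(outDir, paste0("candidates_", e,
                                                    ".tsv")),
                           header = TRUE, sep = "\t",
                           colClasses = "character")
        inputs <- c(inputs, paste0("candidates_", e, ".tsv"))
        null <- permutationNull(means, gset, K = K, nPerm = p$nPerm,
                                qCutoff = g$qCutoff, minSnps = g$minSnps,
                                window = g$window,
                                windowGenes = p$windowGenes,
                                seed = config$seed + 17L)
        hs <- suppressWarnings(
            slidingHotspots(cand, geneModels(gset),
                            windowGenes = p$windowGenes,
                            nullMax = null$nullMax))
        write.table(hs[, setdiff(names(hs), "genes")],
                    file.path(outDir, paste0("hotspots_", e, ".tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        writeHotspotsBed(hs, file.path(outDir, paste0("hotspots_", e,
                                                      ".bed")))
        write.table(null$perPermutation,
                    file.path(outDir, paste0("hotspot_null_", e, ".tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        wrote <- c(wrote, paste0(c("hotspots_", "hotspots_",
                                   "hotspot_null_"), e,
                                 c(".tsv", ".bed", ".tsv")))
    }
    .writeManifest(outDir, "hotspots", p, inputs, wrote)
    wrote
}

.stageLd <- function(config, outDir) {
    expts <- .expts(config)
    p <- config$ld
    gset <- mafFilter(.readGset(outDir), config$gwas$minMaf)
    s2g <- assignSnpsToGenes(gset, window = config$genes$window)
    collapsed <- collapseLoci(gset, s2g)
    wrote <- character(); inputs <- character()
    for (e in expts) {
        cand <- read.table(file.path(outDir, paste0("candidates_", e,
                                                    ".tsv")),
                           header = TRUE, sep = "\t",
                           colClasses = "character")
        inputs <- c(inputs, paste0("candidates_", e, ".tsv"))
        scr <- nonsyntenicLdScreen(cand, collapsed, geneModels(gset),
                                   r2Threshold = p$r2Threshold)
        write.table(scr$pairs,
                    file.path(outDir, paste0("ld_nonsyntenic_", e, ".tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        write.table(data.frame(experiment = e, q99 = scr$q99,
                               max = scr$max,
                               n_nonsyntenic = scr$nNonSyntenic),
                    file.path(outDir, paste0("ld_background_", e, ".tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        wrote <- c(wrote, paste0(c("ld_nonsyntenic_", "ld_background_"),
                                 e, ".tsv"))
    }
    .writeManifest(outDir, "ld", p, inputs, wrote)
    wrote
}

.stageEnrich <- function(config, outDir) {
    expts <- .expts(config)
    p <- config$enrich
    ann <- read.table(file.path(outDir, "annotation.tsv"), header = TRUE,
                      sep = "\t")
    classMap <- setNames(ann$class, ann$compound_id)
    wrote <- character(); inputs <- "annotation.tsv"
    meansList <- list()
    for (e in expts) {
        cand <- read.table(file.path(outDir, paste0("candidates_", e,
                                                    ".tsv")),
                           header = TRUE, sep = "\t",
                           colClasses = "character")
        inputs <- c(inputs, paste0("candidates_", e, ".tsv"))
        means <- readWideMeans(file.path(outDir, paste0("means_", e,
                                                        ".tsv")))
        meansList[[e]] <- means
        enr <- classEnrichment(cand, classMap, rownames(means))
        out <- paste0("enrichment_", e, ".tsv")
        write.table(enr, file.path(outDir, out), sep = "\t", quote = FALSE,
                    row.names = FALSE)
        wrote <- c(wrote, out)
    }
    if (length(meansList) >= 2) {
        da <- differentialAbundance(meansList[[1]], meansList[[2]],
                                    alpha = p$alpha)
        write.table(da, file.path(outDir, "differential_abundance.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        wrote <- c(wrote, "differential_abundance.tsv")
    }
    .writeManifest(outDir, "enrich", p, inputs, wrote)
    wrote
}

#' Summarize a completed pipeline run
#'
#' Collates per-stage outputs into a human-readable summary: counts per
#' stage, the hotspot table, network summaries, and the association-count
#' histograms (metabolites per gene-count bin, genes per metabolite-count
#' bin).  Incomplete runs yield a partial report with warnings.
#'
#' @param outDir a pipeline run directory.
#' @return a list of per-experiment summaries (class `metaboGWAReport`).
#' @export
pipelineReport <- function(outDir) {
    expts <- sub("^candidates_(.*)\\.tsv$", "\\1",
                 list.files(outDir, pattern = "^candidates_.*\\.tsv$"))
    if (!length(expts))
        warning("no candidate tables found; report will be partial")
    rpt <- list(directory = outDir, experiments = list())
    for (e in expts) {
        cand <- read.table(file.path(outDir, paste0("candidates_", e,
                                                    ".tsv")),
                           header = TRUE, sep = "\t",
                           colClasses = "character")
        genesPerMet <- if (nrow(cand)) table(table(cand$compound)) else
            table(integer())
        metsPerGene <- if (nrow(cand)) table(table(cand$gene)) else
            table(integer())
        hsFile <- file.path(outDir, paste0("hotspots_", e, ".tsv"))
        hs <- if (file.exists(hsFile))
            read.table(hsFile, header = TRUE, sep = "\t") else {
                warning("hotspot table missing for experiment ", e)
                NULL
            }
        nsFile <- file.path(outDir, paste0("network_summary_", e, ".tsv"))
        ns <- if (file.exists(nsFile))
            read.table(nsFile, header = TRUE, sep = "\t") else NULL
        rpt$experiments[[e]] <- list(
            nCandidateLinks = nrow(cand),
            nAssociatedMetabolites = length(unique(cand$compound)),
            nAssociatedGenes = length(unique(cand$gene)),
            genesPerMetabolite = genesPerMet,
            metabolitesPerGene = metsPerGene,
            hotspots = hs, networkSummary = ns)
    }
    class(rpt) <- "metaboGWAReport"
    rpt
}

#' @export
print.metaboGWAReport <- function(x, ...) {
    cat("metaboGWA pipeline report —", x$directory, "\n")
    for (e in names(x$experiments)) {
        s <- x$experiments[[e]]
        cat(sprintf("\nExperiment %s: %d candidate links (%d metabolites, %d genes)\n",
                    e, s$nCandidateLinks, s$nAssociatedMetabolites,
                    s$nAssociatedGenes))
        if (!is.null(s$hotspots))
            cat("  hotspots:", nrow(s$hotspots), "\n")
        if (!is.null(s$networkSummary))
            cat(sprintf("  network: %d nodes, %d edges (mean degree %.2f)\n",
                        s$networkSummary$nodes, s$networkSummary$edges,
                        s$networkSummary$average_degree))
        if (length(s$genesPerMetabolite)) {
            cat("  genes per metabolite:",
                paste(sprintf("%s gene(s): %s met", names(s$genesPerMetabolite),
                              as.integer(s$genesPerMetabolite)),
                      collapse = "; "), "\n")
        }
    }
    invisible(x)
}
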