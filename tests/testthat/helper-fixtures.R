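# Shared in-code fixtures for the test suite.

# A small panel with explicit metadata: nAcc accessions x (nFlats x nReps)
# samples per accession, values supplied by `fill(accession, flat, rep)`.
toyPanel <- function(nAcc = 3, nFlats = 2, nReps = 2, compounds = c("c1", "c2"),
                     fill = function(a, f, r) 2^9, batches = 1,
                     scale = "count") {
    accs <- paste0("a", seq_len(nAcc))
    design <- expand.grid(replicate = seq_len(nReps),
                          flat = paste0("F", seq_len(nFlats)),
                          accession = accs, stringsAsFactors = FALSE)
    design$experiment <- "A"
    design$run_date <- paste0("d", rep_len(seq_len(batches), nrow(design)))
    v <- matrix(NA_real_, length(compounds), nrow(design),
                dimnames = list(compounds,
                                paste0("s", seq_len(nrow(design)))))
    for (i in seq_len(nrow(design)))
        for (cmp in compounds)
            v[cmp, i] <- fill(design$accession[i], design$flat[i],
                              as.integer(design$replicate[i]))
    MetabolitePanel(v, design[, c("accession", "experiment", "flat",
                                  "replicate", "run_date")], scale = scale)
}

# Panel from an explicit compounds x samples matrix plus per-sample accession
panelFromMatrix <- function(values, accession,
                            run_date = rep("d1", ncol(values)),
                            flat = rep("F1", ncol(values)),
                            replicate = seq_len(ncol(values)),
                            experiment = rep("A", ncol(values)),
                            scale = "count") {
    info <- data.frame(accession = accession, experiment = experiment,
                       flat = flat, replicate = replicate,
                       run_date = run_date)
    rownames(info) <- colnames(values)
    MetabolitePanel(values, info, scale = scale)
}

# A tiny GenotypeSet from an explicit matrix and coordinates
toyGenotypes <- function(G, chrom, pos, genes = NULL) {
    colnames(G) <- paste0(chrom, ":", pos)
    snps <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L))
    names(snps) <- colnames(G)
    if (is.null(genes)) genes <- GenomicRanges::GRanges()
    GenotypeSet(G, snps, genes)
}

smallSimConfig <- function(...) {
    args <- utils::modifyList(
        list(nAccessions = 24L, nStructureGroups = 3L, nSnps = 200L,
             nChromosomes = 2L, ldBlockLength = 5L, nMetabolites = 6L,
             seed = 42L),
        list(...))
    do.call(simulationConfig, args)
}
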