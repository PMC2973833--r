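Package: metaboGWA
Title: Genome-Wide Association and Network Analysis of Plant Metabolomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for replicated untargeted metabolite profiles
    measured on a panel of inbred Arabidopsis thaliana accessions.  Covers
    ion-count preprocessing (presence filters, per-run-date log2 median
    normalization), broad-sense heritability and genetic coefficients of
    variation from a nested fixed-effects ANOVA, genetic metabolite-metabolite
    networks by shrinkage partial correlation with density-based local false
    discovery rates, kinship-corrected single-SNP mixed-model association
    scans with Storey q-values, gene-level candidate calling, sliding-window
    association hotspot detection calibrated by phenotype permutation, and
    gene-level (including non-syntenic) linkage-disequilibrium analysis.
    Includes a synthetic-data module that emulates the study design
    (structured inbred accessions, LD-blocked SNPs, replicated log-normal ion
    counts with planted causal genes, a pleiotropic hotspot gene, and a latent
    precision-matrix network) so every stage is testable without original
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    igraph,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
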