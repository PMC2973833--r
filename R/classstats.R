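## Cross-experiment differential abundance and metabolite class / pathway
## statistics on association results.

#' Paired differential abundance between two experiments
#'
#' Per compound detected in both experiments, a two-sample paired t-test
#' across the shared accessions, Bonferroni-corrected over the shared
#' compounds.  The differential flag requires both the adjusted p below
#' `alpha` and a greater-than-two-fold difference (fold computed as the
#' ratio of geometric means, i.e. `2^|mean log2 difference| > 2`).
#'
#' @param meansA,meansB compounds x accessions matrices of accession means
#'   (log2 units), paired by accession id.
#' @param alpha significance level on the Bonferroni-adjusted p (default
#'   0.05).
#' @param foldThreshold fold-difference threshold (default 2).
#' @return data.frame per shared compound: `compound`, `t`, `df`, `p`,
#'   `p_bonferroni`, `fold_difference` (B relative to A, count scale),
#'   `flag`.
#' @export
differentialAbundance <- function(meansA, meansB, alpha = 0.05,
                                  foldThreshold = 2) {
    cmps <- intersect(rownames(meansA), rownames(meansB))
    accs <- intersect(colnames(meansA), colnames(meansB))
    if (!length(cmps) || !length(accs))
        stop("no shared compounds or accessions between the two experiments")
    m <- length(cmps)
    out <- lapply(cmps, function(cmp) {
        d <- meansB[cmp, accs] - meansA[cmp, accs]
        d <- d[!is.na(d)]
        if (length(d) < 3)
            return(data.frame(compound = cmp, t = NA_real_, df = NA_real_,
                              p = NA_real_, p_bonferroni = NA_real_,
                              fold_difference = NA_real_, flag = NA))
        tt <- if (sd(d) > 1e-10 * max(1, abs(mean(d)))) t.test(d) else
            list(statistic = Inf * sign(mean(d)), parameter = length(d) - 1,
                 p.value = if (mean(d) == 0) 1 else 0)
        lfc <- mean(d)
        pb <- min(1, tt$p.value * m)
        data.frame(compound = cmp, t = unname(tt$statistic),
                   df = unname(tt$parameter), p = tt$p.value,
                   p_bonferroni = pb, fold_difference = 2^lfc,
                   flag = pb < alpha & abs(lfc) > log2(foldThreshold))
    })
    do.call(rbind, out)
}

#' Metabolite class over-representation among associated compounds
#'
#' Per class, a 2x2 Pearson chi-square test (1 df, no continuity
#' correction) of class membership against association with at least one
#' gene, over the compound universe.
#'
#' @param candidates candidate links from [callCandidateGenes()] (compounds
#'   with >= 1 link count as associated).
#' @param classMap named character vector: compound id -> class
#'   (unannotated compounds may be absent; they count towards the
#'   "unannotated" side only through the universe).
#' @param universe character vector of all tested compounds.
#' @return data.frame per class: `class`, `n_class`, `observed` (associated
#'   in class), `expected`, `chisq`, `p`, `unreliable` (TRUE when an
#'   expected cell is below 1).
#' @export
classEnrichment <- function(candidates, classMap, universe) {
    if (!all(unique(candidates$compound) %in% universe))
        stop("candidate compounds must be contained in the universe")
    assoc <- universe %in% unique(candidates$compound)
    cls <- classMap[universe]
    out <- lapply(sort(unique(cls[!is.na(cls)])), function(cl) {
        inClass <- !is.na(cls) & cls == cl
        tab <- table(factor(inClass, c(TRUE, FALSE)),
                     factor(assoc, c(TRUE, FALSE)))
        ch <- suppressWarnings(chisq.test(tab, correct = FALSE))
        data.frame(class = cl, n_class = sum(inClass),
                   observed = sum(inClass & assoc),
                   expected = unname(ch$expected[1, 1]),
                   chisq = unname(ch$statistic), p = ch$p.value,
                   unreliable = any(ch$expected < 1))
    })
    do.call(rbind, out)
}

#' Gene sharing within a metabolite class or pathway
#'
#' Counts the genes associated with at least two compounds of the group,
#' and compares the group's gene-association-count distribution (how many
#' group compounds each associated gene links to) against the distribution
#' over all compounds with a Pearson chi-square test on binned counts.
#'
#' @param candidates candidate links from [callCandidateGenes()].
#' @param classMap named character vector compound -> class (or use
#'   a pathway map restricted to one pathway).
#' @param group the class/pathway id to analyze.
#' @param maxBin counts are binned as 1, 2, ..., `maxBin`+ (default 3).
#' @return list with `sharedGenes` (gene ids linked to >= 2 group
#'   compounds), `nShared`, `chisq`, `p`, and `tables` (binned count
#'   distributions for the group and for all compounds).
#' @export
sharedGeneAnalysis <- function(candidates, classMap, group, maxBin = 3L) {
    groupCompounds <- names(classMap)[!is.na(classMap) & classMap == group]
    if (!length(groupCompounds))
        stop("group '", group, "' has no annotated compounds")
    inGroup <- candidates[candidates$compound %in% groupCompounds, ,
                          drop = FALSE]
    cntGroup <- table(inGroup$gene)
    cntAll <- table(candidates$gene)
    sharedGenes <- names(cntGroup)[cntGroup >= 2]
    binit <- function(cnt) {
        if (!length(cnt)) return(table(factor(integer(),
                                              levels = seq_len(maxBin))))
        table(factor(pmin(as.integer(cnt), maxBin), levels = seq_len(maxBin)))
    }
    tabGroup <- binit(cntGroup); tabAll <- binit(cntAll)
    ch <- if (sum(tabGroup) && sum(tabAll)) {
        suppressWarnings(chisq.test(rbind(all = as.integer(tabAll),
                                          group = as.integer(tabGroup))))
    } else list(statistic = NA_real_, p.value = NA_real_)
    list(sharedGenes = sharedGenes, nShared = length(sharedGenes),
         chisq = unname(ch$statistic), p = ch$p.value,
         tables = list(group = tabGroup, all = tabAll))
}
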