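## Preprocessing of replicate-level ion-count tables: per-accession presence
## filter, sample coverage filter against the predominant compound set, and
## log2 median normalization per GC-TOF-MS run date.  "Detected" means a
## non-missing, positive ion count.

#' Filter compounds by within-accession presence
#'
#' Retains a compound iff there is at least one accession in which it is
#' detected in strictly more than `withinAccessionFraction` of that
#' accession's samples.  Compound order is preserved.
#'
#' @param panel a [MetabolitePanel].
#' @param withinAccessionFraction strict detection-fraction threshold
#'   (default 0.5, i.e. "present in >50% of the samples per accession").
#' @return the filtered [MetabolitePanel].
#' @export
filterCompoundsByPresence <- function(panel, withinAccessionFraction = 0.5) {
    if (ncol(panel) == 0L || nrow(panel) == 0L)
        stop("empty panel: no samples or no compounds")
    det <- .detected(panel)
    acc <- as.character(colData(panel)$accession)
    accLevels <- unique(acc)
    ind <- vapply(accLevels, function(a) acc == a,
                  logical(ncol(panel)))          # samples x accessions
    detCount <- det %*% ind                      # compounds x accessions
    nSamp <- colSums(ind)
    frac <- sweep(detCount, 2, nSamp, "/")
    keep <- apply(frac > withinAccessionFraction, 1, any)
    panel[keep, ]
}

#' Filter samples by coverage of the predominant compounds
#'
#' First determines the predominant set: compounds detected in at least
#' `predominantFraction` of all samples.  Then retains the samples that
#' detect at least `sampleFraction` of that set.
#'
#' @param panel a [MetabolitePanel].
#' @param predominantFraction detection fraction (over all samples) defining
#'   a predominant compound (default 0.7).
#' @param sampleFraction fraction of the predominant set a sample must
#'   detect to be retained (default 0.5).
#' @return the filtered [MetabolitePanel].
#' @export
filterSamplesByCoverage <- function(panel, predominantFraction = 0.7,
                                    sampleFraction = 0.5) {
    if (nrow(panel) == 0L)
        stop("empty panel: no compounds")
    det <- .detected(panel)
    predominant <- rowMeans(det) >= predominantFraction
    if (!any(predominant)) {
        warning("predominant compound set is empty; all samples retained")
        return(panel)
    }
    cover <- colMeans(det[predominant, , drop = FALSE])
    panel[, cover >= sampleFraction]
}

#' Log2 transform and per-run-date median normalization
#'
#' Transforms ion counts to log2 and, within each run-date batch, subtracts
#' the batch median and adds `target`, so every batch's median equals
#' exactly `target` log2 units afterwards.
#'
#' @param panel a [MetabolitePanel] on the count scale; all retained values
#'   must be positive.
#' @param target the common post-normalization median (default 9 log2
#'   units).
#' @return a [MetabolitePanel] on the `"log2"` scale.
#' @export
log2MedianNormalize <- function(panel, target = 9) {
    if (valueScale(panel) != "count")
        stop("panel is already on the log2 scale")
    v <- panelValues(panel)
    bad <- which(!is.na(v) & v <= 0, arr.ind = TRUE)
    if (nrow(bad))
        stop(sprintf("nonpositive ion count for compound '%s' in sample '%s'",
                     rownames(v)[bad[1, 1]], colnames(v)[bad[1, 2]]))
    lv <- log2(v)
    batch <- as.character(colData(panel)$run_date)
    for (b in unique(batch)) {
        cols <- batch == b
        med <- median(lv[, cols], na.rm = TRUE)
        lv[, cols] <- lv[, cols] - med + target
    }
    out <- MetabolitePanel(lv, sampleData(panel), scale = "log2")
    metadata(out)$normalizationTarget <- target
    out
}

#' Full preprocessing pipeline, per experiment
#'
#' Applies, independently within each experiment: the compound presence
#' filter, then the sample coverage filter, then log2 median normalization.
#'
#' @param panel a [MetabolitePanel] (count scale), possibly spanning several
#'   experiments.
#' @param withinAccessionFraction,predominantFraction,sampleFraction,target
#'   passed to the three steps.
#' @return a named list of normalized [MetabolitePanel]s, one per
#'   experiment.
#' @export
preprocessPanel <- function(panel, withinAccessionFraction = 0.5,
                            predominantFraction = 0.7, sampleFraction = 0.5,
                            target = 9) {
    expts <- unique(as.character(colData(panel)$experiment))
    out <- lapply(expts, function(e) {
        sub <- panel[, as.character(colData(panel)$experiment) == e]
        sub <- filterCompoundsByPresence(sub, withinAccessionFraction)
        sub <- filterSamplesByCoverage(sub, predominantFraction,
                                       sampleFraction)
        log2MedianNormalize(sub, target)
    })
    names(out) <- expts
    out
}
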