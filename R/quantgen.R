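## Broad-sense heritability, adjusted accession means and genetic
## coefficients of variation from the replicated design.
##
## Heritability model (per compound, log2 values):
##   y ~ mu + S + F + A(S) + R(F) + e,   e ~ N(0, sigma_e^2)
## with S the structure group, F the flat, A the accession (nested in S) and
## R the replicate (nested in F).  H^2 is the type-II sum of squares of
## A(S) — computed by model comparison (full model vs the model dropping
## A(S)), which also handles unbalanced data — divided by the total
## corrected sum of squares.
##
## Accession means come from the same model without S: y ~ mu + F + A +
## R(F) + e; the adjusted mean of accession a is the model prediction for a
## averaged over the flat x replicate grid, which puts all accessions on a
## common, flat/replicate-adjusted scale.

#' Estimate broad-sense heritability per compound
#'
#' @param panel a normalized [MetabolitePanel] (log2 scale recommended).
#' @param structure named vector/factor mapping accession id to structure
#'   group.  If `NULL`, a single group is used (the model reduces to
#'   `y ~ F + A + R(F)`).
#' @return data.frame with one row per compound: `compound`, `h2`, the
#'   type-II accession sum of squares `ss_accession`, the sequential
#'   sums of squares of all model terms (`ss_structure`, `ss_flat`,
#'   `ss_accession_seq`, `ss_replicate`, `ss_residual`) and `ss_total`.
#'   Compounds whose model is rank deficient get `NA` with a warning.
#' @export
estimateHeritability <- function(panel, structure = NULL) {
    v <- panelValues(panel)
    meta <- sampleData(panel)
    acc <- factor(as.character(meta$accession))
    if (is.null(structure)) {
        grp <- factor(rep("S1", ncol(v)))
    } else {
        grp <- factor(as.character(structure[as.character(meta$accession)]))
        if (anyNA(grp))
            stop("'structure' does not cover all accessions in the panel")
    }
    flat <- factor(as.character(meta$flat))
    repl <- factor(as.character(meta$replicate))
    useS <- nlevels(grp) > 1L

    out <- lapply(rownames(v), function(cmp) {
        y <- v[cmp, ]
        ok <- !is.na(y)
        d <- data.frame(y = y[ok], S = droplevels(grp[ok]),
                        A = droplevels(acc[ok]), F = droplevels(flat[ok]),
                        R = droplevels(repl[ok]))
        res <- data.frame(compound = cmp, h2 = NA_real_,
                          ss_accession = NA_real_, ss_structure = NA_real_,
                          ss_flat = NA_real_, ss_accession_seq = NA_real_,
                          ss_replicate = NA_real_, ss_residual = NA_real_,
                          ss_total = NA_real_)
        if (nrow(d) < 3L || nlevels(d$A) < 2L) {
            warning("compound '", cmp, "': too few accessions or samples; NA")
            return(res)
        }
        nuisance <- .designTerms(d)
        withS <- nlevels(d$S) > 1L && useS
        flatTerm <- intersect("F", nuisance)
        replTerm <- setdiff(nuisance, "F")
        fullForm <- stats::reformulate(c(if (withS) "S", flatTerm, "A",
                                         replTerm), response = "y")
        redForm <- stats::reformulate(c(if (withS) "S", flatTerm, replTerm,
                                        "1"), response = "y")
        full <- lm(fullForm, data = d)
        if (full$df.residual < 1L) {
            warning("compound '", cmp, "': model is saturated; NA")
            return(res)
        }
        red <- lm(redForm, data = d)
        rssFull <- sum(full$residuals^2)
        ssA <- max(0, sum(red$residuals^2) - rssFull)
        ssTot <- sum((d$y - mean(d$y))^2)
        if (ssTot <= 0) {
            warning("compound '", cmp, "': zero total variance; NA")
            return(res)
        }
        tab <- anova(full)
        seqss <- setNames(tab$`Sum Sq`, rownames(tab))
        res$h2 <- ssA / ssTot
        res$ss_accession <- ssA
        res$ss_structure <- if ("S" %in% names(seqss)) seqss[["S"]] else 0
        res$ss_flat <- if ("F" %in% names(seqss)) seqss[["F"]] else 0
        res$ss_accession_seq <- seqss[["A"]]
        res$ss_replicate <- if ("F:R" %in% names(seqss)) seqss[["F:R"]] else 0
        res$ss_residual <- seqss[["Residuals"]]
        res$ss_total <- ssTot
        res
    })
    do.call(rbind, out)
}

#' Adjusted accession means per compound
#'
#' Fits `y ~ F + A + R(F)` per compound and reports, for every accession,
#' the model prediction averaged over the observed flat x replicate grid.
#' Accessions without data for a compound get `NA`.
#'
#' @param panel a normalized [MetabolitePanel].
#' @return compounds x accessions numeric matrix of adjusted genetic means
#'   (log2 units).
#' @export
estimateAccessionMeans <- function(panel) {
    v <- panelValues(panel)
    meta <- sampleData(panel)
    accAll <- sort(unique(as.character(meta$accession)))
    out <- matrix(NA_real_, nrow(v), length(accAll),
                  dimnames = list(rownames(v), accAll))
    for (cmp in rownames(v)) {
        y <- v[cmp, ]
        ok <- !is.na(y)
        if (!any(ok)) next
        d <- data.frame(y = y[ok],
                        A = factor(as.character(meta$accession)[ok]),
                        F = factor(as.character(meta$flat)[ok]),
                        R = factor(as.character(meta$replicate)[ok]))
        nuisance <- .designTerms(d)
        if (length(nuisance)) {
            fit <- lm(stats::reformulate(c("A", nuisance), response = "y"),
                      data = d)
            grid <- expand.grid(A = levels(d$A), F = levels(d$F),
                                R = levels(d$R))
            pred <- suppressWarnings(predict(fit, newdata = grid))
            m <- tapply(pred, grid$A, mean, na.rm = TRUE)
        } else {
            m <- tapply(d$y, d$A, mean)
        }
        out[cmp, names(m)] <- m
    }
    out
}

#' Genetic coefficient of variation
#'
#' Per compound, the standard deviation of the accession means divided by
#' their mean (sigma/mu), as a fraction.  Compounds whose mean is not
#' strictly positive get `NA` with a warning.
#'
#' @param means compounds x accessions matrix of accession means.
#' @param backTransform if `TRUE`, means are exponentiated (2^x) to the
#'   count scale before computing the CV.
#' @return named numeric vector of CVs (fractions).
#' @export
geneticCV <- function(means, backTransform = FALSE) {
    if (backTransform) means <- 2^means
    mu <- rowMeans(means, na.rm = TRUE)
    s <- apply(means, 1, sd, na.rm = TRUE)
    cv <- s / mu
    bad <- !is.na(mu) & mu <= 0
    if (any(bad)) {
        warning(sum(bad), " compound(s) with nonpositive mean; CV set to NA")
        cv[bad] <- NA_real_
    }
    cv
}

#' Compare two genetic-CV distributions on shared compounds
#'
#' @param cvA,cvB named per-compound CV vectors (e.g. one population each).
#' @return list with `fractionHigher` (share of shared compounds with
#'   `cvB > cvA`), `fractionAboveMax` (share of `cvB` exceeding
#'   `max(cvA)`), and `table`, the per-compound paired data.frame.
#' @export
compareCVDistributions <- function(cvA, cvB) {
    shared <- intersect(names(cvA), names(cvB))
    shared <- shared[!is.na(cvA[shared]) & !is.na(cvB[shared])]
    if (!length(shared))
        stop("no shared compounds between the two CV tables")
    a <- cvA[shared]; b <- cvB[shared]
    list(fractionHigher = mean(b > a),
         fractionAboveMax = mean(b > max(a)),
         table = data.frame(compound = shared, cv_a = unname(a),
                            cv_b = unname(b), higher_in_b = unname(b > a)))
}

## nuisance design terms that are actually estimable: flat, and replicate
## nested in flat (plain replicate when only one flat exists)
.designTerms <- function(d) {
    terms <- character()
    if (nlevels(d$F) > 1L) terms <- c(terms, "F")
    if (nlevels(d$R) > 1L)
        terms <- c(terms, if (nlevels(d$F) > 1L) "F:R" else "R")
    terms
}

#' Derive structure groups from a kinship matrix
#'
#' Hierarchical clustering (average linkage on 1 - kinship) cut into
#' `nGroups` groups; used when no external structure assignment is
#' available.
#'
#' @param K accession x accession kinship matrix.
#' @param nGroups number of groups (default 8).
#' @return named integer vector accession -> group.
#' @export
deriveStructureGroups <- function(K, nGroups = 8L) {
    hc <- hclust(as.dist(1 - K), method = "average")
    cutree(hc, k = min(nGroups, nrow(K)))
}
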