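## Kinship-corrected single-SNP association scans.
##
## Model per SNP s:  y = mu + x_s beta + u + e, with u ~ N(0, sigma_g^2 K)
## and e ~ N(0, sigma_e^2 I).  The variance ratio delta = sigma_e^2 /
## sigma_g^2 is estimated once per trait under the null (no-SNP) model by
## maximum likelihood via one spectral decomposition of K, a grid search
## over log delta in [-10, 10] refined by Brent optimization; per-SNP
## effects are then tested by a generalized-least-squares F test on
## (1, N - 2) df using the null-model variance components (the standard
## "population parameters previously determined" approximation).  With
## K = I the scan reduces exactly to ordinary least squares.

#' Minor-allele-frequency filter
#'
#' Retains SNPs whose minor allele frequency among non-missing accessions is
#' strictly greater than `minMaf`.
#'
#' @param gset a [GenotypeSet].
#' @param minMaf MAF threshold (default 0.05).
#' @return the filtered [GenotypeSet].
#' @export
mafFilter <- function(gset, minMaf = 0.05) {
    keep <- snpMaf(gset) > minMaf
    keep[is.na(keep)] <- FALSE
    .subsetSnps(gset, keep)
}

#' Identity-by-state kinship matrix
#'
#' Pairwise allele-sharing fraction over non-missing SNPs: the fraction of
#' SNPs at which two accessions carry the same (homozygous) allele.
#' Symmetric with unit diagonal and positive semidefinite.
#'
#' @param gset a [GenotypeSet] with at least 2 accessions and 1 SNP.
#' @return accession x accession kinship matrix.
#' @export
kinshipMatrix <- function(gset) {
    G <- genotypeMatrix(gset)
    if (nrow(G) < 2 || ncol(G) < 1)
        stop("need at least 2 accessions and 1 SNP")
    obs <- !is.na(G)
    G0 <- G; G0[!obs] <- 0
    G1 <- 1 - G; G1[!obs] <- 0
    nObs <- tcrossprod(obs * 1)
    if (any(nObs == 0))
        stop("accession pair(s) with no overlapping genotyped SNPs")
    K <- (tcrossprod(G0) + tcrossprod(G1)) / nObs
    dimnames(K) <- list(rownames(G), rownames(G))
    K
}

## Null-model ML fit of delta = sigma_e^2/sigma_g^2 for one trait.
## eig: eigen(K); returns delta, sigma_g^2, and the ML log-likelihood.
.emmaNull <- function(yt, onet, lam, gridLogDelta = seq(-10, 10,
                                                        length.out = 100)) {
    n <- length(yt)
    ll <- function(logDelta) {
        delta <- exp(logDelta)
        w <- 1 / (lam + delta)
        mu <- sum(w * onet * yt) / sum(w * onet^2)
        r <- yt - mu * onet
        sg2 <- sum(w * r^2) / n
        -0.5 * (n * log(2 * pi * sg2) + sum(log(lam + delta)) + n)
    }
    gridLL <- vapply(gridLogDelta, ll, numeric(1))
    best <- which.max(gridLL)
    lo <- gridLogDelta[max(1, best - 1)]
    hi <- gridLogDelta[min(length(gridLogDelta), best + 1)]
    opt <- optimize(ll, c(lo, hi), maximum = TRUE)
    if (opt$objective < max(gridLL) - 1e-6) {   # guard: refinement never worse
        opt <- list(maximum = gridLogDelta[best], objective = gridLL[best])
    }
    delta <- exp(opt$maximum)
    w <- 1 / (lam + delta)
    mu <- sum(w * onet * yt) / sum(w * onet^2)
    sg2 <- sum(w * (yt - mu * onet)^2) / n
    list(delta = delta, sigmaG2 = sg2, logLik = opt$objective,
         gridMax = max(gridLL))
}

#' Mixed-model single-SNP association scan for one trait
#'
#' @param y named numeric vector of per-accession trait values (no missing
#'   values; typically adjusted accession means), indexed by the accessions
#'   of `gset`.
#' @param gset a [GenotypeSet] (missing genotypes are mean-imputed per SNP).
#' @param K kinship matrix (defaults to [kinshipMatrix()] of `gset`); must
#'   be positive semidefinite.
#' @param eig optional precomputed `eigen(K, symmetric = TRUE)` (used by the
#'   multi-trait wrapper to avoid refactorizations).
#' @param Gt optional precomputed rotated genotype matrix `t(U) %*% G`.
#' @return data.frame per SNP: `snp`, `chrom`, `pos`, `beta`, `p`
#'   (monomorphic SNPs get `beta = 0`, `p = 1`); the fitted `delta` and
#'   `sigmaG2` are attached as attributes.
#' @export
emmaScan <- function(y, gset, K = NULL, eig = NULL, Gt = NULL) {
    accs <- accessionIds(gset)
    if (is.null(names(y))) {
        if (length(y) != length(accs))
            stop("'y' must be named by accession or match the accession count")
        names(y) <- accs
    }
    if (anyNA(y[accs])) stop("'y' has missing values for some accessions")
    y <- y[accs]
    if (is.null(K)) K <- kinshipMatrix(gset)
    K <- K[accs, accs]
    n <- length(y)
    if (is.null(eig)) {
        eig <- eigen(K, symmetric = TRUE)
        if (min(eig$values) < -1e-6 * max(abs(eig$values)))
            stop("kinship matrix is not positive semidefinite")
        eig$values <- pmax(eig$values, 0)
    }
    U <- eig$vectors; lam <- eig$values
    yt <- drop(crossprod(U, y))
    onet <- drop(crossprod(U, rep(1, n)))
    null <- .emmaNull(yt, onet, lam)
    w <- 1 / (lam + null$delta)
    if (is.null(Gt)) {
        G <- genotypeMatrix(gset)
        G <- .meanImpute(G)
        Gt <- crossprod(U, G)
    }
    a11 <- sum(w * onet^2)
    a1y <- sum(w * onet * yt)
    ayy <- sum(w * yt^2)
    a1x <- colSums(w * onet * Gt)
    axx <- colSums(w * Gt^2)
    axy <- colSums(w * Gt * yt)
    det <- a11 * axx - a1x^2
    mono <- det <= 1e-10 * a11 * pmax(axx, 1e-300)
    det[mono] <- 1
    beta <- (a11 * axy - a1x * a1y) / det
    b0 <- (axx * a1y - a1x * axy) / det
    rss1 <- pmax(ayy - b0 * a1y - beta * axy, 0)
    rss0 <- ayy - a1y^2 / a11
    Fstat <- pmax(rss0 - rss1, 0) / pmax(rss1 / (n - 2), 1e-300)
    p <- pf(Fstat, 1, n - 2, lower.tail = FALSE)
    p[mono] <- 1
    beta[mono] <- 0
    snps <- snpRanges(gset)
    out <- data.frame(snp = names(snps),
                      chrom = as.character(seqnames(snps)),
                      pos = start(snps), beta = beta, p = pmax(p, 1e-300),
                      row.names = NULL)
    attr(out, "delta") <- null$delta
    attr(out, "sigmaG2") <- null$sigmaG2
    out
}

.meanImpute <- function(G) {
    if (!anyNA(G)) return(G)
    mu <- colMeans(G, na.rm = TRUE)
    idx <- which(is.na(G), arr.ind = TRUE)
    G[idx] <- mu[idx[, 2]]
    G
}

#' Storey q-values
#'
#' The null proportion pi0 is estimated by the Storey smoother: pi0(lambda)
#' = #\{p > lambda\} / (m (1 - lambda)) over a lambda grid, smoothed with a
#' cubic spline and evaluated at the largest lambda.  Then q(i) is the
#' running minimum of pi0 * m * p(j) / rank(j) over p(j) >= p(i).  With
#' fewer than 20 p-values the Benjamini-Hochberg adjustment is used with a
#' warning (pi0 = 1).
#'
#' @param p vector of p-values in (0, 1].
#' @param lambdaGrid grid for the pi0 smoother (default 0.05..0.95).
#' @param pi0 optional fixed null proportion overriding the smoother.
#' @return list with `q` (same order as `p`) and `pi0`.
#' @export
qvalues <- function(p, lambdaGrid = seq(0.05, 0.95, by = 0.05), pi0 = NULL) {
    if (any(p <= 0 | p > 1, na.rm = TRUE))
        stop("p-values must lie in (0, 1]")
    m <- length(p)
    if (m < 20 && is.null(pi0)) {
        warning("fewer than 20 p-values; falling back to Benjamini-Hochberg")
        return(list(q = p.adjust(p, "BH"), pi0 = 1))
    }
    if (is.null(pi0)) {
        pi0l <- vapply(lambdaGrid,
                       function(l) mean(p > l, na.rm = TRUE) / (1 - l),
                       numeric(1))
        sp <- smooth.spline(lambdaGrid, pi0l, df = 3)
        pi0 <- predict(sp, max(lambdaGrid))$y
        pi0 <- min(1, max(pi0, 1 / m))
    }
    ord <- order(p, decreasing = TRUE)
    q <- rep(NA_real_, m)
    q[ord] <- cummin(pi0 * m * p[ord] / rank(p, ties.method = "max")[ord])
    list(q = pmin(q, 1), pi0 = pi0)
}

#' Multi-trait association scan with per-trait q-values
#'
#' Runs [emmaScan()] for every compound of a means matrix against all SNPs
#' of a MAF-filtered genotype set, sharing one spectral decomposition of the
#' kinship matrix and one rotated genotype matrix across traits, and
#' computes Storey q-values per compound (each compound's scan is its own
#' multiplicity family).
#'
#' @param means compounds x accessions matrix of accession means (rows with
#'   missing accession values are dropped with a warning).
#' @param gset a [GenotypeSet] (apply [mafFilter()] beforehand if desired).
#' @param K kinship matrix; computed from `gset` when `NULL`.
#' @return an association table: data.frame with `compound`, `snp`, `chrom`,
#'   `pos`, `beta`, `p`, `q`; per-compound `delta` and `pi0` as attribute
#'   `traitFits`.
#' @export
associationScan <- function(means, gset, K = NULL) {
    accs <- accessionIds(gset)
    if (!all(accs %in% colnames(means)))
        stop("means matrix does not cover all accessions in the genotype set")
    means <- means[, accs, drop = FALSE]
    complete <- !apply(is.na(means), 1, any)
    if (!all(complete)) {
        warning(sum(!complete), " compound(s) with missing accession means ",
                "dropped from the scan")
        means <- means[complete, , drop = FALSE]
    }
    if (is.null(K)) K <- kinshipMatrix(gset)
    K <- K[accs, accs]
    eig <- eigen(K, symmetric = TRUE)
    if (min(eig$values) < -1e-6 * max(abs(eig$values)))
        stop("kinship matrix is not positive semidefinite")
    eig$values <- pmax(eig$values, 0)
    G <- .meanImpute(genotypeMatrix(gset))
    Gt <- crossprod(eig$vectors, G)
    fits <- list()
    res <- lapply(rownames(means), function(cmp) {
        sc <- emmaScan(means[cmp, ], gset, K = K, eig = eig, Gt = Gt)
        qv <- qvalues(sc$p)
        fits[[cmp]] <<- c(delta = attr(sc, "delta"), pi0 = qv$pi0)
        data.frame(compound = cmp, sc, q = qv$q)
    })
    out <- do.call(rbind, res)
    attr(out, "traitFits") <- do.call(rbind, fits)
    out
}

#' Genomic inflation factor
#'
#' Median of the 1-df chi-square quantiles of the p-values divided by the
#' theoretical null median (0.4549).
#'
#' @param p vector of p-values.
#' @return the inflation factor (1 under a calibrated null).
#' @export
genomicInflation <- function(p) {
    p <- p[!is.na(p)]
    median(qchisq(p, df = 1, lower.tail = FALSE)) / qchisq(0.5, df = 1)
}
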