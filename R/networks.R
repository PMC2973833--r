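## Genetic metabolite-metabolite networks across accessions.
##
## Zero-order association is Spearman's rho with the usual t approximation
## t = rho * sqrt((n - 2) / (1 - rho^2)) on n - 2 df.  First-order structure
## is estimated by shrinkage partial correlation: the sample correlation
## matrix is shrunk towards the identity with the analytic
## Schafer-Strimmer intensity (lambda* = sum of estimated variances of the
## off-diagonal correlations over the sum of their squares), and partial
## correlations are the negative scaled inverse of the shrunk matrix.
## Edge significance uses a density-based local false discovery rate: a
## two-component mixture f(x) = eta0 f0(x; kappa) + (1 - eta0) fA(x), where
## f0 is the null density of a sample correlation with kappa degrees of
## freedom, fitted by censored maximum likelihood on the central part of
## the statistic distribution, and the mixture density f comes from a
## Grenander (monotone) estimator on |x|.

#' Spearman correlation matrix with t-approximation p-values
#'
#' @param means compounds x accessions matrix of accession means.
#' @return list with `rho` (pairwise-complete Spearman coefficients), `p`
#'   (two-sided p-values from the t reference distribution on n - 2 df; NA
#'   where fewer than 4 complete pairs), and `n` (pairwise complete counts).
#' @export
spearmanMatrix <- function(means) {
    x <- t(means)
    rho <- suppressWarnings(cor(x, method = "spearman",
                                use = "pairwise.complete.obs"))
    n <- crossprod(!is.na(x))
    tstat <- rho * sqrt(pmax(n - 2, 0) / pmax(1 - rho^2, 1e-300))
    p <- 2 * pt(abs(tstat), pmax(n - 2, 1), lower.tail = FALSE)
    p <- pmax(p, 1e-300)
    p[n < 4] <- NA
    rho[n < 4] <- NA
    diag(p) <- NA
    list(rho = rho, p = p, n = n)
}

#' Shrinkage partial correlation (Schafer-Strimmer)
#'
#' Estimates the correlation matrix (pairwise complete), shrinks it towards
#' the identity with the analytic intensity that minimizes the estimated
#' mean squared error, and converts to partial correlations via the
#' negative scaled inverse.  Constant (zero-variance) compounds are dropped
#' with a warning.  With `lambda = 0` (and a well-conditioned matrix) the
#' result equals the plain inverse-correlation partial correlation.
#'
#' @param means compounds x accessions matrix.
#' @param lambda optional fixed shrinkage intensity in `[0, 1]`; `NULL`
#'   (default) uses the analytic estimate.
#' @return list with `pcor` (partial correlations, unit diagonal),
#'   `lambda`, `r` (unshrunk correlations), and `n` (accessions used).
#' @export
shrinkagePartialCorrelation <- function(means, lambda = NULL) {
    x <- t(means)                              # accessions x compounds
    v <- apply(x, 2, var, na.rm = TRUE)
    if (any(constant <- (is.na(v) | v < 1e-12))) {
        warning(sum(constant), " constant compound(s) excluded from the ",
                "partial-correlation estimate")
        x <- x[, !constant, drop = FALSE]
    }
    p <- ncol(x)
    if (p < 2) stop("need at least 2 non-constant compounds")
    n <- nrow(x)
    xs <- scale(x)
    xs0 <- xs; xs0[is.na(xs0)] <- 0
    obs <- !is.na(xs)
    nmat <- crossprod(obs)
    S1 <- crossprod(xs0)                       # sum_k w_kij
    S2 <- crossprod(xs0^2)                     # sum_k w_kij^2
    R <- S1 / pmax(nmat - 1, 1)
    R[nmat < 3] <- 0
    diag(R) <- 1
    R <- pmin(pmax(R, -1), 1)
    if (is.null(lambda)) {
        varw <- (S2 - S1^2 / pmax(nmat, 1)) * nmat / pmax(nmat - 1, 1)^3
        off <- upper.tri(R)
        denom <- sum(R[off]^2)
        lambda <- if (denom > 0) sum(varw[off]) / denom else 1
        lambda <- min(1, max(0, lambda))
    }
    Rs <- (1 - lambda) * R
    diag(Rs) <- 1
    omega <- solve(Rs)
    pc <- -cov2cor(omega)
    diag(pc) <- 1
    dimnames(pc) <- list(colnames(x), colnames(x))
    list(pcor = pc, lambda = lambda, r = R, n = n)
}

## Null density of a sample correlation coefficient with kappa degrees of
## freedom: f0(x; kappa) = (1 - x^2)^((kappa - 3)/2) / B(1/2, (kappa - 1)/2)
.dcor0 <- function(x, kappa) {
    x <- pmin(abs(x), 1 - 1e-10)
    exp((kappa - 3) / 2 * log1p(-x^2) -
        lbeta(0.5, (kappa - 1) / 2))
}

## P(|r| <= q) under the null: r^2 ~ Beta(1/2, (kappa-1)/2)
.pcor0 <- function(q, kappa) pbeta(pmin(q, 1)^2, 0.5, (kappa - 1) / 2)

## Grenander estimator of a non-increasing density on [0, Inf): slopes of
## the least concave majorant of the empirical CDF of |x|.
.grenander <- function(absx) {
    n <- length(absx)
    s <- sort(absx)
    ux <- unique(s)
    Fy <- cumsum(tabulate(match(s, ux))) / n
    x <- c(0, ux)
    y <- c(0, Fy)
    ## least concave majorant via monotone (upper) chain: keep slopes
    ## strictly decreasing
    keep <- 1L
    for (i in 2:length(x)) {
        while (length(keep) >= 2) {
            k1 <- keep[length(keep) - 1]; k2 <- keep[length(keep)]
            s1 <- (y[k2] - y[k1]) / (x[k2] - x[k1])
            s2 <- (y[i] - y[k2]) / max(x[i] - x[k2], 1e-300)
            if (s2 >= s1) keep <- keep[-length(keep)] else break
        }
        keep <- c(keep, i)
    }
    kx <- x[keep]; ky <- y[keep]
    slopes <- diff(ky) / diff(kx)
    function(q) {
        idx <- findInterval(q, kx, rightmost.closed = FALSE,
                            all.inside = TRUE)
        pmax(slopes[pmin(idx, length(slopes))], 1e-10)
    }
}

#' Density-based local false discovery rate for correlation statistics
#'
#' Fits the two-component model `f(x) = eta0 f0(x; kappa) + (1 - eta0)
#' fA(x)`: the null degrees of freedom `kappa` are estimated by censored
#' maximum likelihood on the statistics whose absolute value lies below the
#' `censorQuantile` quantile (the central, predominantly null part), `eta0`
#' follows from the censored fraction, the mixture density is a Grenander
#' (monotone) estimate on `|x|`, and `fdr(x) = eta0 f0(x) / f(x)` is
#' clipped to `[0, 1]` and made monotone non-increasing in `|x|`.
#'
#' @param statistics numeric vector of per-edge correlation-scale statistics
#'   (partial correlations or Spearman coefficients); at least 50.
#' @param censorQuantile quantile of `|x|` used as censoring point for the
#'   null fit (default 0.75).
#' @return list with `fdr` (aligned with the input, `NA` preserved),
#'   `eta0` (estimated null proportion) and `kappa` (fitted null degrees of
#'   freedom).
#' @export
localFdr <- function(statistics, censorQuantile = 0.75) {
    out <- rep(NA_real_, length(statistics))
    ok <- !is.na(statistics)
    x <- statistics[ok]
    if (length(x) < 50)
        warning("fewer than 50 statistics; local FDR estimates are unstable")
    if (length(unique(x)) == 1L) {
        warning("all statistics are equal; local fdr set to 1")
        out[ok] <- 1
        return(list(fdr = out, eta0 = 1, kappa = NA_real_))
    }
    ax <- abs(x)
    x0 <- quantile(ax, censorQuantile, names = FALSE)
    if (x0 <= 0) x0 <- min(ax[ax > 0])
    cen <- ax[ax <= x0]
    nll <- function(logk) {
        k <- exp(logk) + 3
        -(sum(log(.dcor0(cen, k))) -
          length(cen) * log(max(.pcor0(x0, k), 1e-300)))
    }
    fit <- optimize(nll, c(log(1e-2), log(1e5)))
    kappa <- exp(fit$minimum) + 3
    eta0 <- min(1, (length(cen) / length(x)) / max(.pcor0(x0, kappa), 1e-300))
    fhat <- .grenander(ax)
    fdr <- pmin(1, eta0 * .dcor0(ax, kappa) / fhat(ax))
    ## enforce monotone non-increasing in |x|
    ord <- order(ax)
    fdr[ord] <- cummin(fdr[ord])
    out[ok] <- fdr
    list(fdr = out, eta0 = eta0, kappa = kappa)
}

#' Assemble the metabolite network edge table
#'
#' Computes, for every unordered compound pair: the Spearman coefficient and
#' its p-value, the shrinkage partial correlation, its sign, and the
#' density-based local FDR of the chosen statistic.  Compounds with less
#' than `minCoverage` non-missing accession means are excluded.
#'
#' @param means compounds x accessions matrix.
#' @param statistic statistic the local FDR is computed on: `"pcor"`
#'   (default, first-order network) or `"rho"` (zero-order network).
#' @param minCoverage minimum fraction of non-missing accessions (default
#'   0.5).
#' @return data.frame with columns `compound_i`, `compound_j` (i < j in
#'   compound order), `rho`, `rho_p`, `pcor`, `sign`, `local_fdr`; the
#'   shrinkage intensity and fitted null parameters are attached as
#'   attributes `lambda`, `eta0`, `kappa`.
#' @export
networkEdges <- function(means, statistic = c("pcor", "rho"),
                         minCoverage = 0.5) {
    statistic <- match.arg(statistic)
    cover <- rowMeans(!is.na(means))
    if (any(cover < minCoverage)) {
        means <- means[cover >= minCoverage, , drop = FALSE]
    }
    sp <- spearmanMatrix(means)
    pcfit <- shrinkagePartialCorrelation(means)
    ids <- rownames(pcfit$pcor)
    idx <- which(upper.tri(pcfit$pcor), arr.ind = TRUE)
    edges <- data.frame(compound_i = ids[idx[, 1]],
                        compound_j = ids[idx[, 2]],
                        rho = sp$rho[ids, ids][idx],
                        rho_p = sp$p[ids, ids][idx],
                        pcor = pcfit$pcor[idx])
    stat <- if (statistic == "pcor") edges$pcor else edges$rho
    fit <- localFdr(stat)
    edges$sign <- ifelse(stat >= 0, "+", "-")
    edges$local_fdr <- fit$fdr
    attr(edges, "lambda") <- pcfit$lambda
    attr(edges, "eta0") <- fit$eta0
    attr(edges, "kappa") <- fit$kappa
    edges
}

#' Threshold an edge table into a network and summarize it
#'
#' Retains edges with `local_fdr < fdrCutoff`; nodes are the compounds
#' incident to at least one retained edge.  Summaries follow the usual
#' network descriptors: average degree k = 2E/V, clustering coefficient per
#' degree C(k), and the degree distribution P(k).
#'
#' @param edges an edge table from [networkEdges()] (needs `local_fdr`).
#' @param fdrCutoff local FDR threshold (e.g. 0.05 or 0.20).
#' @return list with `summary` (list: `nodes`, `edges`, `averageDegree`,
#'   `Ck` data.frame, `Pk` data.frame), `edges` (retained rows) and `graph`
#'   (an [igraph::graph]).
#' @export
buildNetwork <- function(edges, fdrCutoff = 0.2) {
    keep <- !is.na(edges$local_fdr) & edges$local_fdr < fdrCutoff
    kept <- edges[keep, , drop = FALSE]
    g <- igraph::graph_from_data_frame(
        kept[, c("compound_i", "compound_j"), drop = FALSE],
        directed = FALSE)
    nV <- igraph::vcount(g); nE <- igraph::ecount(g)
    deg <- igraph::degree(g)
    locC <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
    Ck <- if (nV) aggregate(data.frame(C = locC), list(k = deg), mean) else
        data.frame(k = integer(), C = numeric())
    Pk <- if (nV) {
        tb <- table(deg)
        data.frame(k = as.integer(names(tb)),
                   P = as.numeric(tb) / nV)
    } else data.frame(k = integer(), P = numeric())
    list(summary = list(nodes = nV, edges = nE,
                        averageDegree = if (nV) 2 * nE / nV else 0,
                        Ck = Ck, Pk = Pk),
         edges = kept, graph = g)
}

#' Compare two metabolite networks
#'
#' Reports the edges shared between the two networks (identical unordered
#' compound pairs retained in both), their per-edge sign agreement, and
#' permutation p-values for differences in connectivity: average degree and
#' triad closure (local clustering) by two-sample permutation of the
#' node-level quantities across the two networks, and the degree
#' distributions by a two-sample Kolmogorov-Smirnov test.
#'
#' @param netA,netB outputs of [buildNetwork()].
#' @param nPerm permutation rounds (default 1000).
#' @return list with `sharedEdges` (data.frame pair + signs +
#'   `sign_agreement`), `nShared`, and `connectivity` (data.frame of
#'   statistic, observed difference A - B, p-value).
#' @export
compareNetworks <- function(netA, netB, nPerm = 1000) {
    key <- function(e) paste(pmin(e$compound_i, e$compound_j),
                             pmax(e$compound_i, e$compound_j), sep = "|")
    allCompounds <- union(c(netA$edges$compound_i, netA$edges$compound_j),
                          c(netB$edges$compound_i, netB$edges$compound_j))
    if (!length(allCompounds))
        stop("both networks are empty; nothing to compare")
    kA <- key(netA$edges); kB <- key(netB$edges)
    sharedK <- intersect(kA, kB)
    shared <- if (length(sharedK)) {
        a <- netA$edges[match(sharedK, kA), ]
        b <- netB$edges[match(sharedK, kB), ]
        data.frame(compound_i = a$compound_i, compound_j = a$compound_j,
                   sign_a = a$sign, sign_b = b$sign,
                   sign_agreement = a$sign == b$sign)
    } else data.frame(compound_i = character(), compound_j = character(),
                      sign_a = character(), sign_b = character(),
                      sign_agreement = logical())

    permTest <- function(a, b) {
        obs <- mean(a) - mean(b)
        pool <- c(a, b); nA <- length(a)
        if (!length(a) || !length(b)) return(c(obs = obs, p = NA))
        perm <- replicate(nPerm, {
            idx <- sample.int(length(pool), nA)
            mean(pool[idx]) - mean(pool[-idx])
        })
        c(obs = obs, p = (1 + sum(abs(perm) >= abs(obs) - 1e-12)) / (nPerm + 1))
    }
    degA <- igraph::degree(netA$graph); degB <- igraph::degree(netB$graph)
    triA <- igraph::transitivity(netA$graph, "localundirected",
                                 isolates = "zero")
    triB <- igraph::transitivity(netB$graph, "localundirected",
                                 isolates = "zero")
    d1 <- permTest(degA, degB)
    d2 <- permTest(triA, triB)
    ks <- if (length(degA) && length(degB))
        suppressWarnings(ks.test(degA, degB)) else list(statistic = NA, p.value = NA)
    list(sharedEdges = shared, nShared = nrow(shared),
         connectivity = data.frame(
             statistic = c("average_degree", "triad_closure",
                           "degree_distribution_ks"),
             difference = c(d1["obs"], d2["obs"], unname(ks$statistic)),
             p = c(d1["p"], d2["p"], ks$p.value)))
}
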