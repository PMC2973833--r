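test_that("Spearman matrix handles monotone, reversed and short inputs", {
    m <- rbind(x = 1:5, y = 5:1, z = c(2, 1, 4, 3, 5))
    sp <- spearmanMatrix(m)
    expect_equal(sp$rho["x", "z"], cor(m["x", ], m["z", ], method = "spearman"))
    expect_equal(sp$rho["x", "y"], -1)
    # fewer than 4 complete pairs -> NA
    m2 <- rbind(a = c(1, 2, 3, NA, NA), b = c(2, 1, NA, 4, 5))
    expect_true(is.na(spearmanMatrix(m2)$rho["a", "b"]))
})

test_that("Spearman p-values are uniform under the null", {
    set.seed(4)
    m <- matrix(rnorm(20 * 96), 20, 96,
                dimnames = list(paste0("m", 1:20), NULL))
    sp <- spearmanMatrix(m)
    ks <- suppressWarnings(ks.test(sp$p[upper.tri(sp$p)], "punif"))
    expect_gt(ks$p.value, 0.01)
})

test_that("lambda = 0 reproduces inverse-correlation partial correlations", {
    set.seed(2)
    x <- matrix(rnorm(5000), 1000, 5) %*% matrix(rnorm(25), 5)
    colnames(x) <- paste0("m", 1:5)
    pc <- shrinkagePartialCorrelation(t(x), lambda = 0)$pcor
    oracle <- -cov2cor(solve(cor(x)))
    diag(oracle) <- 1
    expect_lt(max(abs(pc - oracle)), 1e-10)
})

test_that("conditioning removes the indirect chain correlation", {
    set.seed(3)
    n <- 500
    X <- rnorm(n); Y <- X + rnorm(n); Z <- Y + rnorm(n)
    fit <- shrinkagePartialCorrelation(rbind(X = X, Y = Y, Z = Z))
    expect_gt(cor(X, Z), 0.3)
    expect_lt(abs(fit$pcor["X", "Z"]), 0.1)
    expect_gt(fit$pcor["X", "Y"], 0.3)
})

test_that("shrunk correlation matrix stays positive definite and symmetric", {
    set.seed(9)
    m <- matrix(rnorm(30 * 25), 30, 25,
                dimnames = list(paste0("m", 1:30), NULL))  # p > n
    fit <- shrinkagePartialCorrelation(m)
    expect_gt(fit$lambda, 0)
    expect_equal(fit$pcor, t(fit$pcor))
    expect_true(all(diag(fit$pcor) == 1))
    Rs <- (1 - fit$lambda) * fit$r; diag(Rs) <- 1
    expect_gt(min(eigen(Rs, symmetric = TRUE)$values), 0)
    # null data at p << n: partial correlations concentrate near zero
    set.seed(10)
    mn <- matrix(rnorm(20 * 96), 20, 96,
                 dimnames = list(paste0("m", 1:20), NULL))
    fn <- shrinkagePartialCorrelation(mn)
    offd <- abs(fn$pcor[upper.tri(fn$pcor)])
    expect_lt(quantile(offd, 0.95), 0.3)
})

test_that("constant compounds are excluded with a warning", {
    m <- rbind(a = rnorm(30), b = rnorm(30), const = rep(1, 30))
    expect_warning(fit <- shrinkagePartialCorrelation(m), "constant")
    expect_equal(rownames(fit$pcor), c("a", "b"))
})

test_that("local fdr handles degenerate and mixed inputs", {
    expect_warning(f0 <- localFdr(rep(0, 100)), "equal")
    expect_true(all(f0$fdr == 1))
    # recovery: eta0 = 0.9 mixture, alternative |pcor| = 0.6, 1000 edges
    set.seed(6)
    stats <- c(tanh(rnorm(900, 0, 1 / sqrt(93))),
               0.6 * sample(c(-1, 1), 100, TRUE) + rnorm(100, 0, 0.05))
    stats <- pmin(pmax(stats, -0.99), 0.99)
    fit <- localFdr(stats)
    expect_gte(fit$eta0, 0.8)
    expect_lte(fit$eta0, 1.0)
    # the largest |statistic| attains the smallest fdr
    expect_equal(which.min(fit$fdr), which.max(abs(stats)))
    # monotone non-increasing in |x| over the full output
    ord <- order(abs(stats))
    expect_true(all(diff(fit$fdr[ord]) <= 1e-12))
})

test_that("network summaries match hand-checked toy graphs", {
    tri <- data.frame(compound_i = c("a", "a", "b"),
                      compound_j = c("b", "c", "c"),
                      local_fdr = 0.01)
    net <- buildNetwork(tri, fdrCutoff = 0.05)
    expect_equal(net$summary$nodes, 3)
    expect_equal(net$summary$averageDegree, 2)
    expect_equal(net$summary$Ck$C, 1)          # closed triangle
    star <- data.frame(compound_i = "hub",
                       compound_j = paste0("leaf", 1:4),
                       local_fdr = 0.01)
    nets <- buildNetwork(star, fdrCutoff = 0.05)
    expect_equal(nets$summary$Ck$C[nets$summary$Ck$k == 4], 0)
    # strict cutoff: fdr at the threshold is not retained
    edge <- data.frame(compound_i = "a", compound_j = "b", local_fdr = 0.05)
    expect_equal(buildNetwork(edge, fdrCutoff = 0.05)$summary$edges, 0)
})

test_that("identical networks compare as indistinguishable", {
    set.seed(8)
    e <- data.frame(compound_i = c("a", "b", "c", "a"),
                    compound_j = c("b", "c", "d", "d"),
                    sign = c("+", "-", "+", "-"), local_fdr = 0.01)
    nA <- buildNetwork(e, 0.05)
    cmp <- compareNetworks(nA, nA, nPerm = 200)
    expect_equal(cmp$nShared, 4)
    expect_true(all(cmp$sharedEdges$sign_agreement))
    expect_true(all(cmp$connectivity$p[1:2] > 0.99))
    # opposite sign on a shared edge is reported as disagreement
    e2 <- e; e2$sign[1] <- "-"
    cmp2 <- compareNetworks(nA, buildNetwork(e2, 0.05), nPerm = 50)
    expect_false(all(cmp2$sharedEdges$sign_agreement))
})

test_that("zero-order networks are at least as dense as partial-correlation networks", {
    # data from a sparse chain-bearing precision matrix: marginal (rho)
    # correlations pick up the indirect edges that conditioning removes
    set.seed(19)
    net <- randomNetworkPrecision(25, 12, 0.45)
    x <- matrix(rnorm(96 * 25), 96, 25) %*% chol(chol2inv(chol(net$omega)))
    colnames(x) <- sprintf("m%02d", 1:25)
    means <- t(x)
    ePcor <- networkEdges(means, statistic = "pcor")
    eRho <- networkEdges(means, statistic = "rho")
    cutoff <- 0.2
    expect_gte(buildNetwork(eRho, cutoff)$summary$edges,
               buildNetwork(ePcor, cutoff)$summary$edges)
})
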