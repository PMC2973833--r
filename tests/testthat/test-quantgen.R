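test_that("zero residual noise with pure accession effects gives H2 = 1", {
    eff <- c(a1 = 1, a2 = 2, a3 = 5)
    panel <- toyPanel(nAcc = 3, fill = function(a, f, r) 2^eff[[a]],
                      scale = "count")
    panel <- MetabolitePanel(log2(panelValues(panel)), sampleData(panel),
                             scale = "log2")
    h <- suppressWarnings(estimateHeritability(panel))  # perfect-fit anova
    expect_equal(h$h2, rep(1, nrow(h)), tolerance = 1e-10)
})

test_that("sequential sums of squares decompose the total", {
    cfg <- smallSimConfig(nMetabolites = 5L, targetH2 = 0.5)
    sim <- simulateMetabolome(simulateGenotypes(cfg), cfg)
    panel <- log2MedianNormalize(sim$panel)
    h <- estimateHeritability(panel, structure = sim$truth$groupAssignment)
    lhs <- h$ss_structure + h$ss_flat + h$ss_accession_seq +
        h$ss_replicate + h$ss_residual
    expect_equal(lhs, h$ss_total, tolerance = 1e-8)
    # balanced design: type-II accession SS equals the sequential SS
    expect_equal(h$ss_accession, h$ss_accession_seq, tolerance = 1e-8)
    expect_true(all(h$h2 >= 0 & h$h2 <= 1))
})

test_that("H2 is shift invariant; the genetic CV is not", {
    cfg <- smallSimConfig(nMetabolites = 4L)
    sim <- simulateMetabolome(simulateGenotypes(cfg), cfg)
    panel <- log2MedianNormalize(sim$panel)
    shifted <- MetabolitePanel(panelValues(panel) + 3, sampleData(panel),
                               scale = "log2")
    h1 <- estimateHeritability(panel, sim$truth$groupAssignment)
    h2 <- estimateHeritability(shifted, sim$truth$groupAssignment)
    expect_equal(h1$h2, h2$h2, tolerance = 1e-8)
    cv1 <- geneticCV(estimateAccessionMeans(panel))
    cv2 <- geneticCV(estimateAccessionMeans(shifted))
    expect_true(all(abs(cv1 - cv2) > 1e-6))
})

test_that("null heritability shrinks towards the design floor as replicates grow", {
    # with pure noise the SS-ratio estimator concentrates at the analytic
    # floor (nAcc - nGroups) / (N - 1): 0.115 at 8 replicates, 0.23 at 4
    mk <- function(nReps, seed) {
        cfg <- simulationConfig(nAccessions = 96L, nSnps = 200L,
                                nChromosomes = 2L, nMetabolites = 40L,
                                targetH2 = 0, nFlats = 2L,
                                nReplicates = nReps %/% 2L, seed = seed)
        sim <- simulateMetabolome(simulateGenotypes(cfg), cfg)
        h <- estimateHeritability(log2MedianNormalize(sim$panel),
                                  sim$truth$groupAssignment)
        mean(h$h2, na.rm = TRUE)
    }
    m4 <- mk(4L, 21L)
    m8 <- mk(8L, 22L)
    expect_lt(m8, m4)
    expect_equal(m8, 88 / 767, tolerance = 0.25)
    expect_equal(m4, 88 / 383, tolerance = 0.25)
})

test_that("balanced designs reduce adjusted means to raw averages", {
    set.seed(5)
    vals <- new.env()
    panel <- toyPanel(nAcc = 4, nFlats = 1, nReps = 4, compounds = "c1",
                      fill = function(a, f, r) 2^rnorm(1, 9))
    m <- estimateAccessionMeans(panel)
    v <- panelValues(panel)
    acc <- sampleData(panel)$accession
    raw <- tapply(v["c1", ], acc, mean)
    expect_equal(unname(m["c1", names(raw)]), as.numeric(raw),
                 tolerance = 1e-10)
})

test_that("adjusted means remove a known additive flat offset", {
    # 2 accessions x 2 flats, one replicate, flat 2 offset +1 log2 unit
    base <- c(a1 = 3, a2 = 7)
    panel <- toyPanel(nAcc = 2, nFlats = 2, nReps = 1, compounds = "c1",
                      fill = function(a, f, r)
                          2^(base[[a]] + ifelse(f == "F2", 1, 0)))
    m <- estimateAccessionMeans(log2MedianNormalize(panel, target = 9))
    # hand solve: y(a, f) = mu_a + flat_f; adjusted difference = 4
    expect_equal(unname(m["c1", "a2"] - m["c1", "a1"]), 4,
                 tolerance = 1e-8)
})

test_that("adjusted means track the true genetic values", {
    cfg <- smallSimConfig(nAccessions = 96L, nMetabolites = 20L,
                          targetH2 = 0.8, nSnps = 300L)
    sim <- simulateMetabolome(simulateGenotypes(cfg), cfg)
    m <- estimateAccessionMeans(log2MedianNormalize(sim$panel))
    A <- sim$truth$accessionValues[, colnames(m)]
    cors <- vapply(rownames(m), function(cmp) cor(m[cmp, ], A[cmp, ]),
                   numeric(1))
    expect_gt(mean(cors), 0.9)
})

test_that("genetic CV follows the sigma/mu definition", {
    m <- rbind(c1 = c(8, 10, 12), c2 = c(5, 5, 5))
    cv <- geneticCV(m)
    expect_equal(unname(cv["c1"]), 2 / 10)       # sample sd with n-1
    expect_equal(unname(cv["c2"]), 0)
    expect_warning(cv2 <- geneticCV(rbind(neg = c(-2, -1, 0))),
                   "nonpositive")
    expect_true(is.na(cv2["neg"]))
})

test_that("CV distribution comparison counts orderings correctly", {
    cv <- setNames(runif(10, 0.1, 1), paste0("c", 1:10))
    same <- compareCVDistributions(cv, cv)
    expect_equal(same$fractionHigher, 0)
    expect_equal(same$fractionAboveMax, 0)
    dbl <- compareCVDistributions(cv, cv * 2)
    expect_equal(dbl$fractionHigher, 1)
    # toy table with known orderings vs brute-force counting
    cvB <- cv; cvB[1:4] <- cv[1:4] + 1; cvB[5:10] <- cv[5:10] - 0.05
    cmp <- compareCVDistributions(cv, cvB)
    expect_equal(cmp$fractionHigher, mean(cvB > cv))
    expect_equal(cmp$fractionAboveMax, mean(cvB > max(cv)))
    expect_error(compareCVDistributions(c(x = 1), c(y = 1)), "shared")
})

test_that("structure groups can be derived from kinship", {
    cfg <- smallSimConfig(nAccessions = 48L)
    gset <- simulateGenotypes(cfg)
    K <- kinshipMatrix(gset)
    grp <- deriveStructureGroups(K, nGroups = 3)
    expect_length(grp, 48L)
    expect_equal(length(unique(grp)), 3L)
})
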