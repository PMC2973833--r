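test_that("compound presence filter applies a strict per-accession rule", {
    # compound "all": detected everywhere -> retained
    # compound "half": detected in exactly 2 of 4 samples for every
    # accession (fraction exactly 0.5, strict threshold) -> removed
    panel <- toyPanel(nAcc = 3, nFlats = 2, nReps = 2,
                      compounds = c("all", "half"),
                      fill = function(a, f, r) 512)
    v <- panelValues(panel)
    half <- rep(c(NA, 512), length.out = ncol(v))
    v["half", ] <- half
    panel <- panelFromMatrix(v, sampleData(panel)$accession)
    out <- filterCompoundsByPresence(panel)
    expect_identical(compoundIds(out), "all")
})

test_that("compound filter matches brute-force per-accession counts", {
    # 3 accessions x 4 replicates x 5 compounds with a stated pattern
    set.seed(11)
    acc <- rep(paste0("a", 1:3), each = 4)
    v <- matrix(512, 5, 12, dimnames = list(paste0("c", 1:5),
                                            paste0("s", 1:12)))
    v[2, acc == "a1"] <- c(512, NA, NA, NA)     # 1/4 everywhere -> drop
    v[2, acc == "a2"] <- c(512, NA, NA, NA)
    v[2, acc == "a3"] <- c(512, NA, NA, NA)
    v[3, acc == "a1"] <- c(512, 512, 512, NA)   # 3/4 in a1 -> keep
    v[3, acc == "a2"] <- NA
    v[3, acc == "a3"] <- NA
    v[4, ] <- rep(c(512, 512, NA, NA), 3)       # exactly 1/2 -> drop
    v[5, acc != "a3"] <- NA                     # only a3, 4/4 -> keep
    panel <- panelFromMatrix(v, acc)
    out <- filterCompoundsByPresence(panel)

    # independent brute force: per accession detection fractions
    keep <- vapply(rownames(v), function(cmp) {
        any(vapply(unique(acc), function(a) {
            mean(!is.na(v[cmp, acc == a]) & v[cmp, acc == a] > 0) > 0.5
        }, logical(1)))
    }, logical(1))
    expect_identical(compoundIds(out), rownames(v)[keep])
    expect_identical(compoundIds(out), c("c1", "c3", "c5"))
})

test_that("sample coverage filter uses the predominant compound set", {
    # 10 compounds x 10 samples; compounds 1-6 predominant (detected in
    # >= 70% of samples), samples retained iff they detect >= 50% of them
    v <- matrix(512, 10, 10, dimnames = list(paste0("c", 1:10),
                                             paste0("s", 1:10)))
    v[7:10, 1:7] <- NA                  # rare compounds
    v[1:6, 1] <- NA                     # s1 detects 0/6 predominant
    v[1:4, 2] <- NA                     # s2 detects 2/6 -> dropped
    v[1:3, 3] <- NA                     # s3 detects 3/6 = 50% -> kept
    panel <- panelFromMatrix(v, paste0("a", 1:10))
    out <- filterSamplesByCoverage(panel)

    det <- !is.na(v) & v > 0
    predominant <- rowMeans(det) >= 0.7
    keep <- colMeans(det[predominant, ]) >= 0.5
    expect_identical(colnames(panelValues(out)), colnames(v)[keep])
    expect_false("s1" %in% colnames(panelValues(out)))
    expect_false("s2" %in% colnames(panelValues(out)))
    expect_true("s3" %in% colnames(panelValues(out)))
})

test_that("empty predominant set warns and retains all samples", {
    v <- matrix(c(512, NA, NA, NA, 512, NA, NA, NA, 512), 3, 3,
                dimnames = list(paste0("c", 1:3), paste0("s", 1:3)))
    panel <- panelFromMatrix(v, paste0("a", 1:3))
    expect_warning(out <- filterSamplesByCoverage(panel), "predominant")
    expect_identical(dim(out), dim(panel))
})

test_that("filters are idempotent", {
    cfg <- smallSimConfig(detectionLimit = 400, nMetabolites = 10L)
    sim <- simulateMetabolome(simulateGenotypes(cfg), cfg)
    f1 <- filterCompoundsByPresence(sim$panel)
    expect_identical(panelValues(filterCompoundsByPresence(f1)),
                     panelValues(f1))
    f2 <- filterSamplesByCoverage(f1)
    expect_identical(panelValues(filterSamplesByCoverage(f2)),
                     panelValues(f2))
})

test_that("log2 median normalization hits the target exactly", {
    # single batch, all counts 512 = 2^9 -> all values exactly 9
    p1 <- toyPanel(fill = function(a, f, r) 512)
    n1 <- log2MedianNormalize(p1)
    expect_true(all(panelValues(n1) == 9))
    expect_identical(valueScale(n1), "log2")

    # toy batch {2, 8, 32}: log2 {1,3,5}, median 3, shift +(9-3) -> {7,9,11}
    v <- matrix(c(2, 8, 32), 3, 1, dimnames = list(paste0("c", 1:3), "s1"))
    p2 <- panelFromMatrix(v, "a1")
    expect_equal(unname(panelValues(log2MedianNormalize(p2))[, 1]),
                 c(7, 9, 11))
})

test_that("normalization removes constant batch shifts", {
    # batch 2 counts exactly 4x batch 1 -> identical normalized matrices
    v1 <- matrix(2^runif(20, 5, 12), 5, 4,
                 dimnames = list(paste0("c", 1:5), paste0("s", 1:4)))
    v <- cbind(v1, 4 * v1)
    colnames(v) <- paste0("s", 1:8)
    panel <- panelFromMatrix(v, paste0("a", rep(1:4, 2)),
                             run_date = rep(c("d1", "d2"), each = 4))
    norm <- panelValues(log2MedianNormalize(panel))
    expect_equal(norm[, 1:4], norm[, 5:8], ignore_attr = TRUE)
    # per-batch median of normalized values equals the target exactly
    expect_equal(median(norm[, 1:4]), 9)
    expect_equal(median(norm[, 5:8]), 9)
})

test_that("nonpositive counts fail with sample and compound named", {
    v <- matrix(c(512, 0), 2, 1, dimnames = list(c("good", "bad"), "s9"))
    panel <- panelFromMatrix(v, "a1")
    expect_error(log2MedianNormalize(panel), "bad.*s9")
})

test_that("preprocessPanel composes the stages per experiment in order", {
    cfg <- smallSimConfig(detectionLimit = 300, nMetabolites = 12L)
    sim <- simulateMetabolome(simulateGenotypes(cfg), cfg)
    out <- preprocessPanel(sim$panel)
    expect_named(out, "A")
    manual <- log2MedianNormalize(
        filterSamplesByCoverage(filterCompoundsByPresence(sim$panel)))
    expect_identical(panelValues(out$A), panelValues(manual))
})
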