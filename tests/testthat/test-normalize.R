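test_that("fractional coverage normalizes each sample to sum 1", {
    x <- flatExperiment(twoGenePanel()[1:5], n = 10, depth = 100)
    fr <- fracMatrix(fractionalCoverage(x))
    expect_true(all(fr == 0.2))

    d <- depthMatrix(x)
    d[, 1] <- c(50, 50, 100, 0, 0)
    assay(x, "depth") <- d
    fr <- fracMatrix(fractionalCoverage(x))
    expect_equal(unname(fr[1:3, 1]), c(0.25, 0.25, 0.5))

    set.seed(4)
    for (i in 1:100) {
        m <- matrix(rexp(5 * 6, 1 / 100), 5, 6)
        sm <- data.frame(sample_id = paste0("s", 1:6), batch_id = "b",
                         sex = "female", phenotype = "HCM")
        fx <- fractionalCoverage(CnvExperiment(m, twoGenePanel()[1:5], sm))
        expect_equal(unname(colSums(fracMatrix(fx))), rep(1, 6),
                     tolerance = 1e-12)
    }
})

test_that("a sample with zero total depth is rejected by name", {
    x <- flatExperiment(twoGenePanel()[1:4], n = 5)
    d <- depthMatrix(x)
    d[, 3] <- 0
    assay(x, "depth") <- d
    expect_error(fractionalCoverage(x), "S03")
})

test_that("log2 ratios recover known copy-ratio shifts", {
    tg <- twoGenePanel()   # 39 targets: one aberrant exon barely moves the
    x <- flatExperiment(tg, n = 10, depth = 200)   # carrier's own total
    d <- depthMatrix(x)
    d[4, 1] <- 100   # 0.5x the batch median on one target
    d[7, 2] <- 300   # 1.5x
    assay(x, "depth") <- d
    l2 <- log2Matrix(log2Ratios(x))
    expect_equal(unname(l2[4, 1]), -1, tolerance = 0.05)
    expect_equal(unname(l2[7, 2]), log2(1.5), tolerance = 0.05)
    expect_lt(l2[4, 1], -0.55)   # loss-eligible
    expect_gt(l2[7, 2], 0.40)    # gain-eligible
    ## a sample exactly at the batch median scores 0
    expect_equal(unname(l2[1, 5]), 0, tolerance = 1e-12)
})

test_that("every unmasked target is median-centered within 1e-9", {
    sim <- simulateCohort(simConfig(n_batches = 3, batch_size = 10,
                                    n_targets = 80, seed = 7))
    x <- suppressWarnings(log2Ratios(fractionalCoverage(sim$experiment)))
    l2 <- log2Matrix(x)
    msk <- maskedMatrix(x)
    batch <- batchIds(x)
    sex <- sampleSex(x)
    sex_t <- as.character(seqnames(rowRanges(x))) %in% c("chrX", "chrY")
    for (b in unique(batch)) {
        for (t in seq_len(nrow(l2))) {
            cols <- which(batch == b & !msk[t, ])
            if (sex_t[t]) {
                for (sx in c("female", "male")) {
                    cc <- cols[sex[cols] == sx]
                    if (length(cc) >= 3)
                        expect_lt(abs(median(l2[t, cc])), 1e-9)
                }
            } else if (length(cols)) {
                expect_lt(abs(median(l2[t, cols])), 1e-9)
            }
        }
    }
})

test_that("log2 ratios are invariant to per-sample library scaling", {
    sim <- simulateCohort(simConfig(n_batches = 1, n_targets = 40, seed = 3))
    x <- sim$experiment
    l2a <- log2Matrix(suppressWarnings(log2Ratios(fractionalCoverage(x))))
    for (c_factor in c(0.01, 3.7, 1000)) {
        d <- depthMatrix(x)
        d[, 4] <- d[, 4] * c_factor
        x2 <- x
        assay(x2, "depth") <- d
        l2b <- log2Matrix(suppressWarnings(
            log2Ratios(fractionalCoverage(x2))))
        expect_equal(l2b[, 4], l2a[, 4], tolerance = 1e-12)
    }
})

test_that("raising one cell's depth never lowers its log2 ratio", {
    set.seed(21)
    sim <- simulateCohort(simConfig(n_batches = 1, n_targets = 30, seed = 9))
    x <- sim$experiment
    base <- log2Matrix(log2Ratios(fractionalCoverage(x)))
    for (i in 1:25) {
        t <- sample(nrow(x), 1)
        s <- sample(ncol(x), 1)
        d <- depthMatrix(x)
        d[t, s] <- d[t, s] * runif(1, 1, 3)
        x2 <- x
        assay(x2, "depth") <- d
        l2 <- log2Matrix(log2Ratios(fractionalCoverage(x2)))
        if (!is.na(l2[t, s]) && !is.na(base[t, s]))
            expect_gte(l2[t, s], base[t, s] - 1e-9)
    }
})

test_that("sex chromosomes are normalized within sex strata", {
    tg <- makeTargets(chrom = c(rep("chr1", 6), rep("chrX", 4)),
                      start = (0:9) * 1000, end = (0:9) * 1000 + 200,
                      gene = c(rep("A", 6), rep("GLA", 4)),
                      exon = c(1:6, 1:4))
    sm <- data.frame(sample_id = sprintf("s%d", 1:10), batch_id = "b1",
                     sex = rep(c("female", "male"), each = 5),
                     phenotype = "HCM")
    d <- matrix(100, 10, 10)
    d[7:10, 6:10] <- 50   # males: one X copy
    x <- log2Ratios(fractionalCoverage(CnvExperiment(d, tg, sm)))
    l2 <- log2Matrix(x)
    ## males are not called as X-deletion carriers: their stratum median is
    ## their own level
    expect_true(all(abs(l2[7:10, ]) < 1e-9, na.rm = TRUE))
    expect_true(all(!maskedMatrix(x)))
})

test_that("undersized sex strata and unknown sex are masked with a warning", {
    tg <- makeTargets(chrom = c(rep("chr1", 4), rep("chrX", 2)),
                      start = (0:5) * 1000, end = (0:5) * 1000 + 200,
                      gene = c(rep("A", 4), rep("GLA", 2)),
                      exon = c(1:4, 1:2))
    sm <- data.frame(sample_id = sprintf("s%d", 1:6), batch_id = "b1",
                     sex = c(rep("female", 4), "male", "unknown"),
                     phenotype = "HCM")
    x <- CnvExperiment(matrix(100, 6, 6), tg, sm)
    expect_warning(x <- log2Ratios(fractionalCoverage(x)), "< 3 samples")
    msk <- maskedMatrix(x)
    expect_true(all(msk[5:6, 5]))       # lone male masked on X
    expect_true(all(msk[5:6, 6]))       # unknown sex masked on X
    expect_false(any(msk[1:4, ]))       # autosomes untouched
    expect_true(all(!msk[5:6, 1:4]))    # female stratum (n=4) normalized
})

test_that("capture dropouts are masked, not called", {
    tg <- twoGenePanel()[1:6]
    x <- flatExperiment(tg, n = 8)
    d <- depthMatrix(x)
    d[3, ] <- 0   # dead target across the whole batch
    assay(x, "depth") <- d
    x <- log2Ratios(fractionalCoverage(x))
    expect_true(all(maskedMatrix(x)[3, ]))
    expect_true(all(is.na(log2Matrix(x)[3, ])))
    expect_identical(nrow(callCNVs(x)), 0L)
})
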