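test_that("simulation is bit-reproducible from its seed", {
    cfg <- simConfig(n_batches = 2, n_targets = 60, n_events = 5, seed = 123)
    a <- simulateCohort(cfg)
    b <- simulateCohort(cfg)
    expect_identical(depthMatrix(a$experiment), depthMatrix(b$experiment))
    expect_identical(a$truth, b$truth)
    c <- simulateCohort(simConfig(n_batches = 2, n_targets = 60,
                                  n_events = 5, seed = 124))
    expect_false(identical(depthMatrix(a$experiment),
                           depthMatrix(c$experiment)))
})

test_that("a noiseless null cohort normalizes to all-zero log2 ratios", {
    sim <- simulateCohort(simConfig(n_batches = 2, n_targets = 50,
                                    noise_sd = 0, seed = 1))
    x <- suppressWarnings(log2Ratios(fractionalCoverage(sim$experiment)))
    l2 <- log2Matrix(x)
    expect_true(all(abs(l2[!maskedMatrix(x)]) < 1e-9))
    expect_identical(nrow(callCNVs(x)), 0L)
})

test_that("noiseless injected events land at their analytic log2 ratio", {
    ## het deletion: log2 ratio is -1 plus the renormalization shift from
    ## the event's own weight in the carrier's total
    ev <- data.frame(sample = 1L, first_target = 10L, last_target = 12L,
                     copy_number = 1L)
    sim <- simulateCohort(simConfig(n_batches = 1, n_targets = 50,
                                    noise_sd = 0, events = ev, seed = 2))
    x <- suppressWarnings(log2Ratios(fractionalCoverage(sim$experiment)))
    l2 <- log2Matrix(x)
    d <- depthMatrix(sim$experiment)
    eps <- cnvThresholds()@pseudofrac
    ## closed form: carrier fraction over the (all-identical) null fraction
    expected <- log2((d[11:13, 1] / sum(d[, 1]) + eps) /
                     (d[11:13, 2] / sum(d[, 2]) + eps))
    expect_equal(unname(l2[11:13, 1]), unname(expected), tolerance = 1e-9)
    expect_equal(unname(l2[11:13, 1]), rep(-1, 3), tolerance = 0.05)
    calls <- callCNVs(x)
    expect_identical(calls$direction, "loss")
    expect_identical(calls$first_target, 10L)
    expect_identical(calls$last_target, 12L)
})

test_that("a noiseless female X trisomy scores log2(1.5) under sex-aware
           normalization", {
    sim <- simulateCohort(simConfig(n_batches = 1, batch_size = 10,
                                    n_targets = 50, noise_sd = 0,
                                    sex_ratio = 1, seed = 3))
    x <- sim$experiment
    on_x <- as.character(seqnames(rowRanges(x))) == "chrX"
    xo <- genomeOrder(x)[on_x]
    x <- injectEvent(x, "S0001", min(xo), max(xo), copyNumber = 3)
    l2 <- log2Matrix(log2Ratios(fractionalCoverage(x)))
    ## analytic value: log2(1.5) minus the carrier-total renormalization
    d <- depthMatrix(x)
    eps <- cnvThresholds()@pseudofrac
    frac_ref <- d[on_x, 2] / sum(d[, 2])
    frac_car <- d[on_x, 1] / sum(d[, 1])
    expect_equal(unname(l2[on_x, 1]),
                 unname(log2((frac_car + eps) / (frac_ref + eps))),
                 tolerance = 1e-9)
    ## within the renormalization shift bound of the idealized log2(3/2)
    expect_true(all(abs(l2[on_x, 1] - log2(1.5)) < 0.1))
    calls <- callCNVs(log2Ratios(fractionalCoverage(x)))
    xcall <- calls[calls$chrom == "chrX", ]
    expect_identical(nrow(xcall), 1L)
    expect_identical(xcall$direction, "gain")
    expect_identical(xcall$span_kind, "multi_gene")
})

test_that("event injection scales exactly the affected cells", {
    sim <- simulateCohort(simConfig(n_batches = 1, n_targets = 40, seed = 5))
    x <- sim$experiment
    d0 <- depthMatrix(x)
    ## neutral copy number leaves the matrix bit-identical
    x2 <- injectEvent(x, "S0002", 5, 8, copyNumber = 2)
    expect_identical(depthMatrix(x2), d0)
    ## homozygous deletion zeroes the span
    x0 <- injectEvent(x, "S0003", 5, 8, copyNumber = 0)
    expect_true(all(depthMatrix(x0)[6:9, 3] == 0))
    expect_identical(depthMatrix(x0)[-(6:9), ], d0[-(6:9), ])
    ## two-fold gain quadruples nothing and doubles the span
    x4 <- injectEvent(x, "S0004", 5, 8, copyNumber = 4)
    expect_equal(depthMatrix(x4)[6:9, 4], d0[6:9, 4] * 2)
    ## overlapping injections on one sample are refused
    expect_error(injectEvent(x4, "S0004", 8, 9, copyNumber = 1),
                 "overlapping")
    ## spans outside the panel are refused
    expect_error(injectEvent(x, "S0001", 35, 45, copyNumber = 1),
                 "outside")
})

test_that("planted artifact loci appear at about their population frequency", {
    art <- list(list(first_target = 20L, n_targets = 3L, frequency = 0.05,
                     copy_number = 1L))
    sim <- simulateCohort(simConfig(n_batches = 40, n_targets = 60,
                                    artifact_loci = art, seed = 8))
    carriers <- sum(sim$truth$is_artifact)
    expect_gt(carriers, 5)       # 400 samples at 5%: ~20 expected
    expect_lt(carriers, 45)
    expect_true(all(sim$truth$copy_number[sim$truth$is_artifact] == 1))
})

test_that("the null false-call rate stays below 0.05 calls per sample", {
    sim <- simulateCohort(simConfig(n_batches = 20, batch_size = 10,
                                    n_targets = 500, noise_sd = 0.1,
                                    seed = 17))
    x <- suppressWarnings(log2Ratios(fractionalCoverage(sim$experiment)))
    calls <- callCNVs(x)
    expect_lt(nrow(calls) / ncol(x), 0.05)
})
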