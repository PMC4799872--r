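test_that("a multi-exon deletion becomes one intragenic loss call", {
    x <- flatExperiment(twoGenePanel(), n = 10, depth = 200)
    d <- depthMatrix(x)
    d[12:20, 1] <- 100    # MYBPC3 exons 12-20 at half depth
    assay(x, "depth") <- d
    calls <- callCNVs(log2Ratios(fractionalCoverage(x)))
    expect_identical(nrow(calls), 1L)
    expect_identical(calls$sample_id, "S01")
    expect_identical(calls$direction, "loss")
    expect_identical(calls$n_targets, 9L)
    expect_identical(calls$genes, "MYBPC3")
    expect_identical(calls$exon_span, "MYBPC3_ex12-MYBPC3_ex20")
    expect_identical(calls$span_kind, "intragenic")
    ## closed form incl. the carrier-total renormalization: the 9 halved
    ## targets shrink the carrier's own denominator
    eps <- cnvThresholds()@pseudofrac
    expected <- log2((100 / (39 * 200 - 9 * 100) + eps) /
                     (200 / (39 * 200) + eps))
    expect_equal(calls$mean_log2, expected, tolerance = 1e-9)
    expect_equal(calls$mean_log2, -1, tolerance = 0.2)
})

test_that("a whole-gene duplication is labelled whole_gene", {
    ## wide panel so the duplicated gene is a small share of the total
    tg <- makeTargets(chrom = c(rep("chr2", 60), rep("chr11", 25),
                                rep("chr12", 14)),
                      start = c((0:59) * 500, (0:24) * 500, (0:13) * 500),
                      end = c((0:59) * 500 + 200, (0:24) * 500 + 200,
                              (0:13) * 500 + 200),
                      gene = c(rep("TTN", 60), rep("MYBPC3", 25),
                               rep("PKP2", 14)),
                      exon = c(1:60, 1:25, 1:14))
    x <- flatExperiment(tg, n = 10, depth = 200)
    d <- depthMatrix(x)
    d[86:99, 2] <- 300    # all 14 PKP2 exons at 1.5x
    assay(x, "depth") <- d
    calls <- callCNVs(log2Ratios(fractionalCoverage(x)))
    expect_identical(nrow(calls), 1L)
    expect_identical(calls$direction, "gain")
    expect_identical(calls$genes, "PKP2")
    expect_identical(calls$span_kind, "whole_gene")
    expect_identical(calls$n_targets, 14L)
})

test_that("sub-threshold profiles produce no calls", {
    l2r <- matrix(0.39, 10, 4)
    l2r[3, ] <- -0.549
    x <- l2mExperiment(l2r)
    expect_identical(nrow(callCNVs(x, cnvThresholds())), 0L)
})

test_that("thresholds are inclusive at exactly +0.40 and -0.55", {
    l2r <- matrix(0, 6, 4)
    l2r[2, 1] <- 0.40
    l2r[5, 2] <- -0.55
    l2r[3, 3] <- 0.40 - 1e-12
    l2r[4, 4] <- -0.55 + 1e-12
    calls <- callCNVs(l2mExperiment(l2r), cnvThresholds())
    expect_identical(nrow(calls), 2L)
    expect_setequal(calls$direction, c("gain", "loss"))
    expect_setequal(calls$sample_id, c("S01", "S02"))
})

test_that("masked targets and chromosome boundaries break contiguity", {
    ## 25 MYBPC3 targets on chr11 then 14 PKP2 targets on chr12
    l2r <- matrix(0, 39, 3)
    l2r[23:28, 1] <- -1           # crosses the chr11/chr12 boundary
    l2r[5:9, 2] <- -1             # contiguous but for a mask at 7
    masked <- matrix(FALSE, 39, 3)
    masked[7, 2] <- TRUE
    calls <- callCNVs(l2mExperiment(l2r, masked = masked), cnvThresholds())
    s1 <- calls[calls$sample_id == "S01", ]
    expect_identical(nrow(s1), 2L)
    expect_identical(s1$chrom, c("chr11", "chr12"))
    s2 <- calls[calls$sample_id == "S02", ]
    expect_identical(nrow(s2), 2L)
    expect_identical(s2$first_target, c(4L, 7L))  # 0-based genome order
    expect_identical(s2$n_targets, c(2L, 2L))
})

test_that("segmentation matches the brute-force oracle on random matrices", {
    set.seed(42)
    tg <- makeTargets(chrom = rep(c("chr2", "chr7"), each = 20),
                      start = rep((0:19) * 1000, 2),
                      end = rep((0:19) * 1000 + 200, 2),
                      gene = rep(c("A", "B", "C", "D"), each = 10),
                      exon = rep(1:10, 4))
    chrom <- as.character(seqnames(tg))
    th <- cnvThresholds()
    for (trial in 1:200) {
        l2r <- matrix(rnorm(40 * 8, sd = 0.5), 40, 8)
        masked <- matrix(runif(40 * 8) < 0.05, 40, 8)
        x <- l2mExperiment(l2r, targets = tg, masked = masked)
        got <- callCNVs(x, th)
        got <- got[order(match(got$sample_id, colnames(x)),
                         got$first_target), ]
        want <- oracleSegments(l2r, masked, chrom, th@gainMin, th@lossMax)
        expect_identical(nrow(got), nrow(want))
        if (nrow(got)) {
            expect_identical(got$first_target, want$first - 1L)
            expect_identical(got$last_target, want$last - 1L)
            expect_identical(got$direction, want$direction)
            expect_identical(match(got$sample_id, colnames(x)), want$sample)
        }
    }
})

test_that("VCF output round-trips through an independent reader", {
    skip_if_not_installed("VariantAnnotation")
    l2r <- matrix(0, 10, 4)
    l2r[2:4, 1] <- -1
    l2r[7, 3] <- 0.585
    calls <- callCNVs(l2mExperiment(l2r), cnvThresholds())
    vcf_path <- tempfile(fileext = ".vcf")
    writeCallsVcf(calls, vcf_path)
    v <- VariantAnnotation::readVcf(vcf_path)
    expect_identical(nrow(v), 2L)
    alts <- unlist(lapply(VariantAnnotation::alt(v), as.character))
    expect_setequal(alts, c("<DEL>", "<DUP>"))
    expect_identical(VariantAnnotation::info(v)$END,
                     calls$end[order(calls$start)])
    expect_equal(VariantAnnotation::info(v)$FOLD_CHANGE,
                 2^calls$mean_log2[order(calls$start)], tolerance = 1e-3)
})
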