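## Small in-code fixtures shared across test files.

suppressPackageStartupMessages({
    library(SummarizedExperiment)
    library(GenomicRanges)
})

## two-gene autosomal panel: MYBPC3 with 25 exons on chr11, PKP2 with 14 on
## chr12
twoGenePanel <- function() {
    makeTargets(chrom = c(rep("chr11", 25), rep("chr12", 14)),
                start = c(1000 + (0:24) * 500, 2000 + (0:13) * 500),
                end = c(1000 + (0:24) * 500 + 200, 2000 + (0:13) * 500 + 200),
                gene = c(rep("MYBPC3", 25), rep("PKP2", 14)),
                exon = c(1:25, 1:14))
}

## constant-depth batch: every cell identical so all log2 ratios are 0
flatExperiment <- function(targets = twoGenePanel(), n = 10, depth = 100,
                           sex = "female", batch = "b1") {
    sm <- data.frame(sample_id = sprintf("S%02d", seq_len(n)),
                     batch_id = batch, sex = rep_len(sex, n),
                     phenotype = "HCM")
    CnvExperiment(matrix(depth, length(targets), n), targets, sm)
}

## wrap a bare log2-ratio matrix (targets x samples) in a CnvExperiment so
## callCNVs() can be exercised with exact values
l2mExperiment <- function(l2r, targets = NULL, masked = NULL) {
    if (is.null(targets)) {
        stopifnot(nrow(l2r) <= 39)
        targets <- twoGenePanel()[seq_len(nrow(l2r))]
    }
    n <- ncol(l2r)
    sm <- data.frame(sample_id = sprintf("S%02d", seq_len(n)),
                     batch_id = "b1", sex = "female", phenotype = "HCM")
    x <- CnvExperiment(matrix(100, nrow(l2r), n), targets, sm)
    dimnames(l2r) <- dimnames(assay(x, "depth"))
    assay(x, "log2ratio") <- l2r
    if (is.null(masked))
        masked <- matrix(FALSE, nrow(l2r), ncol(l2r))
    dimnames(masked) <- dimnames(l2r)
    assay(x, "masked") <- masked
    x
}

## Independent reference for segmentation: naive per-cell scan with explicit
## run construction, no vectorization shared with the package code.
oracleSegments <- function(l2r, masked, chrom, gain, loss) {
    out <- data.frame(sample = integer(), first = integer(),
                      last = integer(), direction = character())
    for (j in seq_len(ncol(l2r))) {
        run_dir <- ""
        run_first <- NA_integer_
        for (i in seq_len(nrow(l2r))) {
            v <- l2r[i, j]
            st <- if (masked[i, j] || !is.finite(v)) ""
                  else if (v >= gain) "gain"
                  else if (v <= loss) "loss"
                  else ""
            boundary <- run_dir != "" &&
                (st != run_dir || chrom[i] != chrom[i - 1L])
            if (boundary) {
                out <- rbind(out, data.frame(sample = j, first = run_first,
                                             last = i - 1L,
                                             direction = run_dir))
                run_dir <- ""
            }
            if (st != "" && run_dir == "") {
                run_dir <- st
                run_first <- i
            }
        }
        if (run_dir != "")
            out <- rbind(out, data.frame(sample = j, first = run_first,
                                         last = nrow(l2r),
                                         direction = run_dir))
    }
    out[order(out$sample, out$first), , drop = FALSE]
}

## minimal call table for review/filter tests
fakeCall <- function(sample_id, first, last, direction = "loss",
                     chrom = "chr11", mean_log2 = -1) {
    data.frame(sample_id = sample_id, chrom = chrom,
               start = 1000 + first * 500, end = 1000 + last * 500 + 200,
               genes = "MYBPC3", exon_span = "x", direction = direction,
               first_target = first, last_target = last,
               n_targets = last - first + 1L, mean_log2 = mean_log2,
               span_kind = "intragenic", stringsAsFactors = FALSE)
}
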