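#' Run the full CNV pipeline on a coverage matrix
#'
#' Reads targets, coverage and sample metadata; normalizes each batch to
#' fractional coverage and batch-median log2 ratios; calls CNVs at the fixed
#' thresholds; reviews calls (cohort-frequency artifact filter plus
#' signal-to-noise score); classifies them against the gene-knowledge table;
#' and summarizes detection rates over the cohort. All tabular outputs are
#' deterministic given inputs and configuration; on any error partial
#' outputs are removed.
#'
#' Files written to `outDir`: `log2_ratios.tsv`, `masked.tsv`, `calls.tsv`
#' (with review and classification columns), `summary.tsv`,
#' `provenance.yaml`, optionally `calls.vcf` and one `profile_<sample>.png`
#' per sample with a passing call.
#'
#' @param targetsBed path to the targets BED.
#' @param coverageTsv path to the coverage matrix TSV.
#' @param samplesTsv path to the sample metadata TSV.
#' @param kbTsv path to a gene-knowledge TSV; `NULL` skips classification.
#' @param outDir output directory (created if needed).
#' @param thresholds a [cnvThresholds()].
#' @param freqCutoff cohort-frequency artifact cutoff (default 0.01).
#' @param noiseMultiplier review signal-to-noise multiplier (default 2).
#' @param vcf also write symbolic VCF records (default `FALSE`).
#' @param plots write per-sample profile plots for samples with passing
#'   calls (default `TRUE`).
#' @param config optional YAML file; its keys (`targets`, `coverage`,
#'   `samples`, `kb`, `out`, `gain_threshold`, `loss_threshold`,
#'   `freq_cutoff`, `noise_multiplier`, `vcf`, `plots`) supply defaults that
#'   explicit arguments override.
#' @return invisibly, a list with `experiment`, `calls`, `summary` and the
#'   output paths.
#' @export
runPipeline <- function(targetsBed = NULL, coverageTsv = NULL,
                        samplesTsv = NULL, kbTsv = NULL, outDir = NULL,
                        thresholds = cnvThresholds(), freqCutoff = 0.01,
                        noiseMultiplier = 2, vcf = FALSE, plots = TRUE,
                        config = NULL) {
    if (!is.null(config)) {
        cfg <- yaml::read_yaml(config)
        if (is.null(targetsBed)) targetsBed <- cfg$targets
        if (is.null(coverageTsv)) coverageTsv <- cfg$coverage
        if (is.null(samplesTsv)) samplesTsv <- cfg$samples
        if (is.null(kbTsv)) kbTsv <- cfg$kb
        if (is.null(outDir)) outDir <- cfg$out
        if (!is.null(cfg$gain_threshold) || !is.null(cfg$loss_threshold))
            thresholds <- cnvThresholds(
                gainMin = cfg$gain_threshold %||% thresholds@gainMin,
                lossMax = cfg$loss_threshold %||% thresholds@lossMax)
        if (!is.null(cfg$freq_cutoff)) freqCutoff <- cfg$freq_cutoff
        if (!is.null(cfg$noise_multiplier)) noiseMultiplier <-
            cfg$noise_multiplier
        if (!is.null(cfg$vcf)) vcf <- cfg$vcf
        if (!is.null(cfg$plots)) plots <- cfg$plots
    }
    if (is.null(targetsBed) || is.null(coverageTsv) || is.null(samplesTsv) ||
        is.null(outDir))
        stop("targetsBed, coverageTsv, samplesTsv and outDir are required")
    for (p in c(targetsBed, coverageTsv, samplesTsv, kbTsv))
        if (!file.exists(p)) stop("input file not found: ", p)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    written <- character()
    ok <- FALSE
    on.exit(if (!ok) unlink(written), add = TRUE)
    out <- function(f) {
        p <- file.path(outDir, f)
        written <<- c(written, p)
        p
    }
    targets <- readTargets(targetsBed)
    x <- readCoverageMatrix(coverageTsv, targets, samplesTsv)
    x <- log2Ratios(fractionalCoverage(x), thresholds)
    l2r <- log2Matrix(x)
    write.table(data.frame(label = rownames(l2r), l2r, check.names = FALSE),
                out("log2_ratios.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE, fileEncoding = "UTF-8")
    msk <- maskedMatrix(x)
    write.table(data.frame(label = rownames(msk), msk, check.names = FALSE),
                out("masked.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE, fileEncoding = "UTF-8")
    calls <- callCNVs(x, thresholds)
    calls <- reviewCalls(calls, x, nSamples = ncol(x),
                         freqCutoff = freqCutoff,
                         noiseMultiplier = noiseMultiplier)
    if (!is.null(kbTsv))
        calls <- classifyCalls(calls, readGeneKnowledge(kbTsv))
    writeCalls(calls, out("calls.tsv"))
    if (vcf) writeCallsVcf(calls, out("calls.vcf"))
    summary <- NULL
    if (!is.null(kbTsv)) {
        comp <- as.data.frame(table(phenotype = x$phenotype),
                              responseName = "count")
        comp$phenotype <- as.character(comp$phenotype)
        classified <- calls[calls$verdict == "pass", , drop = FALSE]
        classified$phenotype <-
            samplePhenotype(x)[classified$sample_id]
        summary <- summarizeCohort(classified, comp)
        writeSummary(summary, out("summary.tsv"))
    }
    if (plots && nrow(calls)) {
        for (s in unique(calls$sample_id[calls$verdict == "pass"]))
            plotSampleProfile(x, s, calls,
                              file = out(sprintf("profile_%s.png", s)))
    }
    prov <- list(package = "exonCNV",
                 version = as.character(packageVersion("exonCNV")),
                 inputs = list(targets = targetsBed, coverage = coverageTsv,
                               samples = samplesTsv, kb = kbTsv),
                 input_md5 = as.list(tools::md5sum(
                     c(targetsBed, coverageTsv, samplesTsv))),
                 thresholds = list(gain = thresholds@gainMin,
                                   loss = thresholds@lossMax,
                                   pseudofrac = thresholds@pseudofrac),
                 freq_cutoff = freqCutoff,
                 noise_multiplier = noiseMultiplier)
    yaml::write_yaml(prov, out("provenance.yaml"))
    ok <- TRUE
    invisible(list(experiment = x, calls = calls, summary = summary,
                   files = written))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-sample log2-ratio profile plot
#'
#' Scatter of a sample's log2 ratios by relative genome order, with the gain
#' and loss thresholds drawn as horizontal lines, called spans highlighted,
#' and gene boundaries ticked along the axis. Masked targets are rendered as
#' gaps. The figure size and resolution are fixed so identical inputs give
#' identical plots.
#'
#' @param x a [CnvExperiment-class] with the `"log2ratio"` assay.
#' @param sample sample id.
#' @param calls optional call `data.frame` ([callCNVs()]); this sample's
#'   calls are highlighted.
#' @param file output PNG path, or `NULL` to draw on the current device.
#' @param thresholds thresholds to draw; defaults to those stored in
#'   `metadata(x)`.
#' @return invisibly, a list with the plotted `points` (genome_order, log2)
#'   and `highlights` (one row per highlighted call span).
#' @export
plotSampleProfile <- function(x, sample, calls = NULL, file = NULL,
                              thresholds = NULL) {
    if (!sample %in% colnames(x)) stop("unknown sample: ", sample)
    if (is.null(thresholds)) thresholds <- metadata(x)$thresholds
    if (is.null(thresholds)) thresholds <- cnvThresholds()
    l2r <- log2Matrix(x)[, sample]
    masked <- maskedMatrix(x)[, sample]
    go <- genomeOrder(x)
    gene <- mcols(rowRanges(x))$gene
    pts <- data.frame(genome_order = go[!masked], log2 = l2r[!masked])
    hl <- if (!is.null(calls) && nrow(calls)) {
        sub <- calls[calls$sample_id == sample, , drop = FALSE]
        sub[, c("first_target", "last_target", "direction")]
    } else data.frame(first_target = integer(), last_target = integer(),
                      direction = character())
    if (!is.null(file)) {
        grDevices::png(file, width = 1200, height = 400, res = 96)
        on.exit(grDevices::dev.off(), add = TRUE)
    }
    graphics::plot(pts$genome_order, pts$log2, pch = 20, cex = 0.6,
                   col = "grey30", xlab = "relative genome order",
                   ylab = "log2 ratio", main = sample,
                   ylim = range(c(pts$log2, -1, 1), finite = TRUE))
    graphics::abline(h = thresholds@gainMin, col = "red3", lty = 2)
    graphics::abline(h = thresholds@lossMax, col = "blue3", lty = 2)
    bounds <- go[c(TRUE, gene[-1L] != gene[-length(gene)])]
    graphics::axis(1, at = bounds, labels = FALSE, tcl = -0.2)
    if (nrow(hl)) {
        for (i in seq_len(nrow(hl))) {
            sel <- pts$genome_order >= hl$first_target[i] &
                pts$genome_order <= hl$last_target[i]
            graphics::points(pts$genome_order[sel], pts$log2[sel], pch = 20,
                             cex = 0.9,
                             col = if (hl$direction[i] == "gain") "red3"
                                   else "blue3")
            graphics::rect(hl$first_target[i] - 0.5, -10,
                           hl$last_target[i] + 0.5, 10,
                           border = NA,
                           col = grDevices::adjustcolor("gold", 0.2))
        }
    }
    invisible(list(points = pts, highlights = hl))
}
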