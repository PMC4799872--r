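#' Threshold-based CNV calling
#'
#' Per sample, a target is aberrant when its log2 ratio is at or above the
#' gain threshold (gain) or at or below the loss threshold (loss) — both
#' bounds inclusive. Maximal runs of same-direction aberrant targets that are
#' contiguous in genome order and lie on one chromosome become one call;
#' masked targets break contiguity. `span_kind` is `whole_gene` when the call
#' covers every target of at least one gene, `multi_gene` for at least two
#' genes, and `intragenic` otherwise.
#'
#' @param x a [CnvExperiment-class] with `"log2ratio"`/`"masked"` assays (from
#'   [log2Ratios()]); if absent they are computed with `thresholds`.
#' @param thresholds a [cnvThresholds()]; defaults to the thresholds stored by
#'   [log2Ratios()] in `metadata(x)`.
#' @return A `data.frame` with one row per call: `sample_id`, `chrom`,
#'   `start`, `end` (1-based inclusive span of the underlying targets),
#'   `genes` (`/`-separated), `exon_span`, `direction` (`loss`/`gain`),
#'   `first_target`, `last_target` (genome_order bounds), `n_targets`,
#'   `mean_log2`, `span_kind`. Zero rows when nothing exceeds the thresholds.
#' @examples
#' sim <- simulateCohort(simConfig(n_batches = 2, n_targets = 60,
#'                                 n_events = 3))
#' calls <- callCNVs(sim$experiment)
#' calls[, c("sample_id", "genes", "direction", "n_targets")]
#' @export
callCNVs <- function(x, thresholds = NULL) {
    if (!"log2ratio" %in% assayNames(x)) {
        if (is.null(thresholds)) thresholds <- cnvThresholds()
        x <- log2Ratios(x, thresholds)
    }
    if (is.null(thresholds)) thresholds <- metadata(x)$thresholds
    if (is.null(thresholds)) thresholds <- cnvThresholds()
    l2r <- log2Matrix(x)
    masked <- maskedMatrix(x)
    tg <- rowRanges(x)
    chrom <- as.character(seqnames(tg))
    gene <- mcols(tg)$gene
    go <- mcols(tg)$genome_order
    gene_targets <- split(seq_along(tg), gene)
    out <- vector("list", ncol(l2r))
    for (j in seq_len(ncol(l2r))) {
        v <- l2r[, j]
        status <- integer(length(v))
        ok <- !masked[, j] & is.finite(v)
        status[ok & v >= thresholds@gainMin] <- 1L
        status[ok & v <= thresholds@lossMax] <- -1L
        if (!any(status != 0L)) next
        grp <- paste(chrom, status)
        r <- rle(grp)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        keep <- which(status[starts] != 0L)
        rows <- lapply(keep, function(k) {
            idx <- starts[k]:ends[k]
            covered <- vapply(gene_targets[unique(gene[idx])],
                              function(gt) all(gt %in% idx), NA)
            span_kind <- if (sum(covered) >= 2L) "multi_gene"
                         else if (sum(covered) >= 1L) "whole_gene"
                         else "intragenic"
            lab <- mcols(tg)$label[idx]
            data.frame(
                sample_id = colnames(l2r)[j],
                chrom = chrom[idx[1L]],
                start = min(start(tg)[idx]),
                end = max(end(tg)[idx]),
                genes = paste(unique(gene[idx]), collapse = "/"),
                exon_span = if (length(idx) == 1L) lab else
                    paste(lab[1L], lab[length(lab)], sep = "-"),
                direction = if (status[idx[1L]] > 0L) "gain" else "loss",
                first_target = go[idx[1L]],
                last_target = go[idx[length(idx)]],
                n_targets = length(idx),
                mean_log2 = mean(l2r[idx, j]),
                span_kind = span_kind,
                stringsAsFactors = FALSE)
        })
        out[[j]] <- do.call(rbind, rows)
    }
    out <- out[!vapply(out, is.null, NA)]
    if (!length(out)) return(.emptyCalls())
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

.emptyCalls <- function() {
    data.frame(sample_id = character(), chrom = character(),
               start = integer(), end = integer(), genes = character(),
               exon_span = character(), direction = character(),
               first_target = integer(), last_target = integer(),
               n_targets = integer(), mean_log2 = numeric(),
               span_kind = character(), stringsAsFactors = FALSE)
}

#' Write calls as TSV
#'
#' @param calls call `data.frame` from [callCNVs()] (optionally with review
#'   and classification columns appended).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCalls <- function(calls, path) {
    write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE,
                fileEncoding = "UTF-8")
    invisible(path)
}

#' Write calls as VCF 4.2 symbolic records
#'
#' Losses become `<DEL>` and gains `<DUP>` records with `END`, `SVTYPE`,
#' `NTARGETS` and `FOLD_CHANGE` (`2^mean_log2`) in INFO. POS is the first
#' base of the first affected target; REF is reported as `N`.
#'
#' @param calls call `data.frame` from [callCNVs()].
#' @param path output path (plain-text `.vcf`).
#' @return `path`, invisibly.
#' @export
writeCallsVcf <- function(calls, path) {
    hdr <- c(
        "##fileformat=VCFv4.2",
        sprintf("##source=exonCNV-%s", as.character(packageVersion("exonCNV"))),
        "##ALT=<ID=DEL,Description=\"Deletion\">",
        "##ALT=<ID=DUP,Description=\"Duplication\">",
        "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
        "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
        paste0("##INFO=<ID=NTARGETS,Number=1,Type=Integer,",
               "Description=\"Number of affected targets\">"),
        paste0("##INFO=<ID=FOLD_CHANGE,Number=1,Type=Float,",
               "Description=\"2^mean_log2 of the call\">"),
        paste0("##INFO=<ID=SAMPLE,Number=1,Type=String,",
               "Description=\"Carrier sample\">"),
        paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
              sep = "\t"))
    recs <- character(0L)
    if (nrow(calls)) {
        alt <- ifelse(calls$direction == "gain", "<DUP>", "<DEL>")
        svtype <- ifelse(calls$direction == "gain", "DUP", "DEL")
        info <- sprintf("END=%d;SVTYPE=%s;NTARGETS=%d;FOLD_CHANGE=%.4f;SAMPLE=%s",
                        calls$end, svtype, calls$n_targets,
                        2^calls$mean_log2, calls$sample_id)
        recs <- paste(calls$chrom, calls$start,
                      sprintf("cnv_%s_%d", calls$sample_id,
                              calls$first_target),
                      "N", alt, ".", ".", info, sep = "\t")
    }
    writeLines(c(hdr, recs), path, useBytes = TRUE)
    invisible(path)
}
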