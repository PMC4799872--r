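#' Cohort-frequency artifact filter
#'
#' Calls recurring across the cohort are presumed technical artifacts or
#' benign polymorphisms. Two calls belong to the same locus when they have
#' the same direction and reciprocal target overlap of at least 50% (both
#' ways, counted in targets); loci are the connected components of that
#' relation. A locus whose carrier count (distinct samples) reaches
#' `freqCutoff` of the cohort is marked `artifact_freq`; all other calls
#' `pass`. Recurrence requires at least two distinct carriers: a private
#' call is never an artifact, however small the cohort. The partition is
#' deterministic and invariant to call order.
#'
#' @param calls call `data.frame` from [callCNVs()], pooled over all batches.
#' @param nSamples cohort size the frequency is computed against.
#' @param freqCutoff carrier-fraction cutoff (default `0.01`, i.e. calls in
#'   >= 1% of samples are not analyzed further).
#' @return `calls` with added columns `locus_id`, `cohort_freq` and
#'   `verdict` (`pass` / `artifact_freq`).
#' @export
frequencyFilter <- function(calls, nSamples, freqCutoff = 0.01) {
    stopifnot(nSamples >= 1L)
    if (!nrow(calls)) {
        calls$locus_id <- integer(0L)
        calls$cohort_freq <- numeric(0L)
        calls$verdict <- character(0L)
        return(calls)
    }
    comp <- .callLoci(calls)
    carriers <- vapply(split(calls$sample_id, comp),
                       function(s) length(unique(s)), 0L)
    freq <- carriers[as.character(comp)] / nSamples
    calls$locus_id <- comp
    calls$cohort_freq <- as.numeric(freq)
    calls$verdict <- ifelse(carriers[as.character(comp)] >= 2L &
                                calls$cohort_freq >= freqCutoff,
                            "artifact_freq", "pass")
    calls
}

## Connected components of the same-locus relation. Locus ids are renumbered
## by the genomically first member so the labelling is order-invariant.
.callLoci <- function(calls) {
    n <- nrow(calls)
    parent <- seq_len(n)
    find <- function(i) {
        while (parent[i] != i) i <- parent[i]
        i
    }
    for (i in seq_len(n - 1L)) {
        for (k in seq(i + 1L, n)) {
            if (calls$direction[i] != calls$direction[k]) next
            if (calls$chrom[i] != calls$chrom[k]) next
            ov <- min(calls$last_target[i], calls$last_target[k]) -
                max(calls$first_target[i], calls$first_target[k]) + 1L
            if (ov <= 0L) next
            if (ov / calls$n_targets[i] >= 0.5 &&
                ov / calls$n_targets[k] >= 0.5) {
                ri <- find(i); rk <- find(k)
                if (ri != rk) parent[max(ri, rk)] <- min(ri, rk)
            }
        }
    }
    roots <- vapply(seq_len(n), find, 0L)
    ## label components by their genomically first member so the ids do not
    ## depend on row order
    key <- vapply(split(seq_len(n), roots), function(ix) {
        o <- ix[order(calls$chrom[ix], calls$first_target[ix],
                      calls$direction[ix], calls$sample_id[ix])][1L]
        paste(calls$chrom[o], calls$first_target[o], calls$direction[o],
              calls$sample_id[o])
    }, "")
    comp_key <- key[as.character(roots)]
    match(comp_key, sort(unique(comp_key)))
}

#' Quantitative review scores for CNV calls
#'
#' A reproducible surrogate for manual plot review: each call gets its
#' cohort frequency (see [frequencyFilter()]), the noise of its targets in
#' the rest of the batch, and its own signal strength.
#'
#' * `cohort_freq` — fraction of cohort samples carrying an overlapping
#'   same-direction call.
#' * `batch_noise` — median absolute deviation (consistency-scaled,
#'   [stats::mad()]) of the call's targets' log2 ratios across non-carrier
#'   batch samples.
#' * `signal` — `|mean_log2|` of the call.
#'
#' Verdicts, in precedence order: `artifact_freq` when
#' `cohort_freq >= freqCutoff`; `low_quality` when
#' `signal < noiseMultiplier * batch_noise`; else `pass`. Filtered calls are
#' retained with their verdict, never dropped.
#'
#' @param calls pooled call `data.frame` from [callCNVs()].
#' @param x the [CnvExperiment-class] the calls were derived from (with
#'   `"log2ratio"` assay).
#' @param nSamples cohort size; defaults to `ncol(x)`.
#' @param freqCutoff carrier-fraction cutoff (default `0.01`).
#' @param noiseMultiplier signal must reach this multiple of `batch_noise`
#'   (default `2`).
#' @return `calls` with added columns `locus_id`, `cohort_freq`,
#'   `batch_noise`, `signal`, `verdict`.
#' @export
reviewCalls <- function(calls, x, nSamples = ncol(x), freqCutoff = 0.01,
                        noiseMultiplier = 2) {
    calls <- frequencyFilter(calls, nSamples, freqCutoff)
    if (!nrow(calls)) {
        calls$batch_noise <- numeric(0L)
        calls$signal <- numeric(0L)
        return(calls)
    }
    l2r <- log2Matrix(x)
    go <- genomeOrder(x)
    batches <- batchIds(x)
    noise <- numeric(nrow(calls))
    for (i in seq_len(nrow(calls))) {
        rows <- which(go >= calls$first_target[i] &
                      go <= calls$last_target[i])
        if (!length(rows) || !calls$sample_id[i] %in% colnames(l2r))
            stop("call targets or sample absent from the experiment: ",
                 calls$sample_id[i])
        batch <- batches[calls$sample_id[i]]
        in_batch <- names(batches)[batches == batch]
        locus_samples <- unique(
            calls$sample_id[calls$locus_id == calls$locus_id[i]])
        non_carrier <- setdiff(in_batch, locus_samples)
        vals <- l2r[rows, non_carrier, drop = FALSE]
        vals <- vals[is.finite(vals)]
        noise[i] <- if (length(vals) >= 3L) mad(vals) else NA_real_
    }
    calls$batch_noise <- noise
    calls$signal <- abs(calls$mean_log2)
    low <- !is.na(noise) & calls$signal < noiseMultiplier * noise &
        calls$verdict != "artifact_freq"
    calls$verdict[low] <- "low_quality"
    calls
}
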