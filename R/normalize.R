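#' Fractional coverage per sample
#'
#' Divides each sample's per-target mean depth by that sample's summed depth
#' over all targets, so every sample's fractions add to 1. This cancels
#' library size: scaling a sample's raw depths by any positive constant
#' leaves its fractions (and therefore its log2 ratios) unchanged.
#'
#' @param x a [CnvExperiment-class] with the `"depth"` assay.
#' @return `x` with an added `"frac"` assay.
#' @examples
#' cx <- simulateCohort(simConfig(n_batches = 1, n_targets = 20))$experiment
#' colSums(fracMatrix(fractionalCoverage(cx)))  # all 1
#' @export
fractionalCoverage <- function(x) {
    d <- depthMatrix(x)
    tot <- colSums(d)
    dead <- which(tot <= 0)
    if (length(dead))
        stop("sample(s) with zero total depth: ",
             paste(colnames(d)[dead], collapse = ", "))
    assay(x, "frac") <- sweep(d, 2L, tot, "/")
    x
}

#' Batch-median log2 copy ratios
#'
#' For each sequencing batch independently, each sample's fractional coverage
#' on a target is divided by the per-target batch median of fractional
#' coverage and log2-transformed:
#' `log2((frac + eps) / (median + eps))` with `eps` the pseudofraction from
#' the thresholds. The median is computed on the log scale (for odd strata
#' this is identical to the fractional-scale median; for even strata it uses
#' the geometric rather than arithmetic mean of the two central order
#' statistics), which makes every unmasked target's stratum median of log2
#' ratios exactly zero. The median for autosomal targets is taken over all batch
#' samples (including the sample under test); targets on the X or Y
#' chromosome are normalized against same-sex batch samples only, so a
#' female with three X copies scores `log2(3/2)` and males are not flagged
#' as X-deletion carriers.
#'
#' Masking, recorded in the `"masked"` assay and never called: targets whose
#' stratum median is at or below `eps` (capture dropout); sex-chromosome
#' targets for samples whose sex stratum holds fewer than 3 batch samples
#' (with a warning) or whose sex is unknown.
#'
#' @param x a [CnvExperiment-class]; [fractionalCoverage()] is applied first
#'   if the `"frac"` assay is absent.
#' @param thresholds a [cnvThresholds()] object (supplies the pseudofraction).
#' @return `x` with added `"log2ratio"` and `"masked"` assays;
#'   `metadata(x)$thresholds` records the thresholds used.
#' @export
log2Ratios <- function(x, thresholds = cnvThresholds()) {
    stopifnot(is(thresholds, "CnvThresholds"))
    if (!"frac" %in% assayNames(x)) x <- fractionalCoverage(x)
    fr <- fracMatrix(x)
    eps <- thresholds@pseudofrac
    batches <- as.character(x$batch_id)
    sex <- as.character(x$sex)
    sex_target <- .is_sex_target(x)
    l2r <- matrix(NA_real_, nrow(fr), ncol(fr), dimnames = dimnames(fr))
    masked <- matrix(FALSE, nrow(fr), ncol(fr), dimnames = dimnames(fr))
    small_strata <- character()
    for (b in unique(batches)) {
        cols <- which(batches == b)
        if (length(cols) < 3L)
            stop("batch '", b, "' has fewer than 3 samples; refusing to ",
                 "normalize")
        strata <- list(list(cols = cols, targets = which(!sex_target)))
        if (any(sex_target)) {
            for (sx in c("female", "male")) {
                sc <- cols[sex[cols] == sx]
                if (length(sc) == 0L) next
                if (length(sc) < 3L) {
                    small_strata <- c(small_strata,
                                      sprintf("%s/%s (n=%d)", b, sx,
                                              length(sc)))
                    masked[sex_target, sc] <- TRUE
                    next
                }
                strata <- c(strata, list(list(cols = sc,
                                              targets = which(sex_target))))
            }
            unk <- cols[sex[cols] == "unknown"]
            if (length(unk)) masked[sex_target, unk] <- TRUE
        }
        for (st in strata) {
            if (!length(st$targets)) next
            sub <- fr[st$targets, st$cols, drop = FALSE]
            lsub <- log2(sub + eps)
            lmed <- apply(lsub, 1L, median)
            l2r[st$targets, st$cols] <- sweep(lsub, 1L, lmed, "-")
            dropout <- apply(sub, 1L, median) <= eps
            if (any(dropout))
                masked[st$targets[dropout], st$cols] <- TRUE
        }
    }
    if (length(small_strata))
        warning("sex-chromosome targets masked for strata with < 3 samples: ",
                paste(unique(small_strata), collapse = "; "))
    l2r[masked] <- NA_real_
    assay(x, "log2ratio") <- l2r
    assay(x, "masked") <- masked
    metadata(x)$thresholds <- thresholds
    x
}
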