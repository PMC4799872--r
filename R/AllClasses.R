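#' @import methods
#' @importFrom stats median mad rnorm rbinom runif setNames
#' @importFrom utils read.delim write.table packageVersion head
#' @importFrom BiocGenerics sort
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges seqnames start end width
#' @importFrom GenomeInfoDb seqlevels sortSeqlevels seqlevelsInUse
#' @import SummarizedExperiment
NULL

.SEX_LEVELS <- c("female", "male", "unknown")
.PHENOTYPES <- c("HCM", "DCM", "ARVC", "LVNC", "RCM", "NOS", "other")
.SEX_CHROMS <- c("X", "Y", "chrX", "chrY")

#' Container for targeted-panel coverage data
#'
#' `CnvExperiment` extends [SummarizedExperiment::RangedSummarizedExperiment].
#' Rows are captured targets (exons) carrying `gene`, `label` and
#' `genome_order` metadata columns; columns are samples carrying `sample_id`,
#' `batch_id`, `sex` and `phenotype`. The `"depth"` assay holds mean
#' per-interval read depth; [fractionalCoverage()] and [log2Ratios()] add the
#' `"frac"`, `"log2ratio"` and `"masked"` assays.
#'
#' @slot .. see [SummarizedExperiment::RangedSummarizedExperiment]
#' @seealso [CnvExperiment()] the constructor, [readCoverageMatrix()]
#' @export
setClass("CnvExperiment", contains = "RangedSummarizedExperiment")

setValidity("CnvExperiment", function(object) {
    msg <- character()
    if (!"depth" %in% assayNames(object))
        msg <- c(msg, "assay 'depth' is required")
    else {
        d <- assay(object, "depth")
        if (!is.numeric(d) || anyNA(d) || any(!is.finite(d)))
            msg <- c(msg, "depth must be finite and non-missing")
        else if (any(d < 0))
            msg <- c(msg, "depth values must be >= 0")
    }
    need_row <- c("gene", "label", "genome_order")
    if (!all(need_row %in% colnames(mcols(rowRanges(object)))))
        msg <- c(msg, sprintf("rowRanges must carry mcols: %s",
                              paste(need_row, collapse = ", ")))
    else {
        go <- mcols(rowRanges(object))$genome_order
        if (anyDuplicated(go) || is.unsorted(go, strictly = TRUE))
            msg <- c(msg, "genome_order must be unique and strictly increasing")
    }
    need_col <- c("sample_id", "batch_id", "sex", "phenotype")
    if (!all(need_col %in% colnames(colData(object))))
        msg <- c(msg, sprintf("colData must carry: %s",
                              paste(need_col, collapse = ", ")))
    else {
        cd <- colData(object)
        if (anyDuplicated(cd$sample_id))
            msg <- c(msg, "sample_id must be unique")
        if (!all(cd$sex %in% .SEX_LEVELS))
            msg <- c(msg, sprintf("sex must be one of: %s",
                                  paste(.SEX_LEVELS, collapse = ", ")))
        if (!all(cd$phenotype %in% .PHENOTYPES))
            msg <- c(msg, sprintf("phenotype must be one of: %s",
                                  paste(.PHENOTYPES, collapse = ", ")))
        bs <- table(cd$batch_id)
        if (ncol(object) > 0L && any(bs < 3L))
            msg <- c(msg, sprintf(
                "every batch needs >= 3 samples (too small: %s)",
                paste(names(bs)[bs < 3L], collapse = ", ")))
    }
    if (length(msg)) msg else TRUE
})

#' Construct a CnvExperiment
#'
#' @param depth numeric matrix of mean per-interval depth, one row per target
#'   (in `targets` order) and one column per sample (in `sampleData` order).
#' @param targets `GRanges` of captured intervals as returned by
#'   [readTargets()] or [makeTargets()].
#' @param sampleData `data.frame` (or `DataFrame`) with columns `sample_id`,
#'   `batch_id`, `sex` (`female`/`male`/`unknown`) and `phenotype`; extra
#'   columns (e.g. `panel`) are retained.
#' @return A [CnvExperiment-class] object.
#' @examples
#' tg <- makeTargets(chrom = "chr1", start = c(0, 100, 200),
#'                   end = c(50, 150, 250), gene = "MYBPC3",
#'                   exon = 1:3)
#' sm <- data.frame(sample_id = paste0("S", 1:4), batch_id = "b1",
#'                  sex = "female", phenotype = "HCM")
#' cx <- CnvExperiment(matrix(100, 3, 4), tg, sm)
#' @export
CnvExperiment <- function(depth, targets, sampleData) {
    depth <- as.matrix(depth)
    sampleData <- as(sampleData, "DataFrame")
    if (nrow(depth) != length(targets))
        stop("depth rows (", nrow(depth), ") do not match targets (",
             length(targets), ")")
    if (ncol(depth) != nrow(sampleData))
        stop("depth columns (", ncol(depth), ") do not match sampleData rows (",
             nrow(sampleData), ")")
    dimnames(depth) <- list(mcols(targets)$label, sampleData$sample_id)
    rownames(sampleData) <- sampleData$sample_id
    se <- SummarizedExperiment(assays = list(depth = depth),
                               rowRanges = targets, colData = sampleData)
    new("CnvExperiment", se)
}

setMethod("show", "CnvExperiment", function(object) {
    callNextMethod()
    cat(sprintf("batches(%d): %s\n",
                length(unique(object$batch_id)),
                paste(unique(object$batch_id), collapse = " ")))
    cat(sprintf("genes(%d): %s\n",
                length(unique(mcols(rowRanges(object))$gene)),
                paste(head(unique(mcols(rowRanges(object))$gene), 6L),
                      collapse = " ")))
})

#' Calling thresholds on the log2 copy ratio
#'
#' Fixed thresholds: a target is gain-aberrant when its log2 ratio is at or
#' above `gainMin` (+0.40) and loss-aberrant at or below `lossMax` (-0.55),
#' both bounds inclusive. `pseudofrac` is the pseudocount added on the
#' fractional-coverage scale to numerator and denominator before taking the
#' ratio, keeping log2 finite over capture dropouts; per-target batch medians
#' at or below `pseudofrac` are masked instead of called.
#'
#' @param gainMin minimum log2 ratio for a gain (default `0.40`).
#' @param lossMax maximum log2 ratio for a loss (default `-0.55`).
#' @param pseudofrac pseudocount on the fractional scale (default `1e-6`,
#'   roughly 0.1% of a typical per-target fraction on a ~500-target panel).
#' @return A `CnvThresholds` object.
#' @examples
#' cnvThresholds()
#' cnvThresholds(gainMin = 0.3)
#' @export
cnvThresholds <- function(gainMin = 0.40, lossMax = -0.55, pseudofrac = 1e-6) {
    new("CnvThresholds", gainMin = gainMin, lossMax = lossMax,
        pseudofrac = pseudofrac)
}

#' @rdname cnvThresholds
#' @export
setClass("CnvThresholds",
         representation(gainMin = "numeric", lossMax = "numeric",
                        pseudofrac = "numeric"))

setValidity("CnvThresholds", function(object) {
    msg <- character()
    if (length(object@gainMin) != 1L || length(object@lossMax) != 1L ||
        length(object@pseudofrac) != 1L)
        msg <- c(msg, "all threshold fields must be scalar")
    else {
        if (!(object@gainMin > 0)) msg <- c(msg, "gainMin must be > 0")
        if (!(object@lossMax < 0)) msg <- c(msg, "lossMax must be < 0")
        if (!(object@pseudofrac > 0)) msg <- c(msg, "pseudofrac must be > 0")
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "CnvThresholds", function(object) {
    cat(sprintf("CnvThresholds: gain >= %+.3f, loss <= %+.3f, pseudofrac %g\n",
                object@gainMin, object@lossMax, object@pseudofrac))
})

## -- accessors ---------------------------------------------------------------

#' Accessors for CnvExperiment
#'
#' `depthMatrix()`, `fracMatrix()`, `log2Matrix()` and `maskedMatrix()` return
#' the corresponding assay (targets x samples); `batchIds()`, `sampleSex()`
#' and `samplePhenotype()` return per-sample metadata; `genomeOrder()` the
#' per-target plotting rank.
#'
#' @param x a [CnvExperiment-class].
#' @return matrix or vector, see above.
#' @name accessors
#' @examples
#' cx <- simulateCohort(simConfig(n_batches = 1, n_targets = 20))$experiment
#' dim(depthMatrix(cx))
#' table(batchIds(cx))
NULL

.assay_or_stop <- function(x, name, hint) {
    if (!name %in% assayNames(x))
        stop("assay '", name, "' not present; run ", hint, " first")
    assay(x, name)
}

#' @rdname accessors
#' @export
depthMatrix <- function(x) assay(x, "depth")

#' @rdname accessors
#' @export
fracMatrix <- function(x) .assay_or_stop(x, "frac", "fractionalCoverage()")

#' @rdname accessors
#' @export
log2Matrix <- function(x) .assay_or_stop(x, "log2ratio", "log2Ratios()")

#' @rdname accessors
#' @export
maskedMatrix <- function(x) .assay_or_stop(x, "masked", "log2Ratios()")

#' @rdname accessors
#' @export
batchIds <- function(x) setNames(as.character(x$batch_id), x$sample_id)

#' @rdname accessors
#' @export
sampleSex <- function(x) setNames(as.character(x$sex), x$sample_id)

#' @rdname accessors
#' @export
samplePhenotype <- function(x) setNames(as.character(x$phenotype), x$sample_id)

#' @rdname accessors
#' @export
genomeOrder <- function(x) {
    g <- if (is(x, "GRanges")) x else rowRanges(x)
    mcols(g)$genome_order
}

.is_sex_target <- function(x) {
    as.character(seqnames(rowRanges(x))) %in% .SEX_CHROMS
}
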