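#' Read a per-interval coverage matrix
#'
#' Reads the tab-delimited per-sample mean-depth matrix produced by
#' depth-of-coverage interval summaries: one row per captured interval keyed
#' `chrom:start-end` (1-based inclusive, the interval-summary convention;
#' converted internally to BED semantics), one numeric column per sample.
#' Rows may appear in any order; they are aligned to the target set.
#'
#' @param path coverage TSV; first column `interval`, remaining columns one
#'   per sample. `#` comment lines are ignored.
#' @param targets `GRanges` from [readTargets()].
#' @param sampleData sample metadata `data.frame` (see [CnvExperiment()]) or
#'   a path to a sample-metadata TSV readable by [readSampleMeta()].
#' @return A [CnvExperiment-class] with the `"depth"` assay.
#' @seealso [writeCoverageMatrix()] for the inverse; the pair round-trips
#'   depth values exactly.
#' @export
readCoverageMatrix <- function(path, targets, sampleData) {
    if (!file.exists(path)) stop("coverage file not found: ", path)
    if (is.character(sampleData) && length(sampleData) == 1L)
        sampleData <- readSampleMeta(sampleData)
    tab <- read.delim(path, check.names = FALSE, comment.char = "#",
                      colClasses = "character", fileEncoding = "UTF-8")
    if (ncol(tab) < 2L) stop("coverage TSV needs an interval column plus ",
                             "at least one sample column")
    keys <- tab[[1L]]
    want <- sprintf("%s:%d-%d", as.character(seqnames(targets)),
                    start(targets), end(targets))
    extra <- setdiff(keys, want)
    if (length(extra))
        stop("coverage rows not in the target set: ",
             paste(extra, collapse = ", "))
    miss <- setdiff(want, keys)
    if (length(miss))
        stop("targets missing from coverage matrix: ",
             paste(miss, collapse = ", "))
    if (anyDuplicated(keys))
        stop("duplicated coverage rows: ",
             paste(unique(keys[duplicated(keys)]), collapse = ", "))
    depth <- as.matrix(tab[, -1L, drop = FALSE])
    suppressWarnings(storage.mode(depth) <- "double")
    if (anyNA(depth))
        stop("non-numeric depth value(s) in coverage matrix")
    if (any(depth < 0))
        stop("negative depth value(s) in coverage matrix")
    depth <- depth[match(want, keys), , drop = FALSE]
    ids <- colnames(depth)
    meta_ids <- as.character(sampleData$sample_id)
    miss <- setdiff(ids, meta_ids)
    if (length(miss))
        stop("samples missing from metadata: ", paste(miss, collapse = ", "))
    sampleData <- sampleData[match(ids, meta_ids), , drop = FALSE]
    CnvExperiment(depth, targets, sampleData)
}

#' Write the depth assay as a coverage TSV
#'
#' Values are rendered with 17 significant digits so that
#' [readCoverageMatrix()] recovers them bit-for-bit.
#'
#' @param x a [CnvExperiment-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCoverageMatrix <- function(x, path) {
    tg <- rowRanges(x)
    key <- sprintf("%s:%d-%d", as.character(seqnames(tg)), start(tg), end(tg))
    d <- depthMatrix(x)
    out <- cbind(interval = key,
                 as.data.frame(apply(d, 2L, function(v) sprintf("%.17g", v)),
                               check.names = FALSE))
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                fileEncoding = "UTF-8")
    invisible(path)
}

#' Read sample metadata
#'
#' Tab-delimited, UTF-8, columns `sample_id`, `batch_id`, `sex`, `phenotype`
#' and optionally `panel`; `#` comment lines ignored.
#'
#' @param path metadata TSV.
#' @return `data.frame` of sample metadata.
#' @export
readSampleMeta <- function(path) {
    if (!file.exists(path)) stop("sample metadata file not found: ", path)
    meta <- read.delim(path, check.names = FALSE, comment.char = "#",
                       colClasses = "character", fileEncoding = "UTF-8")
    need <- c("sample_id", "batch_id", "sex", "phenotype")
    miss <- setdiff(need, colnames(meta))
    if (length(miss))
        stop("sample metadata lacks column(s): ", paste(miss, collapse = ", "))
    meta
}

#' Write sample metadata
#'
#' @param x a [CnvExperiment-class] or a sample-metadata `data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSampleMeta <- function(x, path) {
    meta <- if (is(x, "SummarizedExperiment")) as.data.frame(colData(x)) else x
    write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE,
                fileEncoding = "UTF-8")
    invisible(path)
}
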