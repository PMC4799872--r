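#' Read captured targets from a BED file
#'
#' Parses a 4+ column BED (0-based half-open) whose name column encodes gene
#' and exon as `GENE_exN` (e.g. `MYBPC3_ex12`). Intervals are sorted by
#' (chrom, start) with chromosomes in natural karyotype order, and
#' `genome_order` is assigned `0..n-1` in sorted order, so a shuffled BED
#' yields the same target set as a pre-sorted one.
#'
#' @param path path to the BED file; `#` comment lines are ignored.
#' @return A `GRanges` with mcols `gene`, `label`, `genome_order`.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines(c("chr11\t100\t200\tMYBPC3_ex1",
#'              "chr11\t300\t400\tMYBPC3_ex2"), bed)
#' readTargets(bed)
#' @export
readTargets <- function(path) {
    if (!file.exists(path)) stop("BED file not found: ", path)
    raw <- readLines(path, encoding = "UTF-8")
    keep <- !grepl("^\\s*(#|$)", raw)
    lineno <- which(keep)
    raw <- raw[keep]
    if (!length(raw)) stop("no intervals in BED file: ", path)
    fields <- strsplit(raw, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 4L))
        stop("malformed BED line ", lineno[which(nf < 4L)[1L]],
             ": fewer than 4 columns")
    chrom <- vapply(fields, `[`, "", 1L)
    start <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
    end <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
    name <- vapply(fields, `[`, "", 4L)
    bad <- which(is.na(start) | is.na(end))
    if (length(bad))
        stop("malformed BED line ", lineno[bad[1L]],
             ": non-numeric coordinates")
    bad <- which(start >= end)
    if (length(bad))
        stop("invalid interval on BED line ", lineno[bad[1L]],
             ": start >= end")
    if (any(!grepl("_", name)))
        stop("BED name column must encode 'GENE_exN'; offender line ",
             lineno[which(!grepl("_", name))[1L]])
    key <- paste(chrom, start, end)
    if (anyDuplicated(key))
        stop("duplicate interval(s): ",
             paste(unique(key[duplicated(key)]), collapse = "; "))
    gene <- sub("_[^_]+$", "", name)
    .orderTargets(chrom, start, end, gene, name)
}

#' Build a target set programmatically
#'
#' Convenience constructor used by the simulator and tests; applies the same
#' sorting, `genome_order` assignment and validation as [readTargets()].
#'
#' @param chrom,start,end vectors of BED-convention (0-based half-open)
#'   coordinates.
#' @param gene gene symbol per interval.
#' @param exon exon number per interval (used to build the `GENE_exN` label),
#'   or `NULL` to use `label` directly.
#' @param label full exon labels; defaults to `paste0(gene, "_ex", exon)`.
#' @return A `GRanges` with mcols `gene`, `label`, `genome_order`.
#' @export
makeTargets <- function(chrom, start, end, gene, exon = NULL,
                        label = paste0(gene, "_ex", exon)) {
    n <- length(start)
    chrom <- rep_len(chrom, n)
    gene <- rep_len(gene, n)
    if (any(start >= end)) stop("start >= end in targets")
    .orderTargets(chrom, start, end, gene, label)
}

.orderTargets <- function(chrom, start, end, gene, label) {
    gr <- GRanges(chrom, IRanges(start + 1L, end), gene = gene, label = label)
    gr <- sortSeqlevels(gr)
    gr <- sort(gr, ignore.strand = TRUE)
    mcols(gr)$genome_order <- seq_along(gr) - 1L
    for (g in unique(mcols(gr)$gene)) {
        sub <- gr[mcols(gr)$gene == g]
        if (length(sub) > 1L) {
            sp <- split(sub, as.character(seqnames(sub)))
            for (s in sp) {
                if (length(s) > 1L &&
                    any(start(s)[-1L] <= end(s)[-length(s)]))
                    stop("overlapping intervals within gene ", g)
            }
        }
    }
    if (anyDuplicated(mcols(gr)$label))
        stop("duplicate exon labels: ",
             paste(unique(mcols(gr)$label[duplicated(mcols(gr)$label)]),
                   collapse = ", "))
    gr
}

#' Write a target set as BED
#'
#' @param targets `GRanges` from [readTargets()]/[makeTargets()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTargets <- function(targets, path) {
    df <- data.frame(chrom = as.character(seqnames(targets)),
                     start = start(targets) - 1L,
                     end = end(targets),
                     name = mcols(targets)$label)
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}
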