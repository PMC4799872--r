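.TABLE1_MD5 <- "023a786ae83c14d17b46dcf55b51d048"

#' Reference set of clinically significant cardiomyopathy CNVs
#'
#' Loads the packaged transcription of the nine clinically significant CNVs
#' observed in a 1425-patient cardiomyopathy referral cohort: four intragenic
#' deletions (LMNA, LAMP2, MYBPC3, PKP2), two intragenic duplications (TTN,
#' MYOZ2), two whole-gene duplications (NEXN, PKP2) and one trisomy X seen as
#' a duplication of all four X-chromosome panel genes. File integrity is
#' verified by checksum before use.
#'
#' @return `data.frame` with one row per CNV: `sample_id`, `sex`, `age`,
#'   `phenotype`, `genes`, `region`, `direction`, `classification` (as
#'   originally reported), `tier` (`P_LP`/`VUS`, pathogenic and likely
#'   pathogenic collapsed), `span_kind`, `panel`.
#' @examples
#' referenceCnvCalls()
#' @export
referenceCnvCalls <- function() {
    path <- system.file("extdata", "cardio_reference_cnvs.tsv", package = "exonCNV")
    sum <- unname(tools::md5sum(path))
    if (!identical(sum, .TABLE1_MD5))
        stop("integrity check failed for packaged CNV reference table (md5 ",
             sum, ")")
    tab <- read.delim(path, colClasses = "character", fileEncoding = "UTF-8")
    tab$sample_id <- tab$patient_id
    tab$tier <- ifelse(tab$classification %in%
                           c("Pathogenic", "Likely pathogenic"),
                       "P_LP", "VUS")
    tab
}

#' Cohort composition by phenotype
#'
#' The default is the packaged referral-cohort composition (1425 patients:
#' 708 HCM, 479 DCM, 90 ARVC, 54 LVNC, 25 RCM, 61 NOS/combined, 8 with
#' skeletal myopathy features).
#'
#' @param path TSV with columns `phenotype` and `count`; defaults to the
#'   packaged composition.
#' @return `data.frame` with `phenotype`, `count` (integer) and any extra
#'   columns.
#' @export
cohortComposition <- function(path = system.file("extdata",
                                                 "cohort_composition.tsv",
                                                 package = "exonCNV")) {
    comp <- read.delim(path, fileEncoding = "UTF-8")
    if (!all(c("phenotype", "count") %in% colnames(comp)))
        stop("composition needs 'phenotype' and 'count' columns")
    comp$count <- as.integer(comp$count)
    if (anyDuplicated(comp$phenotype)) stop("duplicate phenotype rows")
    comp
}

#' Cohort-level CNV detection rates
#'
#' Aggregates classified calls into the detection-rate arithmetic of a
#' diagnostic cohort: overall and P/LP-only rates (counting individuals, not
#' calls), rates per phenotype, per gene and per gene-within-phenotype, and
#' the fraction of clinically significant calls that are intragenic (counted
#' per call). All rates are kept as exact integer fractions; percentages are
#' derived, never rounded internally.
#'
#' @slot total cohort size.
#' @slot overall,plp,intragenic numerator/denominator pairs.
#' @slot perPhenotype,perGene,genePhenotype rate tables.
#' @slot notes documented caveats carried with the summary.
#' @seealso [summarizeCohort()]
#' @export
setClass("CohortSummary",
         representation(total = "integer",
                        overall = "numeric", plp = "numeric",
                        perPhenotype = "data.frame",
                        perGene = "data.frame",
                        genePhenotype = "data.frame",
                        intragenic = "numeric",
                        notes = "character"))

#' Summarize classified CNV calls over a cohort
#'
#' @param classified `data.frame` of classified, clinically reportable calls
#'   (e.g. [referenceCnvCalls()], or the output of [classifyCalls()] joined with
#'   sample phenotypes); needs columns `sample_id`, `phenotype`, `genes`,
#'   `tier`, `span_kind`. Calls with tier `B_LB` are excluded from the
#'   clinically significant set. A patient with several calls counts once in
#'   all individual-level rates.
#' @param composition cohort composition from [cohortComposition()]; every
#'   phenotype present in `classified` must appear here.
#' @param geneTested optional named integer vector (or a knowledge table with
#'   `gene`/`n_tested` columns, see [readGeneKnowledge()]) giving the
#'   per-gene number of patients tested, used as per-gene denominators;
#'   genes without an entry fall back to the cohort total.
#' @param notes extra note strings to carry in the summary.
#' @return A [CohortSummary-class].
#' @examples
#' s <- summarizeCohort(referenceCnvCalls(), cohortComposition(),
#'                      geneTested = readGeneKnowledge())
#' s
#' summaryRates(s)
#' @export
summarizeCohort <- function(classified, composition = cohortComposition(),
                            geneTested = NULL, notes = character()) {
    need <- c("sample_id", "phenotype", "genes", "tier", "span_kind")
    miss <- setdiff(need, colnames(classified))
    if (length(miss))
        stop("classified calls lack column(s): ", paste(miss, collapse = ", "))
    total <- sum(composition$count)
    bad <- setdiff(unique(classified$phenotype), composition$phenotype)
    if (length(bad))
        stop("phenotype(s) absent from composition: ",
             paste(bad, collapse = ", "))
    if (is.data.frame(geneTested)) {
        if (!all(c("gene", "n_tested") %in% colnames(geneTested)))
            stop("geneTested table needs 'gene' and 'n_tested' columns")
        geneTested <- setNames(as.integer(geneTested$n_tested),
                               geneTested$gene)
    }
    sig <- classified[classified$tier %in% c("P_LP", "VUS"), , drop = FALSE]
    overall <- c(length(unique(sig$sample_id)), total)
    plp <- c(length(unique(sig$sample_id[sig$tier == "P_LP"])), total)
    per_ph <- data.frame(
        phenotype = composition$phenotype,
        n_cnv = vapply(composition$phenotype, function(p)
            length(unique(sig$sample_id[sig$phenotype == p])), 0L),
        n_tested = composition$count)
    per_ph$percent <- 100 * per_ph$n_cnv / per_ph$n_tested
    glist <- strsplit(sig$genes, "/", fixed = TRUE)
    gcalls <- data.frame(gene = as.character(unlist(glist)),
                         sample_id = rep(sig$sample_id, lengths(glist)),
                         phenotype = rep(sig$phenotype, lengths(glist)))
    genes <- sort(unique(gcalls$gene))
    per_gene <- data.frame(
        gene = genes,
        n_cnv = vapply(genes, function(g)
            length(unique(gcalls$sample_id[gcalls$gene == g])), 0L),
        n_tested = vapply(genes, function(g) {
            if (!is.null(geneTested) && g %in% names(geneTested))
                geneTested[[g]] else total
        }, 0L))
    per_gene$percent <- 100 * per_gene$n_cnv / per_gene$n_tested
    gp <- unique(gcalls[, c("gene", "phenotype")])
    gp <- gp[order(gp$gene, gp$phenotype), , drop = FALSE]
    gene_ph <- if (nrow(gp)) data.frame(
        gene = gp$gene, phenotype = gp$phenotype,
        n_cnv = as.integer(mapply(function(g, p)
            length(unique(gcalls$sample_id[gcalls$gene == g &
                                           gcalls$phenotype == p])),
            gp$gene, gp$phenotype)),
        n_tested = composition$count[match(gp$phenotype,
                                           composition$phenotype)])
    else data.frame(gene = character(), phenotype = character(),
                    n_cnv = integer(), n_tested = integer())
    gene_ph$percent <- 100 * gene_ph$n_cnv / gene_ph$n_tested
    rownames(gene_ph) <- NULL
    intragenic <- if (nrow(sig))
        c(sum(sig$span_kind == "intragenic"), nrow(sig))
    else c(NA_real_, 0)
    notes <- c(notes, .compositionNotes(composition, gene_ph))
    new("CohortSummary", total = as.integer(total),
        overall = as.numeric(overall), plp = as.numeric(plp),
        perPhenotype = per_ph, perGene = per_gene, genePhenotype = gene_ph,
        intragenic = as.numeric(intragenic), notes = notes)
}

.compositionNotes <- function(composition, gene_ph) {
    notes <- character()
    if ("ARVC" %in% composition$phenotype &&
        composition$count[composition$phenotype == "ARVC"] == 90L)
        notes <- c(notes, paste(
            "ARVC denominator is the stated cohort composition (n = 90);",
            "an alternative published denominator of 99 would give",
            "correspondingly lower rates."))
    notes
}

#' @rdname summarizeCohort
#' @param object a [CohortSummary-class].
#' @return `summaryRates()`: a `data.frame` with one row per reported rate
#'   (`name`, `numerator`, `denominator`, `percent`); the intragenic fraction
#'   row carries the fraction (not a percentage) in `percent`.
#' @export
summaryRates <- function(object) {
    stopifnot(is(object, "CohortSummary"))
    block <- function(prefix, suffix, num, den) {
        ## paste0() promotes zero-length labels to "prefix", so guard empties
        if (!length(num))
            return(data.frame(name = character(), numerator = numeric(),
                              denominator = numeric()))
        data.frame(name = paste0(prefix, suffix), numerator = num,
                   denominator = den)
    }
    rows <- rbind(
        data.frame(name = "overall", numerator = object@overall[1L],
                   denominator = object@overall[2L]),
        data.frame(name = "plp", numerator = object@plp[1L],
                   denominator = object@plp[2L]),
        block("phenotype_", object@perPhenotype$phenotype,
              object@perPhenotype$n_cnv, object@perPhenotype$n_tested),
        block("gene_", object@perGene$gene,
              object@perGene$n_cnv, object@perGene$n_tested),
        block("gene_", paste0(object@genePhenotype$gene, "_in_",
                              object@genePhenotype$phenotype),
              object@genePhenotype$n_cnv, object@genePhenotype$n_tested))
    rows$percent <- 100 * rows$numerator / rows$denominator
    rows <- rbind(rows, data.frame(
        name = "intragenic_fraction",
        numerator = object@intragenic[1L],
        denominator = object@intragenic[2L],
        percent = if (object@intragenic[2L] > 0)
            object@intragenic[1L] / object@intragenic[2L] else NA_real_))
    rownames(rows) <- NULL
    rows
}

setMethod("show", "CohortSummary", function(object) {
    fmt <- function(num, den) {
        if (den == 0 || is.na(num)) return("n/a")
        sprintf("%d/%d (%.2g%%)", as.integer(num), as.integer(den),
                100 * num / den)
    }
    cat("CNV detection over a cohort of", object@total, "individuals\n")
    cat("  clinically significant (P/LP or VUS):",
        fmt(object@overall[1L], object@overall[2L]), "\n")
    cat("  pathogenic / likely pathogenic:     ",
        fmt(object@plp[1L], object@plp[2L]), "\n")
    if (!is.na(object@intragenic[1L]) && object@intragenic[2L] > 0)
        cat(sprintf("  intragenic fraction of calls:        %d/%d\n",
                    as.integer(object@intragenic[1L]),
                    as.integer(object@intragenic[2L])))
    cat("  by phenotype:\n")
    ph <- object@perPhenotype
    for (i in seq_len(nrow(ph)))
        cat(sprintf("    %-6s %s\n", ph$phenotype[i],
                    fmt(ph$n_cnv[i], ph$n_tested[i])))
    if (nrow(object@perGene)) {
        cat("  by gene (denominator = patients tested for that gene):\n")
        pg <- object@perGene
        for (i in seq_len(nrow(pg)))
            cat(sprintf("    %-8s %s\n", pg$gene[i],
                        fmt(pg$n_cnv[i], pg$n_tested[i])))
    }
    for (n in object@notes) cat("  note:", n, "\n")
})

#' Write a cohort summary as TSV
#'
#' @param object a [CohortSummary-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSummary <- function(object, path) {
    write.table(summaryRates(object), path, sep = "\t", quote = FALSE,
                row.names = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}
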