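#' Simulation configuration
#'
#' Describes a synthetic targeted-panel cohort with the statistical structure
#' the caller assumes: batches of samples sharing per-target capture
#' efficiencies, per-sample library-size factors, multiplicative depth noise,
#' optional recurrent artifact loci, X-linked genes with sex-dependent
#' baseline copy number, and injected CNVs of known span and copy number.
#'
#' Depth is generated as
#' `depth_mean * library_s * efficiency_t * (copies / baseline) * 2^eta`
#' with `eta ~ Normal(0, noise_sd)` on the log2 scale, so an injected event's
#' expected log2 ratio is exactly `log2(copies / baseline)`.
#'
#' @param n_batches number of sequencing batches.
#' @param batch_size samples per batch (default 10, the typical run size the
#'   batch-median normalization was designed around).
#' @param n_targets number of captured exon targets (default 500); roughly
#'   8% are placed in four X-linked genes, the rest in autosomal genes of
#'   2-24 exons.
#' @param target_effect_sd sd (natural-log scale) of the lognormal per-target
#'   capture efficiency (default 0.5).
#' @param depth_mean mean per-target depth at library factor 1 (default 200).
#' @param library_sd sd (natural-log scale) of the lognormal per-sample
#'   library factor (default 0.3).
#' @param noise_sd multiplicative depth noise sd on the log2 scale
#'   (default 0.1).
#' @param sex_ratio probability a sample is female (default 0.5).
#' @param artifact_loci list of recurrent artifact loci, each a list with
#'   `first_target`, `n_targets`, `frequency` (population carrier
#'   frequency) and `copy_number`.
#' @param events `data.frame` of injected CNVs (`sample` index,
#'   `first_target`, `last_target`, `copy_number`), or `NULL` to draw
#'   `n_events` at random.
#' @param n_events number of random autosomal events to inject when `events`
#'   is `NULL`; spans drawn uniformly from `event_span`, copy numbers from
#'   `event_copies`, at most one event per batch per locus.
#' @param event_span integer range of event spans in targets.
#' @param event_copies copy numbers to draw events from (diploid baseline 2).
#' @param seed integer seed; the simulation is fully reproducible from it.
#' @return A `SimConfig` list.
#' @seealso [simulateCohort()]
#' @export
simConfig <- function(n_batches = 5, batch_size = 10, n_targets = 500,
                      target_effect_sd = 0.5, depth_mean = 200,
                      library_sd = 0.3, noise_sd = 0.1, sex_ratio = 0.5,
                      artifact_loci = list(), events = NULL, n_events = 0,
                      event_span = c(1L, 10L), event_copies = c(1L, 3L),
                      seed = 17) {
    cfg <- list(n_batches = as.integer(n_batches),
                batch_size = as.integer(batch_size),
                n_targets = as.integer(n_targets),
                target_effect_sd = target_effect_sd,
                depth_mean = depth_mean, library_sd = library_sd,
                noise_sd = noise_sd, sex_ratio = sex_ratio,
                artifact_loci = artifact_loci, events = events,
                n_events = as.integer(n_events),
                event_span = as.integer(event_span),
                event_copies = as.integer(event_copies),
                seed = as.integer(seed))
    stopifnot(cfg$n_batches >= 1L, cfg$batch_size >= 3L, cfg$n_targets >= 10L,
              cfg$noise_sd >= 0, cfg$sex_ratio >= 0, cfg$sex_ratio <= 1,
              cfg$target_effect_sd >= 0, cfg$library_sd >= 0,
              cfg$depth_mean > 0)
    for (a in cfg$artifact_loci) {
        stopifnot(is.list(a),
                  all(c("first_target", "n_targets", "frequency",
                        "copy_number") %in% names(a)))
        if (a$frequency < 0 || a$frequency > 1)
            stop("artifact frequency must be in [0, 1]")
        if (a$first_target + a$n_targets - 1L > cfg$n_targets)
            stop("artifact locus exceeds target count")
    }
    class(cfg) <- "SimConfig"
    cfg
}

## Deterministic panel layout: autosomal genes of 2-24 exons cycling over
## chr1..chr22, then four X-linked genes holding ~8% of targets.
.simTargets <- function(n_targets) {
    n_x <- max(4L, as.integer(round(0.08 * n_targets)))
    n_auto <- n_targets - n_x
    sizes <- integer(0)
    while (sum(sizes) < n_auto)
        sizes <- c(sizes, sample(2:24, 1L))
    sizes[length(sizes)] <- sizes[length(sizes)] - (sum(sizes) - n_auto)
    sizes <- sizes[sizes > 0L]
    x_sizes <- rep(n_x %/% 4L, 4L)
    x_sizes[seq_len(n_x %% 4L)] <- x_sizes[seq_len(n_x %% 4L)] + 1L
    x_sizes <- x_sizes[x_sizes > 0L]
    gene <- c(rep(sprintf("GENE%03d", seq_along(sizes)), sizes),
              rep(sprintf("XGENE%d", seq_along(x_sizes)), x_sizes))
    chrom <- c(rep(paste0("chr", (seq_along(sizes) - 1L) %% 22L + 1L), sizes),
               rep("chrX", sum(x_sizes)))
    exon <- unlist(lapply(c(sizes, x_sizes), seq_len))
    ## sequential, non-overlapping 200 bp exons; genes on the same chromosome
    ## stacked with a 10 kb offset per gene
    offset <- unlist(lapply(c(sizes, x_sizes), function(s) rep(0L, s)))
    gene_index <- rep(seq_along(c(sizes, x_sizes)), c(sizes, x_sizes))
    start <- 1e6 + gene_index * 1e4 + (exon - 1L) * 500L
    makeTargets(chrom, start, start + 200L, gene, exon)
}

#' Draw random CNV events for a simulated cohort
#'
#' Spans are autosomal, contiguous in genome order within one chromosome,
#' and constrained to at most one event per batch per overlapping locus so
#' the batch median stays a valid copy-neutral reference.
#'
#' @param targets target `GRanges` (from [makeTargets()]).
#' @param n_samples,batch_size cohort shape.
#' @param n_events number of events to draw.
#' @param event_span integer range of span lengths (targets).
#' @param event_copies copy numbers drawn uniformly (baseline 2).
#' @param avoid integer vector of target indices (1-based) events must not
#'   touch (e.g. planted artifact loci).
#' @return `data.frame` with `sample`, `first_target`, `last_target`
#'   (0-based genome order), `copy_number`.
#' @export
sampleEvents <- function(targets, n_samples, batch_size, n_events,
                         event_span = c(1L, 10L), event_copies = c(1L, 3L),
                         avoid = integer()) {
    chrom <- as.character(seqnames(targets))
    autosomal <- which(!chrom %in% .SEX_CHROMS)
    taken <- matrix(FALSE, nrow = length(targets),
                    ncol = ceiling(n_samples / batch_size))
    out <- vector("list", n_events)
    tries <- 0L
    i <- 1L
    while (i <= n_events) {
        tries <- tries + 1L
        if (tries > 50L * n_events)
            stop("could not place ", n_events, " non-overlapping events; ",
                 "reduce n_events or enlarge the panel")
        span <- sample(seq(event_span[1L], event_span[2L]), 1L)
        first <- sample(autosomal, 1L)
        idx <- first:(first + span - 1L)
        if (max(idx) > length(targets)) next
        if (length(unique(chrom[idx])) != 1L) next
        if (any(idx %in% avoid)) next
        s <- sample(n_samples, 1L)
        b <- (s - 1L) %/% batch_size + 1L
        if (any(taken[idx, b])) next
        taken[idx, b] <- TRUE
        out[[i]] <- data.frame(sample = s, first_target = idx[1L] - 1L,
                               last_target = idx[length(idx)] - 1L,
                               copy_number = sample(event_copies, 1L))
        i <- i + 1L
    }
    do.call(rbind, out)
}

#' Simulate a targeted-panel coverage cohort with ground truth
#'
#' @param cfg a [simConfig()].
#' @return list with `experiment` (a [CnvExperiment-class] with the
#'   `"depth"` assay) and `truth` (`data.frame` of injected events and
#'   artifact carriers: `sample_id`, `batch_id`, `chrom`, `start`, `end`,
#'   `first_target`, `last_target`, `copy_number`, `baseline`, `kind`,
#'   `direction`, `expected_log2`, `is_artifact`). Identical seeds give
#'   bit-identical results.
#' @examples
#' sim <- simulateCohort(simConfig(n_batches = 1, n_targets = 40,
#'                                 noise_sd = 0, n_events = 1))
#' sim$truth
#' @export
simulateCohort <- function(cfg) {
    stopifnot(inherits(cfg, "SimConfig"))
    if (exists(".Random.seed", envir = globalenv())) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    }
    set.seed(cfg$seed)
    targets <- .simTargets(cfg$n_targets)
    n_targets <- length(targets)
    n_samples <- cfg$n_batches * cfg$batch_size
    chrom <- as.character(seqnames(targets))
    on_x <- chrom == "chrX"
    sex <- ifelse(runif(n_samples) < cfg$sex_ratio, "female", "male")
    sampleData <- data.frame(
        sample_id = sprintf("S%04d", seq_len(n_samples)),
        batch_id = sprintf("B%03d", rep(seq_len(cfg$n_batches),
                                        each = cfg$batch_size)),
        sex = sex, phenotype = "other")
    eff <- exp(rnorm(n_targets, 0, cfg$target_effect_sd))
    lib <- exp(rnorm(n_samples, 0, cfg$library_sd))
    baseline <- matrix(2, n_targets, n_samples)
    baseline[on_x, sex == "male"] <- 1
    copies <- baseline
    truth <- list()
    for (a in cfg$artifact_loci) {
        idx <- a$first_target:(a$first_target + a$n_targets - 1L)
        carriers <- which(runif(n_samples) < a$frequency)
        for (s in carriers) {
            copies[idx, s] <- a$copy_number
            truth[[length(truth) + 1L]] <-
                .truthRow(targets, sampleData, idx, s, a$copy_number,
                          baseline, is_artifact = TRUE)
        }
    }
    events <- cfg$events
    if (is.null(events) && cfg$n_events > 0L) {
        avoid <- unlist(lapply(cfg$artifact_loci, function(a)
            a$first_target:(a$first_target + a$n_targets - 1L)))
        events <- sampleEvents(targets, n_samples, cfg$batch_size,
                               cfg$n_events, cfg$event_span,
                               cfg$event_copies, avoid = avoid)
    }
    if (!is.null(events) && nrow(events)) {
        for (i in seq_len(nrow(events))) {
            idx <- (events$first_target[i]:events$last_target[i]) + 1L
            s <- events$sample[i]
            copies[idx, s] <- events$copy_number[i]
            truth[[length(truth) + 1L]] <-
                .truthRow(targets, sampleData, idx, s, events$copy_number[i],
                          baseline, is_artifact = FALSE)
        }
    }
    noise <- if (cfg$noise_sd > 0)
        matrix(2^rnorm(n_targets * n_samples, 0, cfg$noise_sd),
               n_targets, n_samples)
    else 1
    depth <- cfg$depth_mean * outer(eff, lib) * (copies / baseline) * noise
    x <- CnvExperiment(depth, targets, sampleData)
    truth <- if (length(truth)) do.call(rbind, truth) else .emptyTruth()
    metadata(x)$truth <- truth
    list(experiment = x, truth = truth)
}

.truthRow <- function(targets, sampleData, idx, s, copy_number, baseline,
                      is_artifact) {
    chrom <- as.character(seqnames(targets))
    gene <- mcols(targets)$gene
    base <- baseline[idx[1L], s]
    gene_sizes <- table(gene)
    covered <- gene_sizes[unique(gene[idx])] ==
        table(gene[idx])[unique(gene[idx])]
    kind <- if (all(chrom[idx] == chrom[idx[1L]]) &&
                length(idx) == sum(chrom == chrom[idx[1L]]))
        "whole_chromosome"
    else if (length(idx) == 1L) "single_exon"
    else if (any(covered)) "whole_gene"
    else "multi_exon"
    data.frame(sample_id = sampleData$sample_id[s],
               batch_id = sampleData$batch_id[s],
               chrom = chrom[idx[1L]],
               start = min(start(targets)[idx]),
               end = max(end(targets)[idx]),
               first_target = idx[1L] - 1L,
               last_target = idx[length(idx)] - 1L,
               copy_number = copy_number,
               baseline = base,
               kind = kind,
               direction = if (copy_number < base) "loss" else "gain",
               expected_log2 = log2(copy_number / base),
               is_artifact = is_artifact)
}

.emptyTruth <- function() {
    data.frame(sample_id = character(), batch_id = character(),
               chrom = character(), start = integer(), end = integer(),
               first_target = integer(), last_target = integer(),
               copy_number = numeric(), baseline = numeric(),
               kind = character(), direction = character(),
               expected_log2 = numeric(), is_artifact = logical())
}

#' Inject a CNV into an existing coverage experiment
#'
#' Scales the affected depth cells by `copyNumber / baseline` (baseline 2 on
#' autosomes; 1 on the X for males) and leaves every other cell untouched.
#' A second injection overlapping a previous one on the same sample is an
#' error — one event per cell.
#'
#' @param x a [CnvExperiment-class].
#' @param sample sample id (or column index).
#' @param firstTarget,lastTarget genome-order bounds (0-based, inclusive).
#' @param copyNumber integer copy number >= 0.
#' @return `x` with scaled depth; the event is recorded in
#'   `metadata(x)$injected`.
#' @export
injectEvent <- function(x, sample, firstTarget, lastTarget, copyNumber) {
    stopifnot(copyNumber >= 0, firstTarget <= lastTarget)
    go <- genomeOrder(x)
    idx <- which(go >= firstTarget & go <= lastTarget)
    if (length(idx) != lastTarget - firstTarget + 1L)
        stop("event span outside the target set")
    j <- if (is.character(sample)) match(sample, colnames(x)) else sample
    if (is.na(j) || j < 1L || j > ncol(x)) stop("unknown sample: ", sample)
    prior <- metadata(x)$injected
    if (!is.null(prior)) {
        clash <- prior$sample == colnames(x)[j] &
            prior$first_target <= lastTarget & prior$last_target >= firstTarget
        if (any(clash))
            stop("overlapping event already injected for sample ",
                 colnames(x)[j])
    }
    base <- ifelse(.is_sex_target(x)[idx] & x$sex[j] == "male", 1, 2)
    d <- assay(x, "depth")
    d[idx, j] <- d[idx, j] * (copyNumber / base)
    assay(x, "depth") <- d
    metadata(x)$injected <- rbind(prior, data.frame(
        sample = colnames(x)[j], first_target = firstTarget,
        last_target = lastTarget, copy_number = copyNumber))
    x
}
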