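#' Configuration of the hyperloop detection pipeline
#'
#' @param resolution bin width in bp (informational; binning happens in
#'   [binAndSplit()]).
#' @param minSupport minimum support (cluster count) for mined candidates.
#' @param kMin,kMax hyperloop size range (kMin >= 3).
#' @param loopSource `"internal"` (distance-decay binomial loop calling) or
#'   the path of a BEDPE file of externally supplied loops.
#' @param loopQ q-value cutoff of the loop caller.
#' @param hyperloopQ q-value cutoff defining significant hyperloops.
#' @param useBias estimate and apply per-bin technical biases?
#' @param interpolation unobserved gap-distance handling, `"interpolate"`
#'   or `"zero"` (see [BackgroundModel-class]).
#' @param minClusterSize,maxClusterSize cluster-size filter before mining.
#' @param nBands,minDist,maxDist distance-decay estimation parameters
#'   (see [estimateDecay()]).
#' @param minMarginalFraction low-coverage bin masking for [iceBiases()].
#' @param decayAwareBias use the decay-normalized balancing scheme of
#'   [iceBiases()] (recommended: it keeps chromosome-end coverage geometry
#'   out of the bias estimates).
#' @param workers number of parallel per-chromosome workers.
#' @return A `pipelineConfig` list.
#' @export
pipelineConfig <- function(resolution = 25000, minSupport = 5L, kMin = 3L,
                           kMax = 5L, loopSource = "internal", loopQ = 0.05,
                           hyperloopQ = 0.05, useBias = TRUE,
                           interpolation = c("interpolate", "zero"),
                           minClusterSize = 2L, maxClusterSize = 1000L,
                           nBands = 100L, minDist = 2L, maxDist = NULL,
                           minMarginalFraction = 0, decayAwareBias = TRUE,
                           workers = 1L) {
    interpolation <- match.arg(interpolation)
    stopifnot(resolution > 0, minSupport >= 1, kMin >= 3L, kMax >= kMin,
              loopQ > 0, loopQ <= 1, hyperloopQ > 0, hyperloopQ <= 1,
              workers >= 1L)
    structure(list(resolution = resolution, minSupport = minSupport,
                   kMin = as.integer(kMin), kMax = as.integer(kMax),
                   loopSource = loopSource, loopQ = loopQ,
                   hyperloopQ = hyperloopQ, useBias = isTRUE(useBias),
                   interpolation = interpolation,
                   minClusterSize = as.integer(minClusterSize),
                   maxClusterSize = as.integer(maxClusterSize),
                   nBands = as.integer(nBands), minDist = as.integer(minDist),
                   maxDist = maxDist, minMarginalFraction = minMarginalFraction,
                   decayAwareBias = isTRUE(decayAwareBias),
                   workers = as.integer(workers)),
              class = "pipelineConfig")
}

# one chromosome end to end; returns list(records, log) or a failure record
runChromosome <- function(cs, config, loops = NULL) {
    cs <- filterClusters(cs, config$minClusterSize, config$maxClusterSize)
    if (numClusters(cs) == 0L) stop("no clusters after size filtering")
    cm <- buildContactMatrix(cs)
    bias <- if (config$useBias)
        iceBiases(cm, maxIter = 500L,
                  minMarginalFraction = config$minMarginalFraction,
                  decayAware = config$decayAwareBias)
    else unitBiases(cs@nBins)
    if (is.null(loops)) {
        if (identical(config$loopSource, "internal")) {
            decay <- estimateDecay(cm, bias, nBands = config$nBands,
                                   minDist = config$minDist,
                                   maxDist = config$maxDist)
            loops <- callLoops(cm, bias, decay, qThreshold = config$loopQ)
        } else {
            loops <- importBedpe(config$loopSource, cs@resolution, cs@nBins,
                                 chrom = cs@chrom)
        }
    }
    cands <- mineFrequent(cs, config$minSupport, config$kMin, config$kMax)
    conn <- filterCandidates(cands, loops, bias)
    records <- if (nrow(conn)) {
        model <- buildBackgroundModel(cs, sort(unique(lengths(conn$bins))),
                                      interpolation = config$interpolation)
        scoreCandidates(conn, model, bias)
    } else {
        data.frame(chrom = character(0), bins = I(list()),
                   k = integer(0), observed = numeric(0),
                   p_raw = numeric(0), p_star = numeric(0),
                   expected = numeric(0), p_value = numeric(0))
    }
    log <- data.frame(chrom = cs@chrom, clusters = numClusters(cs),
                      contacts = totalContacts(cm), loops = numLoops(loops),
                      mined = nrow(cands), connected = nrow(conn),
                      scored = nrow(records))
    list(records = records, log = log)
}

#' Run the full hyperloop detection pipeline
#'
#' Executes, per chromosome: cluster-size filtering, contact matrix
#' construction, bias estimation by matrix balancing, pairwise loop calling
#' (or BEDPE import), FP-growth mining, loop-connectivity filtering,
#' background-model scoring, and size-stratified Benjamini-Hochberg
#' correction. Chromosomes are processed independently (optionally in
#' parallel) and results are merged deterministically, sorted by
#' (chromosome, size, q-value, bins).
#'
#' @param clusterSets a [BinnedClusterSet-class] or a named list of them
#'   (one per chromosome, as produced by [binAndSplit()]).
#' @param config a [pipelineConfig()].
#' @param loops optional precomputed loops: a [LoopSet-class] (single
#'   chromosome) or named list of them, overriding `config$loopSource`.
#' @return A list of class `hyperloopResult`: `hyperloops` (records with
#'   `q_value <= config$hyperloopQ`), `records` (all scored candidates),
#'   `log` (per-chromosome stage counts), `failures` (per-chromosome error
#'   messages, if any) and `config`.
#' @export
runPipeline <- function(clusterSets, config = pipelineConfig(), loops = NULL) {
    if (is(clusterSets, "BinnedClusterSet"))
        clusterSets <- setNames(list(clusterSets), chromName(clusterSets))
    if (is(loops, "LoopSet")) loops <- setNames(list(loops), chromName(loops))
    chroms <- names(clusterSets)
    runOne <- function(chr) {
        tryCatch(runChromosome(clusterSets[[chr]], config, loops[[chr]]),
                 error = function(e) list(failure = data.frame(
                     chrom = chr, error = conditionMessage(e))))
    }
    results <- if (config$workers > 1L)
        parallel::mclapply(chroms, runOne, mc.cores = config$workers)
    else lapply(chroms, runOne)
    names(results) <- chroms

    failures <- do.call(rbind, lapply(results, function(r) r$failure))
    ok <- results[vapply(results, function(r) is.null(r$failure), logical(1L))]
    records <- do.call(rbind, c(lapply(ok, function(r) r$records),
                                list(make.row.names = FALSE)))
    if (is.null(records))
        records <- data.frame(chrom = character(0), bins = I(list()),
                              k = integer(0), observed = numeric(0),
                              p_raw = numeric(0), p_star = numeric(0),
                              expected = numeric(0), p_value = numeric(0))
    records <- groupedBH(records)
    if (nrow(records)) {
        keyOrd <- orderItemsets(records$bins)
        records <- records[keyOrd, , drop = FALSE]
        records <- records[order(records$chrom, records$k, records$q_value), ,
                           drop = FALSE]
        rownames(records) <- NULL
    }
    logs <- do.call(rbind, c(lapply(ok, function(r) r$log),
                             list(make.row.names = FALSE)))
    hyper <- records[!is.na(records$q_value) &
                     records$q_value <= config$hyperloopQ, , drop = FALSE]
    rownames(hyper) <- NULL
    structure(list(hyperloops = hyper, records = records, log = logs,
                   failures = failures, config = config),
              class = "hyperloopResult")
}

#' @method print hyperloopResult
#' @export
print.hyperloopResult <- function(x, ...) {
    cat(sprintf("hyperloopResult: %d significant hyperloops (q <= %g) of %d scored candidates\n",
                nrow(x$hyperloops), x$config$hyperloopQ, nrow(x$records)))
    if (nrow(x$hyperloops)) {
        tb <- table(x$hyperloops$k)
        cat("  by size:", paste(sprintf("k=%s: %d", names(tb), tb), collapse = ", "), "\n")
    }
    if (!is.null(x$failures) && nrow(x$failures))
        cat("  failures on:", paste(x$failures$chrom, collapse = ", "), "\n")
    invisible(x)
}

#' Write a hyperloop table as TSV
#'
#' One row per hyperloop: chromosome, resolution, comma-separated bin start
#' coordinates (bp), size, observed and expected frequency, p- and q-value;
#' sorted by (chromosome, size, q-value). `#` header lines record the
#' configuration.
#'
#' @param result a `hyperloopResult` from [runPipeline()], or a records
#'   data.frame.
#' @param path output file path.
#' @param resolution bin width in bp used to convert bin indices to
#'   coordinates (taken from the config when `result` is a
#'   `hyperloopResult`).
#' @return `path`, invisibly.
#' @export
writeHyperloops <- function(result, path, resolution = NULL) {
    if (inherits(result, "hyperloopResult")) {
        if (is.null(resolution)) resolution <- result$config$resolution
        cfg <- result$config
        hdr <- sprintf("# %s=%s", names(cfg),
                       vapply(cfg, function(v) paste(format(v), collapse = ","), ""))
        tab <- result$hyperloops
    } else {
        hdr <- character(0)
        tab <- result
        if (is.null(resolution)) resolution <- 1
    }
    rows <- sprintf("%s\t%g\t%s\t%d\t%g\t%.6g\t%.6g\t%.6g",
                    tab$chrom, resolution,
                    vapply(tab$bins, function(b) paste(b * resolution, collapse = ","), ""),
                    tab$k, tab$observed, tab$expected, tab$p_value, tab$q_value)
    writeLines(c(hdr, "# chrom\tresolution\tbin_starts_bp\tk\tobserved\texpected\tp_value\tq_value",
                 rows), path)
    invisible(path)
}
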