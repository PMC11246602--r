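#' Coefficient of determination of expected vs observed values
#'
#' \eqn{R^2 = 1 - SS_{res} / SS_{tot}}, treating the expected values as
#' predictions (no refitting). With `logTransform = TRUE`, pairs with any
#' non-positive value are dropped (the number dropped is reported) and the
#' statistic is computed on the log scale, which protects it from outliers
#' and heteroscedastic residuals.
#'
#' @param observed numeric vector of observed values.
#' @param expected numeric vector of model-expected values (same length).
#' @param logTransform compute on the log scale?
#' @return A list of class `FitReport`: `r_squared`, `log_transformed`,
#'   `n_points`, `n_dropped`.
#' @export
rSquared <- function(observed, expected, logTransform = FALSE) {
    if (length(observed) != length(expected)) stop("length mismatch")
    if (length(observed) < 2L) stop("need at least 2 points")
    nDropped <- 0L
    if (logTransform) {
        keep <- observed > 0 & expected > 0
        nDropped <- sum(!keep)
        observed <- log(observed[keep]); expected <- log(expected[keep])
        if (length(observed) < 2L) stop("fewer than 2 positive pairs")
    }
    ssTot <- sum((observed - mean(observed))^2)
    if (ssTot == 0) stop("observed values have zero variance; R^2 undefined")
    ssRes <- sum((observed - expected)^2)
    structure(list(r_squared = 1 - ssRes / ssTot, log_transformed = logTransform,
                   n_points = length(observed), n_dropped = nDropped),
              class = "FitReport")
}

#' @method print FitReport
#' @export
print.FitReport <- function(x, ...) {
    cat(sprintf("FitReport: R^2 = %.4f over %d points%s%s\n", x$r_squared,
                x$n_points, if (x$log_transformed) " (log scale)" else "",
                if (x$n_dropped) sprintf(", %d non-positive pairs dropped", x$n_dropped) else ""))
    invisible(x)
}

#' Shuffle cluster start points preserving gap structure
#'
#' Each cluster keeps its internal gap vector exactly and is moved to a new
#' start bin drawn uniformly among the positions where its full span fits
#' on the chromosome; this destroys specific co-occurrences while keeping
#' the genomic-distance distribution of the data intact. Clusters whose
#' span cannot fit are kept unshuffled (their number is reported in the
#' `nUnshuffled` attribute).
#'
#' @param cs a [BinnedClusterSet-class].
#' @param seed RNG seed (deterministic output).
#' @return The shuffled [BinnedClusterSet-class].
#' @export
shuffleClusters <- function(cs, seed) {
    withSeed(seed, {
        n <- cs@nBins
        spans <- vapply(cs@clusters, function(b) b[length(b)] - b[1L], integer(1L))
        starts <- as.integer(floor(runif(length(spans)) * pmax(n - spans, 1L)))
        newCl <- vector("list", length(spans))
        nFixed <- 0L
        for (ci in seq_along(spans)) {
            if (spans[ci] >= n) { newCl[[ci]] <- cs@clusters[[ci]]; nFixed <- nFixed + 1L }
            else newCl[[ci]] <- starts[ci] + cs@clusters[[ci]] - cs@clusters[[ci]][1L]
        }
        out <- BinnedClusterSet(cs@chrom, cs@resolution, n, newCl, cs@clusterIds)
        attr(out, "nUnshuffled") <- nFixed
        out
    })
}

#' Overlap coefficient between two hyperloop sets
#'
#' \eqn{|A \cap B| / \min(|A|, |B|)}; hyperloops are compared as
#' (chromosome, sorted tuple of bin start coordinates in bp), so results
#' computed at different resolutions remain comparable.
#'
#' @param setA,setB hyperloop tables (data.frames with columns `chrom` and
#'   list-column `bins`, plus attribute or column `resolution`), or
#'   character vectors of precomputed keys.
#' @param resolutionA,resolutionB bin widths (bp) used to convert bin
#'   indices of each table to coordinates; defaults to a `resolution`
#'   column when present.
#' @return The overlap coefficient in `[0, 1]`.
#' @export
overlapCoefficient <- function(setA, setB, resolutionA = NULL, resolutionB = NULL) {
    keyize <- function(s, res) {
        if (is.character(s)) return(s)
        if (nrow(s) == 0L) return(character(0))
        if (is.null(res)) res <- if ("resolution" %in% names(s)) s$resolution else 1
        paste0(s$chrom, ":", mapply(function(b, r) paste(b * r, collapse = ","),
                                    s$bins, res))
    }
    a <- unique(keyize(setA, resolutionA))
    b <- unique(keyize(setB, resolutionB))
    if (!length(a) || !length(b)) stop("overlap coefficient undefined for empty sets")
    length(intersect(a, b)) / min(length(a), length(b))
}

#' Observed vs expected multi-way frequency by gap-pair group
#'
#' Enumerates every size-k subset of every cluster (k = 3), groups the
#' resulting tuples by their vector of consecutive gap distances, and
#' compares the mean observed frequency per possible tuple against the
#' background-model expectation \eqn{\lambda^*} averaged over the group's
#' tuples. This is the model's goodness-of-fit diagnostic: under random
#' polymer looping the two agree up to counting noise.
#'
#' @param cs a [BinnedClusterSet-class].
#' @param model a [BackgroundModel-class] built from `cs`.
#' @param bias optional [BiasVector-class]; when supplied the expectation
#'   uses bias-corrected probabilities and tuples touching invalid bins are
#'   excluded from both sides.
#' @param nGapBins optional number of log-spaced bins per gap axis; when
#'   given, gap-pair groups are pooled into coarse (gap-bin, gap-bin) cells
#'   before comparison. Exact gap pairs at sequencing depths where most
#'   pairs are observed once are dominated by counting noise; coarse cells
#'   recover the regime the diagnostic is meant for.
#' @param minCount groups whose total observed count is below this are
#'   dropped before the fit (log-scale residuals of near-empty groups
#'   measure counting noise, not model fit); default 1 keeps every
#'   non-empty group.
#' @return A list: `table` (data.frame with `d1`, `d2`, `nTuples`,
#'   `observed`, `expected` mean frequencies) and `fit` (the log-scale
#'   `FitReport` from [rSquared()]).
#' @export
gapPairConcordance <- function(cs, model, bias = NULL, nGapBins = NULL,
                               minCount = 1) {
    k <- 3L
    n <- cs@nBins
    tab <- model@dists[[as.character(k)]]
    if (is.null(tab)) stop("model has no size-3 distribution")
    Nk <- model@trials[[as.character(k)]]
    b <- if (is.null(bias)) rep(1, n) else bias@values
    valid <- if (is.null(bias)) rep(TRUE, n) else bias@valid

    # observed: count size-3 subsets per (d1, d2) signature
    sizes <- lengths(cs@clusters)
    stacks <- stackBySize(cs@clusters[sizes >= k])
    keyAll <- list()
    for (si in seq_along(stacks)) {
        m <- stacks[[si]]
        s <- ncol(m)
        idx <- combn(s, 3L)
        b1 <- m[, idx[1L, ], drop = FALSE]
        b2 <- m[, idx[2L, ], drop = FALSE]
        b3 <- m[, idx[3L, ], drop = FALSE]
        ok <- valid[b1 + 1L] & valid[b2 + 1L] & valid[b3 + 1L]
        d1 <- (b2 - b1)[ok]; d2 <- (b3 - b2)[ok]
        keyAll[[si]] <- d1 * n + d2
    }
    keys <- sort(unlist(keyAll, use.names = FALSE))
    if (!length(keys)) stop("no size-3 subsets on valid bins")
    r <- rle(keys)
    d1 <- floor(r$values / n); d2 <- r$values - d1 * n
    obsTotal <- r$lengths

    # expected: lambda* summed over all valid tuples with each signature
    p1 <- gapProbability(tab, d1, model@interpolation)
    p2 <- gapProbability(tab, d2, model@interpolation)
    nTuples <- numeric(length(d1)); biasSum <- numeric(length(d1))
    bv <- ifelse(valid, b, 0)
    for (g in seq_along(d1)) {
        imax <- n - d1[g] - d2[g]
        if (imax < 1) next
        i <- seq_len(imax)
        prodv <- bv[i] * bv[i + d1[g]] * bv[i + d1[g] + d2[g]]
        ok <- valid[i] & valid[i + d1[g]] & valid[i + d1[g] + d2[g]]
        nTuples[g] <- sum(ok)
        biasSum[g] <- sum(prodv[ok])
    }
    keep <- nTuples > 0
    d1 <- d1[keep]; d2 <- d2[keep]; obsTotal <- obsTotal[keep]
    p1 <- p1[keep]; p2 <- p2[keep]
    nTuples <- nTuples[keep]; biasSum <- biasSum[keep]
    expTotal <- (Nk / n) * p1 * p2 * biasSum
    if (!is.null(nGapBins)) {
        breaks <- unique(round(exp(seq(0, log(max(d1, d2) + 1),
                                       length.out = nGapBins + 1L))))
        i1 <- findInterval(d1, breaks); i2 <- findInterval(d2, breaks)
        cell <- i1 * (length(breaks) + 1L) + i2
        oAgg <- rowsum(as.numeric(obsTotal), cell)
        eAgg <- rowsum(expTotal, cell)
        nAgg <- rowsum(nTuples, cell)
        cellIds <- as.integer(rownames(oAgg))
        d1 <- breaks[cellIds %/% (length(breaks) + 1L)]
        d2 <- breaks[cellIds %% (length(breaks) + 1L)]
        obsTotal <- oAgg[, 1L]; expTotal <- eAgg[, 1L]; nTuples <- nAgg[, 1L]
    }
    out <- data.frame(d1 = as.integer(d1), d2 = as.integer(d2),
                      nTuples = as.numeric(nTuples),
                      observed = as.numeric(obsTotal) / as.numeric(nTuples),
                      expected = as.numeric(expTotal) / as.numeric(nTuples))
    out <- out[as.numeric(obsTotal) >= minCount, , drop = FALSE]
    rownames(out) <- NULL
    fit <- rSquared(out$observed, out$expected, logTransform = TRUE)
    list(table = out, fit = fit)
}

#' Empirical false discovery rate by cluster shuffling
#'
#' Runs the full detection pipeline on the observed cluster set and on
#' `nShuffles` start-shuffled versions (identical configuration), and
#' reports hyperloop counts over a grid of q-value thresholds together with
#' the null/observed ratio -- an empirical FDR estimate.
#'
#' @param cs a [BinnedClusterSet-class].
#' @param config a [pipelineConfig()].
#' @param nShuffles number of shuffled replicates (>= 1).
#' @param seed base RNG seed; replicate s uses `seed + s`.
#' @param thresholds q-value grid.
#' @return A data.frame with columns `threshold`, `observed`, `meanNull`,
#'   `ratio`.
#' @export
empiricalFdr <- function(cs, config, nShuffles = 1L, seed = 1L,
                         thresholds = c(0.01, 0.05, 0.1)) {
    if (nShuffles < 1L) stop("nShuffles must be >= 1")
    countAt <- function(res, thr)
        sum(!is.na(res$records$q_value) & res$records$q_value <= thr)
    obs <- runPipeline(cs, config)
    nullCounts <- matrix(0, nrow = nShuffles, ncol = length(thresholds))
    for (s in seq_len(nShuffles)) {
        shuf <- shuffleClusters(cs, seed + s)
        resS <- runPipeline(shuf, config)
        nullCounts[s, ] <- vapply(thresholds, countAt, numeric(1L), res = resS)
    }
    obsCounts <- vapply(thresholds, countAt, numeric(1L), res = obs)
    data.frame(threshold = thresholds, observed = obsCounts,
               meanNull = colMeans(nullCounts),
               ratio = ifelse(obsCounts > 0, colMeans(nullCounts) / obsCounts, NA_real_))
}
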