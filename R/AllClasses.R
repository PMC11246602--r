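#' @include AllGenerics.R
NULL

#' BinnedClusterSet: binned multi-way interaction clusters of one chromosome
#'
#' A per-chromosome collection of multi-way interaction clusters (SPRITE
#' barcode groups or Pore-C concatemer reads), each reduced to a strictly
#' increasing set of 0-based bin indices at a fixed resolution.
#'
#' @slot chrom chromosome name.
#' @slot resolution bin width in bp.
#' @slot nBins number of bins on the chromosome.
#' @slot clusters list of strictly increasing integer vectors of bin indices,
#'   each of length >= 2.
#' @slot clusterIds character vector of cluster identifiers, parallel to
#'   `clusters`.
#'
#' @seealso [binAndSplit()], [filterClusters()], [mineFrequent()]
#' @export
setClass("BinnedClusterSet",
    slots = c(chrom = "character", resolution = "numeric", nBins = "integer",
              clusters = "list", clusterIds = "character"))

setValidity("BinnedClusterSet", function(object) {
    msg <- NULL
    if (length(object@chrom) != 1L || !nzchar(object@chrom))
        msg <- c(msg, "'chrom' must be a single non-empty string")
    if (length(object@resolution) != 1L || object@resolution <= 0)
        msg <- c(msg, "'resolution' must be a single positive number")
    if (length(object@clusters) != length(object@clusterIds))
        msg <- c(msg, "'clusters' and 'clusterIds' lengths differ")
    for (cl in object@clusters) {
        if (length(cl) < 2L) { msg <- c(msg, "all clusters must have >= 2 bins"); break }
        if (is.unsorted(cl, strictly = TRUE)) { msg <- c(msg, "cluster bins must be strictly increasing"); break }
        if (cl[1L] < 0L || cl[length(cl)] >= object@nBins) { msg <- c(msg, "cluster bins out of range"); break }
    }
    if (is.null(msg)) TRUE else msg
})

#' Construct a BinnedClusterSet
#'
#' @param chrom chromosome name.
#' @param resolution bin width in bp.
#' @param nBins number of bins on the chromosome.
#' @param clusters list of integer vectors of 0-based bin indices; each
#'   vector is deduplicated and sorted, and must retain >= 2 bins.
#' @param clusterIds optional cluster identifiers (defaults to `"c<i>"`).
#' @return A [BinnedClusterSet-class] object.
#' @examples
#' cs <- BinnedClusterSet("chr1", 10000, 100L,
#'                        list(c(0L, 2L, 4L), c(1L, 5L)))
#' numClusters(cs)
#' @export
BinnedClusterSet <- function(chrom, resolution, nBins, clusters,
                             clusterIds = NULL) {
    clusters <- unname(lapply(clusters, function(b) sort(unique(as.integer(b)))))
    if (is.null(clusterIds))
        clusterIds <- if (length(clusters)) paste0("c", seq_along(clusters)) else character(0)
    new("BinnedClusterSet", chrom = as.character(chrom),
        resolution = as.numeric(resolution), nBins = as.integer(nBins),
        clusters = clusters, clusterIds = as.character(clusterIds))
}

#' @rdname hyperloopR-generics
setMethod("chromName", "BinnedClusterSet", function(x) x@chrom)
#' @rdname hyperloopR-generics
setMethod("binResolution", "BinnedClusterSet", function(x) x@resolution)
#' @rdname hyperloopR-generics
setMethod("numBins", "BinnedClusterSet", function(x) x@nBins)
#' @rdname hyperloopR-generics
setMethod("clusterBins", "BinnedClusterSet", function(x) x@clusters)
#' @rdname hyperloopR-generics
setMethod("clusterIds", "BinnedClusterSet", function(x) x@clusterIds)
#' @rdname hyperloopR-generics
setMethod("numClusters", "BinnedClusterSet", function(x) length(x@clusters))

setMethod("show", "BinnedClusterSet", function(object) {
    sz <- lengths(object@clusters)
    cat("BinnedClusterSet on", object@chrom,
        sprintf("(%d bins @ %g bp)\n", object@nBins, object@resolution))
    cat(" ", length(sz), "clusters")
    if (length(sz))
        cat(sprintf(", sizes %d-%d (median %g)", min(sz), max(sz), median(sz)))
    cat("\n")
})

#' ContactMatrix: sparse upper-triangular pairwise contact counts
#'
#' Pairwise contact counts of one chromosome, obtained by decomposing each
#' multi-way cluster into all unordered bin pairs. Only entries with
#' `bin1 < bin2` and count >= 1 are stored.
#'
#' @slot chrom chromosome name.
#' @slot nBins number of bins.
#' @slot bin1,bin2 0-based bin indices of the stored entries, `bin1 < bin2`.
#' @slot counts contact counts of the stored entries.
#' @seealso [buildContactMatrix()], [iceBiases()], [estimateDecay()]
#' @export
setClass("ContactMatrix",
    slots = c(chrom = "character", nBins = "integer",
              bin1 = "integer", bin2 = "integer", counts = "numeric"))

setValidity("ContactMatrix", function(object) {
    msg <- NULL
    ne <- length(object@counts)
    if (length(object@bin1) != ne || length(object@bin2) != ne)
        msg <- c(msg, "triplet slots must have equal length")
    if (ne > 0) {
        if (any(object@bin1 >= object@bin2))
            msg <- c(msg, "entries must satisfy bin1 < bin2")
        if (any(object@bin1 < 0L) || any(object@bin2 >= object@nBins))
            msg <- c(msg, "bin indices out of range")
        if (any(object@counts < 1))
            msg <- c(msg, "stored counts must be >= 1")
    }
    if (is.null(msg)) TRUE else msg
})

#' Construct a ContactMatrix from triplet data
#'
#' @param chrom chromosome name.
#' @param nBins number of bins.
#' @param bin1,bin2 0-based bin indices, `bin1 < bin2` elementwise.
#' @param counts contact counts (>= 1).
#' @return A [ContactMatrix-class].
#' @export
ContactMatrix <- function(chrom, nBins, bin1, bin2, counts) {
    new("ContactMatrix", chrom = as.character(chrom), nBins = as.integer(nBins),
        bin1 = as.integer(bin1), bin2 = as.integer(bin2),
        counts = as.numeric(counts))
}

#' @rdname hyperloopR-generics
setMethod("chromName", "ContactMatrix", function(x) x@chrom)
#' @rdname hyperloopR-generics
setMethod("numBins", "ContactMatrix", function(x) x@nBins)
#' @rdname hyperloopR-generics
setMethod("contactPairs", "ContactMatrix", function(x)
    data.frame(bin1 = x@bin1, bin2 = x@bin2, count = x@counts))
#' @rdname hyperloopR-generics
setMethod("totalContacts", "ContactMatrix", function(x) sum(x@counts))

setMethod("show", "ContactMatrix", function(object) {
    cat("ContactMatrix on", object@chrom,
        sprintf("(%d bins): %d non-zero pairs, %g contacts\n",
                object@nBins, length(object@counts), sum(object@counts)))
})

setAs("ContactMatrix", "sparseMatrix", function(from) {
    Matrix::sparseMatrix(i = from@bin1 + 1L, j = from@bin2 + 1L,
                         x = from@counts, dims = c(from@nBins, from@nBins),
                         symmetric = FALSE)
})

#' BiasVector: per-bin multiplicative technical biases
#'
#' Per-bin multiplicative biases \eqn{b_i} estimated by matrix balancing,
#' normalized so that the mean over valid bins is 1 (a bias of 1 means no
#' bias). Bins with insufficient coverage are flagged invalid and carry `NA`.
#'
#' @slot values numeric vector of biases (`NA` on invalid bins).
#' @slot valid logical vector flagging usable bins.
#' @slot converged whether balancing reached its tolerance.
#' @slot iterations number of balancing iterations performed.
#' @seealso [iceBiases()]
#' @export
setClass("BiasVector",
    slots = c(values = "numeric", valid = "logical",
              converged = "logical", iterations = "integer"))

setValidity("BiasVector", function(object) {
    msg <- NULL
    if (length(object@values) != length(object@valid))
        msg <- c(msg, "'values' and 'valid' lengths differ")
    v <- object@values[object@valid]
    if (length(v)) {
        if (any(!is.finite(v)) || any(v <= 0))
            msg <- c(msg, "valid biases must be positive and finite")
        else if (abs(mean(v) - 1) > 1e-6)
            msg <- c(msg, "valid biases must average to 1")
    }
    if (is.null(msg)) TRUE else msg
})

#' Construct a BiasVector
#'
#' Values are rescaled to mean 1 over valid bins.
#'
#' @param values numeric per-bin biases.
#' @param valid logical mask of usable bins.
#' @param converged,iterations balancing metadata.
#' @return A [BiasVector-class].
#' @export
BiasVector <- function(values, valid = is.finite(values),
                       converged = TRUE, iterations = 0L) {
    values[!valid] <- NA_real_
    if (any(valid)) values[valid] <- values[valid] / mean(values[valid])
    new("BiasVector", values = values, valid = valid,
        converged = converged, iterations = as.integer(iterations))
}

#' Unit bias vector (no technical bias)
#'
#' @param n number of bins.
#' @return A [BiasVector-class] with all biases 1 and all bins valid.
#' @export
unitBiases <- function(n) BiasVector(rep(1, n))

#' @rdname hyperloopR-generics
setMethod("biasValues", "BiasVector", function(x) x@values)
#' @rdname hyperloopR-generics
setMethod("validBins", "BiasVector", function(x) x@valid)

setMethod("show", "BiasVector", function(object) {
    cat(sprintf("BiasVector: %d bins (%d valid), range %.3g-%.3g, %s in %d iterations\n",
                length(object@values), sum(object@valid),
                suppressWarnings(min(object@values, na.rm = TRUE)),
                suppressWarnings(max(object@values, na.rm = TRUE)),
                if (object@converged) "converged" else "NOT converged",
                object@iterations))
})

#' DistanceDecay: genomic-distance decay of pairwise contact probability
#'
#' Per-pair contact probability as a function of genomic distance (in bin
#' units), estimated from bias-normalized counts pooled into equal-occupancy
#' distance bands and smoothed to be monotone non-increasing.
#'
#' @slot dist distances (bin units) covered, strictly increasing.
#' @slot prob per-pair contact probability at each distance.
#' @slot nPairs number of possible valid bin pairs at each distance.
#' @slot trials total raw contact count in the modelled distance range; used
#'   as the binomial trial count by [callLoops()].
#' @slot minDist,maxDist distance range modelled.
#' @seealso [estimateDecay()], [callLoops()]
#' @export
setClass("DistanceDecay",
    slots = c(dist = "integer", prob = "numeric", nPairs = "numeric",
              trials = "numeric", minDist = "integer", maxDist = "integer"))

setValidity("DistanceDecay", function(object) {
    msg <- NULL
    if (length(object@dist) != length(object@prob) ||
        length(object@dist) != length(object@nPairs))
        msg <- c(msg, "parallel slots must have equal length")
    if (length(object@dist) && is.unsorted(object@dist, strictly = TRUE))
        msg <- c(msg, "'dist' must be strictly increasing")
    if (any(object@prob < 0)) msg <- c(msg, "probabilities must be >= 0")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "DistanceDecay", function(object) {
    cat(sprintf("DistanceDecay over distances %d-%d bins (%d distances, %g trials)\n",
                object@minDist, object@maxDist, length(object@dist), object@trials))
})

#' LoopSet: significant pairwise chromatin loops
#'
#' The significant pairwise contacts (loop edges) of one chromosome; their
#' anchors are the only bins that can take part in a hyperloop.
#'
#' @slot chrom chromosome name.
#' @slot resolution bin width in bp.
#' @slot loops data.frame with columns `bin1`, `bin2`, `observed`,
#'   `expected`, `p_value`, `q_value`; one row per significant loop,
#'   `bin1 < bin2`, pairs unique.
#' @slot qThreshold significance threshold that defined the set.
#' @slot nTested number of bin pairs tested (the BH family size).
#' @seealso [callLoops()], [importBedpe()], [filterCandidates()]
#' @export
setClass("LoopSet",
    slots = c(chrom = "character", resolution = "numeric", loops = "data.frame",
              qThreshold = "numeric", nTested = "integer"))

setValidity("LoopSet", function(object) {
    msg <- NULL
    need <- c("bin1", "bin2", "observed", "expected", "p_value", "q_value")
    if (!all(need %in% names(object@loops)))
        msg <- c(msg, "loops data.frame lacks required columns")
    else if (nrow(object@loops)) {
        if (any(object@loops$bin1 >= object@loops$bin2))
            msg <- c(msg, "loops must satisfy bin1 < bin2")
        if (anyDuplicated(object@loops[c("bin1", "bin2")]))
            msg <- c(msg, "loop pairs must be unique")
    }
    if (is.null(msg)) TRUE else msg
})

#' Construct a LoopSet
#'
#' @param chrom chromosome name.
#' @param resolution bin width in bp (`NA` if unknown).
#' @param loops data.frame with columns `bin1`, `bin2`, `observed`,
#'   `expected`, `p_value`, `q_value`.
#' @param qThreshold significance threshold that defined the set.
#' @param nTested number of pairs tested.
#' @return A [LoopSet-class].
#' @export
LoopSet <- function(chrom, resolution, loops, qThreshold = NA_real_,
                    nTested = nrow(loops)) {
    new("LoopSet", chrom = as.character(chrom), resolution = as.numeric(resolution),
        loops = loops, qThreshold = as.numeric(qThreshold),
        nTested = as.integer(nTested))
}

#' @rdname hyperloopR-generics
setMethod("chromName", "LoopSet", function(x) x@chrom)
#' @rdname hyperloopR-generics
setMethod("binResolution", "LoopSet", function(x) x@resolution)
#' @rdname hyperloopR-generics
setMethod("loopPairs", "LoopSet", function(x) x@loops)
#' @rdname hyperloopR-generics
setMethod("loopAnchors", "LoopSet", function(x)
    sort(unique(c(x@loops$bin1, x@loops$bin2))))
#' @rdname hyperloopR-generics
setMethod("numLoops", "LoopSet", function(x) nrow(x@loops))

setMethod("show", "LoopSet", function(object) {
    cat(sprintf("LoopSet on %s @ %g bp: %d loops (of %d tested pairs, q <= %g)\n",
                object@chrom, object@resolution, nrow(object@loops),
                object@nTested, object@qThreshold))
})

#' BackgroundModel: random polymer looping background for multi-way contacts
#'
#' For each hyperloop size k, the gap-distance distribution \eqn{P_k(d)} of
#' pairwise contacts (learned from the size-k decomposition of the clusters)
#' and the total number of random experiments
#' \eqn{N_k = \sum_i \binom{|c_i|}{k}}.
#'
#' @slot chrom chromosome name.
#' @slot nBins bin count n of the chromosome (start-point probability 1/n).
#' @slot dists named list (by k) of data.frames with columns `dist`, `prob`.
#' @slot trials named numeric (by k) of trial counts \eqn{N_k}.
#' @slot interpolation `"interpolate"` (log-linear between observed gap
#'   distances, power-law tail beyond) or `"zero"` (unobserved distances get
#'   probability 0).
#' @seealso [buildBackgroundModel()], [candidateProbability()],
#'   [scoreCandidates()]
#' @export
setClass("BackgroundModel",
    slots = c(chrom = "character", nBins = "integer", dists = "list",
              trials = "numeric", interpolation = "character"))

setValidity("BackgroundModel", function(object) {
    msg <- NULL
    if (!identical(sort(names(object@dists)), sort(names(object@trials))))
        msg <- c(msg, "'dists' and 'trials' must be indexed by the same sizes")
    for (d in object@dists) {
        if (!all(c("dist", "prob") %in% names(d))) {
            msg <- c(msg, "each distribution needs 'dist' and 'prob' columns"); break
        }
        if (nrow(d) && abs(sum(d$prob) - 1) > 1e-9) {
            msg <- c(msg, "each distance distribution must sum to 1"); break
        }
        if (any(d$prob < 0)) { msg <- c(msg, "probabilities must be >= 0"); break }
    }
    if (!object@interpolation %in% c("interpolate", "zero"))
        msg <- c(msg, "interpolation must be 'interpolate' or 'zero'")
    if (is.null(msg)) TRUE else msg
})

#' @rdname hyperloopR-generics
setMethod("chromName", "BackgroundModel", function(x) x@chrom)
#' @rdname hyperloopR-generics
setMethod("numBins", "BackgroundModel", function(x) x@nBins)
#' @rdname hyperloopR-generics
setMethod("trialCounts", "BackgroundModel", function(x) x@trials)
#' @rdname hyperloopR-generics
setMethod("distanceDistributions", "BackgroundModel", function(x) x@dists)

setMethod("show", "BackgroundModel", function(object) {
    cat(sprintf("BackgroundModel on %s (%d bins), sizes: %s\n",
                object@chrom, object@nBins,
                paste(names(object@dists), collapse = ", ")))
    for (k in names(object@trials))
        cat(sprintf("  k=%s: N=%g, %d gap distances\n", k, object@trials[[k]],
                    nrow(object@dists[[k]])))
})
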