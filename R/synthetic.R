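#' Configuration for the synthetic multi-way cluster generator
#'
#' Describes a null generative process matching the assumptions of the
#' background model: cluster sizes from a truncated geometric distribution,
#' a uniform start bin, i.i.d. gap distances from a truncated power law
#' \eqn{P(d) \propto d^{-\alpha}} on `1..dMax`, and (optionally)
#' multiplicative per-bin technical biases injected by thinning each bin
#' with retention probability proportional to its bias. Known co-occurring
#' bin tuples can be planted on top with [plantHyperloops()].
#'
#' @param nBins number of bins of the simulated chromosome.
#' @param nClusters number of null clusters to draw.
#' @param minSize,maxSize truncated range of cluster sizes.
#' @param sizeGeomProb success probability of the truncated geometric
#'   cluster-size distribution, `P(s) ~ (1 - p)^(s - minSize)`.
#' @param alpha power-law exponent of the gap-distance decay (> 0).
#' @param dMax largest gap distance drawn (bin units); the configuration is
#'   infeasible unless `dMax * (maxSize - 1) < nBins`.
#' @param biasSigma standard deviation (log scale) of log-normal per-bin
#'   biases; 0 means no technical bias.
#' @param biasVector explicit per-bin bias vector overriding `biasSigma`.
#' @param planted list of `list(bins=, extraSupport=)` tuples to plant.
#' @param resolution nominal bin width in bp for the emitted cluster set.
#' @param seed RNG seed making the generator deterministic.
#' @return A `synthConfig` list.
#' @seealso [generateNullClusters()], [plantHyperloops()]
#' @export
synthConfig <- function(nBins = 500L, nClusters = 50000L,
                        minSize = 2L, maxSize = 10L, sizeGeomProb = 0.35,
                        alpha = 1.2, dMax = 40L,
                        biasSigma = 0, biasVector = NULL,
                        planted = list(), resolution = 25000,
                        seed = 1L) {
    if (alpha <= 0) stop("alpha must be > 0")
    if (minSize < 2L || maxSize < minSize) stop("need 2 <= minSize <= maxSize")
    if (dMax * (maxSize - 1) >= nBins)
        stop("infeasible config: dMax * (maxSize - 1) must be < nBins")
    if (!is.null(biasVector) && length(biasVector) != nBins)
        stop("biasVector must have one value per bin")
    for (pl in planted) {
        if (any(pl$bins < 0L | pl$bins >= nBins)) stop("planted bins out of range")
        if (pl$extraSupport < 1L) stop("planted extraSupport must be >= 1")
    }
    structure(list(nBins = as.integer(nBins), nClusters = as.integer(nClusters),
                   minSize = as.integer(minSize), maxSize = as.integer(maxSize),
                   sizeGeomProb = sizeGeomProb, alpha = alpha,
                   dMax = as.integer(dMax), biasSigma = biasSigma,
                   biasVector = biasVector, planted = planted,
                   resolution = resolution, seed = as.integer(seed)),
              class = "synthConfig")
}

#' Generate null multi-way clusters with known ground truth
#'
#' For each cluster: draw a size s, a uniform start bin and s - 1 i.i.d.
#' gaps from the truncated power law, joining them one by one; clusters
#' whose span does not fit on the chromosome are redrawn. If biases are
#' configured, each bin of each cluster is then independently retained with
#' probability proportional to its bias (scaled so the largest bias has
#' retention 1) and clusters reduced below 2 bins are dropped. Deterministic
#' given `cfg$seed`.
#'
#' @param cfg a [synthConfig()].
#' @return A list with elements `clusters` (a [BinnedClusterSet-class]) and
#'   `truth` (list: `bias` vector used, `gapProb` distribution used,
#'   `planted` tuples -- empty here; see [plantHyperloops()]).
#' @export
generateNullClusters <- function(cfg) {
    stopifnot(inherits(cfg, "synthConfig"))
    withSeed(cfg$seed, {
        n <- cfg$nBins
        sizeSupport <- cfg$minSize:cfg$maxSize
        sizeProb <- (1 - cfg$sizeGeomProb)^(sizeSupport - cfg$minSize)
        sizeProb <- sizeProb / sum(sizeProb)
        gapProb <- (1:cfg$dMax)^(-cfg$alpha)
        gapProb <- gapProb / sum(gapProb)
        bias <- if (!is.null(cfg$biasVector)) cfg$biasVector
                else if (cfg$biasSigma > 0) exp(rnorm(n, 0, cfg$biasSigma))
                else rep(1, n)

        sizes <- sample(sizeSupport, cfg$nClusters, replace = TRUE, prob = sizeProb)
        drawGaps <- function(m) sample.int(cfg$dMax, m, replace = TRUE, prob = gapProb)
        gapIdx <- rep(seq_along(sizes), sizes - 1L)
        gaps <- drawGaps(length(gapIdx))
        spans <- as.integer(rowsum(gaps, gapIdx))
        starts <- as.integer(floor(runif(cfg$nClusters) * n))
        # redraw clusters whose span does not fit from their start
        repeat {
            badIdx <- which(starts + spans > n - 1L)
            if (!length(badIdx)) break
            gaps2 <- drawGaps(sum(sizes[badIdx] - 1L))
            spans[badIdx] <- as.integer(rowsum(gaps2, rep(seq_along(badIdx),
                                                          sizes[badIdx] - 1L)))
            gaps[gapIdx %in% badIdx] <- gaps2
            starts[badIdx] <- as.integer(floor(runif(length(badIdx)) * n))
        }
        cum <- unlist(lapply(split(gaps, gapIdx), cumsum), use.names = FALSE)
        binVec <- rep(starts, sizes - 1L) + cum
        clusters <- c(split(binVec, gapIdx))
        clusters <- Map(function(s, b) c(s, b), starts, clusters)

        if (any(bias != 1)) {
            retain <- bias / max(bias)
            flat <- unlist(clusters, use.names = FALSE)
            keepBin <- runif(length(flat)) < retain[flat + 1L]
            cl <- rep(seq_along(clusters), lengths(clusters))
            clusters <- split(flat[keepBin], factor(cl[keepBin],
                                                    levels = seq_along(clusters)))
            keep <- lengths(clusters) >= 2L
            clusters <- clusters[keep]
        }
        cs <- BinnedClusterSet("chrS", cfg$resolution, n, unname(clusters),
                               paste0("null", seq_along(clusters)))
        list(clusters = cs,
             truth = list(bias = bias, gapProb = gapProb, planted = list()))
    })
}

#' Plant co-occurring bin tuples into a cluster set
#'
#' Appends `extraSupport` new clusters per tuple, each consisting of exactly
#' the tuple's bins, so the support of each planted tuple increases by
#' exactly `extraSupport`. Planted cluster ids are prefixed `"planted"`.
#'
#' @param cs a [BinnedClusterSet-class].
#' @param tuples list of `list(bins=, extraSupport=)`.
#' @param seed unused placeholder kept for interface stability (the default
#'   planting is deterministic).
#' @return The augmented [BinnedClusterSet-class].
#' @export
plantHyperloops <- function(cs, tuples, seed = 1L) {
    if (!length(tuples)) return(cs)
    newCl <- list(); newIds <- character(0)
    for (t in seq_along(tuples)) {
        b <- sort(unique(as.integer(tuples[[t]]$bins)))
        if (any(b < 0L | b >= cs@nBins)) stop("planted bins out of range")
        m <- tuples[[t]]$extraSupport
        newCl <- c(newCl, rep(list(b), m))
        newIds <- c(newIds, sprintf("planted%d_%d", t, seq_len(m)))
    }
    BinnedClusterSet(cs@chrom, cs@resolution, cs@nBins,
                     c(cs@clusters, newCl), c(cs@clusterIds, newIds))
}

#' Draw random well-separated tuples to plant
#'
#' Convenience helper for simulation studies: draws `nTuples` size-`k`
#' tuples with gaps uniform on `gapRange`, starts uniform over the feasible
#' range, avoiding reuse of any bin across tuples.
#'
#' @param nTuples number of tuples.
#' @param k tuple size.
#' @param nBins chromosome bin count.
#' @param gapRange two-element range of gaps (bin units) between
#'   consecutive tuple bins.
#' @param extraSupport support added per tuple.
#' @param seed RNG seed.
#' @return A list of `list(bins=, extraSupport=)` suitable for
#'   [plantHyperloops()] / [synthConfig()].
#' @export
randomPlantedTuples <- function(nTuples, k = 3L, nBins = 500L,
                                gapRange = c(5L, 30L), extraSupport = 10L,
                                seed = 1L) {
    withSeed(seed, {
        used <- integer(0)
        out <- vector("list", nTuples)
        for (t in seq_len(nTuples)) {
            repeat {
                gaps <- sample(gapRange[1L]:gapRange[2L], k - 1L, replace = TRUE)
                start <- sample.int(nBins - sum(gaps), 1L) - 1L
                bins <- start + c(0L, cumsum(gaps))
                if (!any(bins %in% used)) break
            }
            used <- c(used, bins)
            out[[t]] <- list(bins = bins, extraSupport = as.integer(extraSupport))
        }
        out
    })
}

#' A small illustrative multi-way cluster dataset
#'
#' Ten bins and five clusters (A-E); clusters A-D each contain the bin set
#' \{0, 2, 4, 8\}, so that candidate has support 4, while cluster E touches
#' none of its bins. Useful for demonstrating support counting, mining and
#' the pipeline on a dataset small enough to verify by hand.
#'
#' @param resolution nominal bin width in bp.
#' @return A [BinnedClusterSet-class] with 10 bins and 5 clusters.
#' @examples
#' countSupport(toyClusterSet(), c(0, 2, 4, 8))
#' @export
toyClusterSet <- function(resolution = 10000) {
    BinnedClusterSet("chrT", resolution, 10L,
                     list(c(0L, 2L, 4L, 8L),
                          c(0L, 2L, 4L, 6L, 8L),
                          c(0L, 2L, 3L, 4L, 8L),
                          c(0L, 2L, 4L, 8L, 9L),
                          c(1L, 3L, 5L, 7L)),
                     c("A", "B", "C", "D", "E"))
}
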