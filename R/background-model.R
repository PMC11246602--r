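#' Learn the size-specific gap-distance distribution of pairwise contacts
#'
#' Decomposing every cluster of size s into its \eqn{\binom{s}{k}} subsets
#' of size k and each subset into \eqn{\binom{k}{2}} pairwise contacts is
#' equivalent to giving every pair of the cluster weight
#' \eqn{\binom{s-2}{k-2}} (each pair lies in exactly that many k-subsets).
#' The weighted histogram of pair gap distances `|i - j|` (bin units),
#' normalized to total mass 1, is the distance distribution \eqn{P_k(d)}
#' used by the background model for size-k hyperloops.
#'
#' @param cs a [BinnedClusterSet-class].
#' @param k hyperloop size (>= 3); at least one cluster must have >= k bins.
#' @return A data.frame with columns `dist` (increasing) and `prob`
#'   (summing to 1).
#' @export
learnDistanceDistribution <- function(cs, k) {
    if (k < 3L) stop("k must be >= 3")
    sizes <- lengths(cs@clusters)
    if (!any(sizes >= k))
        stop("no cluster of size >= ", k, "; cannot learn a distribution")
    stacks <- stackBySize(cs@clusters[sizes >= k])
    acc <- new.env(parent = emptyenv())
    dAll <- list(); wAll <- list()
    for (si in seq_along(stacks)) {
        m <- stacks[[si]]
        s <- ncol(m)
        wt <- choose(s - 2, k - 2)
        idx <- combn(s, 2L)
        d <- as.vector(m[, idx[2L, ]] - m[, idx[1L, ]])
        dAll[[si]] <- d
        wAll[[si]] <- rep(wt, length(d))
    }
    agg <- rowsum(unlist(wAll, use.names = FALSE), unlist(dAll, use.names = FALSE))
    out <- data.frame(dist = as.integer(rownames(agg)), prob = agg[, 1L])
    out <- out[order(out$dist), , drop = FALSE]
    out$prob <- out$prob / sum(out$prob)
    rownames(out) <- NULL
    out
}

#' Number of random experiments for size-k hyperloops
#'
#' \eqn{N_k = \sum_i \binom{|c_i|}{k}}: every size-k subset of every cluster
#' is one random draw of a k-way contact; clusters smaller than k
#' contribute 0.
#'
#' @param cs a [BinnedClusterSet-class].
#' @param k hyperloop size (>= 3).
#' @return The trial count (numeric; exact integer value).
#' @export
trialCount <- function(cs, k) {
    if (k < 3L) stop("k must be >= 3")
    sum(choose(lengths(cs@clusters), k))
}

#' Build the random polymer looping background model
#'
#' Learns the gap-distance distribution and trial count for each requested
#' hyperloop size with at least one large-enough cluster.
#'
#' @param cs a [BinnedClusterSet-class].
#' @param kRange integer vector of hyperloop sizes (all >= 3).
#' @param interpolation handling of gap distances absent from the learned
#'   histogram: `"interpolate"` (log-linear between the nearest observed
#'   distances, power-law tail beyond the largest) or `"zero"`.
#' @return A [BackgroundModel-class].
#' @export
buildBackgroundModel <- function(cs, kRange = 3:5,
                                 interpolation = c("interpolate", "zero")) {
    interpolation <- match.arg(interpolation)
    sizes <- lengths(cs@clusters)
    dists <- list(); trials <- numeric(0)
    for (k in sort(unique(as.integer(kRange)))) {
        if (!any(sizes >= k)) next
        dists[[as.character(k)]] <- learnDistanceDistribution(cs, k)
        trials[[as.character(k)]] <- trialCount(cs, k)
    }
    if (!length(dists)) stop("no cluster large enough for any requested size")
    new("BackgroundModel", chrom = cs@chrom, nBins = cs@nBins,
        dists = dists, trials = trials, interpolation = interpolation)
}

# Probability P_k(d) for (possibly unobserved) gap distances, vectorised.
# Interpolation: log-linear in log(d) between observed neighbours; below the
# smallest observed distance the smallest observed probability is reused;
# beyond the largest, a power-law tail fitted to the upper half of the
# observed distances extrapolates (slope capped at 0).
gapProbability <- function(tab, d, interpolation = "interpolate") {
    p <- tab$prob[match(d, tab$dist)]
    miss <- is.na(p)
    if (!any(miss)) return(p)
    if (interpolation == "zero") {
        p[miss] <- 0
        return(p)
    }
    dmin <- tab$dist[1L]; dmax <- tab$dist[nrow(tab)]
    dm <- d[miss]
    pm <- numeric(length(dm))
    lo <- dm < dmin
    pm[lo] <- tab$prob[1L]
    inside <- dm > dmin & dm < dmax
    if (any(inside))
        pm[inside] <- exp(approx(log(tab$dist), log(tab$prob),
                                 xout = log(dm[inside]))$y)
    above <- dm > dmax
    if (any(above)) {
        upper <- tab[tab$dist >= dmax / 2, , drop = FALSE]
        slope <- if (nrow(upper) >= 2L) {
            lx <- log(upper$dist); ly <- log(upper$prob)
            sum((lx - mean(lx)) * (ly - mean(ly))) / sum((lx - mean(lx))^2)
        } else -1
        slope <- min(slope, 0)
        pm[above] <- tab$prob[nrow(tab)] * (dm[above] / dmax)^slope
    }
    p[miss] <- pm
    p
}

#' Sampling probability of one hyperloop candidate
#'
#' The probability of generating the candidate in one random experiment:
#' sample a start point uniformly (probability `1/n`), then join pairwise
#' loops between *adjacent* bins, each gap d contributing \eqn{P_k(d)}.
#' Restricting to adjacent gaps is the maximum-spanning-tree approximation:
#' under a power-law decay the path through consecutive bins is the most
#' probable connected subgraph explaining the co-location.
#'
#' @param bins integer vector of bin indices (any order; sorted internally).
#' @param model a [BackgroundModel-class] with a distribution for
#'   `length(bins)`.
#' @return The raw (bias-free) per-experiment probability.
#' @examples
#' ## p(ABCD) = (1/n) * P(d_AB) * P(d_BC) * P(d_CD)
#' @export
candidateProbability <- function(bins, model) {
    bins <- sort(unique(as.integer(bins)))
    k <- length(bins)
    tab <- model@dists[[as.character(k)]]
    if (is.null(tab))
        stop("no distance distribution learned for size k = ", k)
    gaps <- diff(bins)
    prod(gapProbability(tab, gaps, model@interpolation)) / model@nBins
}

#' Score hyperloop candidates under the background model
#'
#' For each candidate: the bias-corrected per-experiment probability
#' \eqn{p^* = p \, b_1 \cdots b_k} (clipped to 1 with a warning), the
#' expected frequency \eqn{\lambda^* = p^* N_k}, and the upper-tail
#' binomial p-value \eqn{P(K \ge \mathrm{observed})} with \eqn{N_k} trials,
#' computed via the regularized incomplete beta function (numerically
#' stable for large \eqn{N_k}). Candidates touching an invalid-bias bin are
#' dropped (count in attribute `nRejected`).
#'
#' @param cands data.frame from [mineFrequent()] / [filterCandidates()]
#'   (list-column `bins`, column `support`).
#' @param model a [BackgroundModel-class].
#' @param bias a [BiasVector-class] ([unitBiases()] for no correction).
#' @return A data.frame with one row per scored candidate: `chrom`, a
#'   list-column `bins`, `k`, `observed`, `p_raw`, `p_star`, `expected`
#'   (\eqn{\lambda^*}) and `p_value`. In `"zero"` interpolation mode,
#'   candidates whose probability vanishes are untestable and get
#'   `p_value = NA`.
#' @export
scoreCandidates <- function(cands, model, bias) {
    nIn <- nrow(cands)
    if (nIn == 0L) {
        out <- data.frame(chrom = character(0), bins = I(list()),
                          k = integer(0), observed = numeric(0),
                          p_raw = numeric(0), p_star = numeric(0),
                          expected = numeric(0), p_value = numeric(0))
        attr(out, "nRejected") <- 0L
        return(out)
    }
    ok <- vapply(cands$bins, function(b) all(bias@valid[b + 1L]), logical(1L))
    cands <- cands[ok, , drop = FALSE]
    ks <- lengths(cands$bins)
    pRaw <- vapply(cands$bins, candidateProbability, numeric(1L), model = model)
    bprod <- vapply(cands$bins, function(b) prod(bias@values[b + 1L]), numeric(1L))
    pStar <- pRaw * bprod
    if (any(pStar > 1)) {
        warning(sum(pStar > 1), " candidate probabilities clipped to 1")
        pStar <- pmin(pStar, 1)
    }
    Nk <- model@trials[as.character(ks)]
    pval <- pbinom(cands$support - 1, Nk, pStar, lower.tail = FALSE)
    if (model@interpolation == "zero") pval[pStar == 0] <- NA_real_
    out <- data.frame(chrom = model@chrom, k = as.integer(ks),
                      observed = as.numeric(cands$support), p_raw = pRaw,
                      p_star = pStar, expected = pStar * Nk, p_value = pval)
    out$bins <- cands$bins
    out <- out[c("chrom", "bins", "k", "observed", "p_raw", "p_star",
                 "expected", "p_value")]
    rownames(out) <- NULL
    attr(out, "nRejected") <- sum(!ok)
    out
}

#' Size-stratified Benjamini-Hochberg correction
#'
#' Standard BH applied independently within each (chromosome, hyperloop
#' size) group: candidate families of different sizes have very different
#' null behaviour, so they are corrected as separate families.
#'
#' @param records data.frame from [scoreCandidates()] (columns `chrom`, `k`,
#'   `p_value`).
#' @return `records` with a `q_value` column added (NA p-values stay NA).
#' @export
groupedBH <- function(records) {
    q <- rep(NA_real_, nrow(records))
    if (nrow(records)) {
        grp <- paste(records$chrom, records$k)
        for (g in unique(grp)) {
            sel <- grp == g & !is.na(records$p_value)
            q[sel] <- p.adjust(records$p_value[sel], method = "BH")
        }
    }
    records$q_value <- q
    records
}
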