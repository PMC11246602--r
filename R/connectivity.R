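#' Test whether a candidate's bins are connected by loop edges
#'
#' Builds the graph whose nodes are the candidate's bins and whose edges are
#' the loop pairs falling inside the candidate, and reports whether it forms
#' a single connected component (union-find). Spatial colocalization only
#' requires the loci to be connected -- transitivity of spatial proximity
#' closes the rest of the clique -- so connectivity, not completeness, is
#' tested.
#'
#' @param bins integer vector of distinct bin indices (>= 2).
#' @param loops a [LoopSet-class].
#' @return `TRUE` iff the induced loop graph on `bins` is connected.
#' @export
isConnected <- function(bins, loops) {
    bins <- sort(unique(as.integer(bins)))
    if (length(bins) < 2L) stop("a candidate needs >= 2 bins")
    lp <- loops@loops
    sel <- lp$bin1 %in% bins & lp$bin2 %in% bins
    .unionFindConnected(bins, lp$bin1[sel], lp$bin2[sel])
}

# union-find over the candidate's own (tiny) node set
.unionFindConnected <- function(bins, e1, e2) {
    k <- length(bins)
    if (length(e1) < k - 1L) return(FALSE)
    parent <- seq_len(k)
    find <- function(a) { while (parent[a] != a) { parent[a] <<- parent[parent[a]]; a <- parent[a] }; a }
    i1 <- match(e1, bins); i2 <- match(e2, bins)
    for (e in seq_along(i1)) {
        r1 <- find(i1[e]); r2 <- find(i2[e])
        if (r1 != r2) parent[r1] <- r2
    }
    length(unique(vapply(seq_len(k), find, integer(1L)))) == 1L
}

#' Filter hyperloop candidates by loop connectivity
#'
#' Keeps the candidates whose bins form a connected graph under the
#' significant pairwise loops; candidates touching a bin flagged invalid by
#' [iceBiases()] are dropped first (their bias product, hence corrected
#' expected frequency, is undefined). Input order is preserved.
#'
#' @param itemsets data.frame from [mineFrequent()] (list-column `bins`,
#'   column `support`).
#' @param loops a [LoopSet-class].
#' @param bias optional [BiasVector-class] used to drop candidates with
#'   invalid bins.
#' @return The filtered data.frame, with attributes `nIn`, `nOut` and
#'   `nInvalidBias` recording the filtering counts.
#' @export
filterCandidates <- function(itemsets, loops, bias = NULL) {
    nIn <- nrow(itemsets)
    keep <- rep(TRUE, nIn)
    nInvalid <- 0L
    if (!is.null(bias) && nIn) {
        ok <- vapply(itemsets$bins, function(b) all(bias@valid[b + 1L]), logical(1L))
        nInvalid <- sum(!ok)
        keep <- ok
    }
    if (any(keep)) {
        anchors <- loopAnchors(loops)
        lp <- loops@loops
        idx <- which(keep)
        # cheap prefilter: every bin must be a loop anchor, else some node is isolated
        onAnchors <- vapply(itemsets$bins[idx],
                            function(b) all(b %in% anchors), logical(1L))
        keep[idx[!onAnchors]] <- FALSE
        for (r in idx[onAnchors]) {
            b <- itemsets$bins[[r]]
            sel <- lp$bin1 %in% b & lp$bin2 %in% b
            keep[r] <- .unionFindConnected(b, lp$bin1[sel], lp$bin2[sel])
        }
    }
    out <- itemsets[keep, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "nIn") <- nIn
    attr(out, "nOut") <- nrow(out)
    attr(out, "nInvalidBias") <- nInvalid
    out
}
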