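#' Mine frequent multi-way bin sets with FP-growth
#'
#' Enumerates exactly the bin sets S with `kMin <= |S| <= kMax` whose
#' support (the number of clusters containing every bin of S) is at least
#' `minFreq`, using an FP-growth frequent itemset miner. Output order is
#' deterministic: by size, then lexicographically by bin indices.
#'
#' @param cs a [BinnedClusterSet-class]; its clusters are the transactions.
#' @param minFreq minimum support threshold (>= 1).
#' @param kMin minimum itemset size; must be >= 3 (multi-way contacts).
#' @param kMax maximum itemset size.
#' @param restrictItems optional integer vector of bins; transactions are
#'   intersected with it before mining (e.g. to restrict to loop anchors).
#' @return A data.frame with a list-column `bins` (sorted integer vectors)
#'   and a numeric column `support`.
#' @examples
#' cs <- toyClusterSet()
#' mineFrequent(cs, minFreq = 4, kMin = 3, kMax = 5)
#' @export
mineFrequent <- function(cs, minFreq, kMin = 3L, kMax = 5L, restrictItems = NULL) {
    if (minFreq < 1) stop("minFreq must be >= 1")
    if (kMin < 3L) stop("kMin must be >= 3: hyperloops are multi-way contacts")
    if (kMax < kMin) stop("kMax must be >= kMin")
    tx <- cs@clusters
    if (!is.null(restrictItems)) {
        restrictItems <- as.integer(restrictItems)
        tx <- lapply(tx, function(b) b[b %in% restrictItems])
    }
    tx <- tx[lengths(tx) >= kMin]
    if (!length(tx))
        return(data.frame(bins = I(list()), support = numeric(0)))
    res <- .fpgrowth_mine(tx, as.numeric(minFreq), as.integer(kMin), as.integer(kMax))
    sets <- res$itemsets
    ord <- orderItemsets(sets)
    data.frame(bins = I(sets[ord]), support = res$support[ord])
}

#' Support of one bin set
#'
#' The number of clusters containing every bin of `bins` (the frequency of
#' the corresponding hyperloop candidate), by exact containment counting.
#'
#' @param cs a [BinnedClusterSet-class].
#' @param bins integer vector of distinct bin indices.
#' @return The integer support count.
#' @examples
#' countSupport(toyClusterSet(), c(0, 2, 4, 8))  # 4
#' @export
countSupport <- function(cs, bins) {
    bins <- sort(unique(as.integer(bins)))
    sum(vapply(cs@clusters, function(cl) all(bins %in% cl), logical(1L)))
}
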