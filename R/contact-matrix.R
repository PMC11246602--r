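#' Decompose a cluster into pairwise contacts
#'
#' A multi-way cluster of k bins yields all `k * (k - 1) / 2` unordered bin
#' pairs, the same decomposition used to build a Hi-C-like contact matrix
#' from multi-way interaction data.
#'
#' @param bins integer vector of distinct bin indices (length >= 2).
#' @return A two-column integer matrix of pairs with `[, 1] < [, 2]`.
#' @examples
#' decomposePairwise(c(0L, 2L, 4L, 8L))  # 6 pairs
#' @export
decomposePairwise <- function(bins) {
    bins <- sort(unique(as.integer(bins)))
    if (length(bins) < 2L) stop("a cluster needs >= 2 distinct bins")
    idx <- combn(length(bins), 2L)
    cbind(bins[idx[1L, ]], bins[idx[2L, ]])
}

#' Build the pairwise contact matrix of a cluster set
#'
#' Every cluster contributes one count to each of its unordered bin pairs
#' (bins within a cluster are already deduplicated), so
#' \eqn{M_{ij} = \#\{c : i \in c, j \in c\}}.
#'
#' @param cs a [BinnedClusterSet-class].
#' @return A [ContactMatrix-class].
#' @export
buildContactMatrix <- function(cs) {
    stacks <- stackBySize(cs@clusters)
    n <- as.numeric(cs@nBins)
    keys <- vector("list", length(stacks))
    for (si in seq_along(stacks)) {
        m <- stacks[[si]]
        s <- ncol(m)
        idx <- combn(s, 2L)
        i <- as.vector(m[, idx[1L, ]])
        j <- as.vector(m[, idx[2L, ]])
        keys[[si]] <- i * n + j
    }
    keys <- sort(unlist(keys, use.names = FALSE))
    if (!length(keys))
        return(ContactMatrix(cs@chrom, cs@nBins, integer(0), integer(0), numeric(0)))
    r <- rle(keys)
    i <- floor(r$values / n)
    j <- r$values - i * n
    ContactMatrix(cs@chrom, cs@nBins, i, j, r$lengths)
}

#' Estimate per-bin biases by iterative matrix balancing
#'
#' Solves the factorization \eqn{M_{ij} = B_i B_j M^*_{ij}} under the
#' equal-visibility constraint that the balanced matrix has equal marginals
#' over entries with \eqn{|i - j| > 1} (the diagonal and adjacent bins are
#' excluded from the constraint), by alternating marginal scaling (iterative
#' correction). The returned biases are rescaled to mean 1 over valid bins,
#' so a bias of 1 means no technical bias.
#'
#' Bins whose restricted marginal is zero, or below `minMarginalFraction`
#' times the median positive marginal, are flagged invalid and excluded.
#'
#' @param cm a [ContactMatrix-class].
#' @param maxIter maximum number of balancing iterations.
#' @param tol convergence tolerance on the maximum relative marginal
#'   deviation.
#' @param minMarginalFraction low-coverage masking threshold as a fraction
#'   of the median positive marginal (0 keeps every bin with a non-zero
#'   marginal).
#' @param decayAware if `TRUE`, each bin's marginal is compared against its
#'   distance-decay expected marginal (recomputed every iteration from the
#'   per-distance mean of the normalized matrix) instead of the common mean
#'   marginal. Near a chromosome end the close -- hence contact-rich --
#'   partner bins are missing on one side, so plain marginal scaling folds
#'   this coverage geometry into the bias estimate; the decay-normalized
#'   scheme leaves it out and isolates the factorizable technical bias.
#' @return A [BiasVector-class]; its `converged`/`iterations` slots report
#'   the balancing outcome.
#' @export
iceBiases <- function(cm, maxIter = 200L, tol = 1e-5, minMarginalFraction = 0,
                      decayAware = FALSE) {
    if (!length(cm@counts)) stop("contact matrix is empty")
    far <- (cm@bin2 - cm@bin1) > 1L
    i <- cm@bin1[far]; j <- cm@bin2[far]; x <- cm@counts[far]
    n <- cm@nBins
    if (!length(x)) stop("no entries with |i - j| > 1; matrix is degenerate")
    s0 <- accumMarginal(i, j, x, n)
    thr <- minMarginalFraction * median(s0[s0 > 0])
    valid <- s0 > 0 & s0 >= thr
    if (!any(valid)) stop("all bins masked as invalid; matrix is degenerate")
    use <- valid[i + 1L] & valid[j + 1L]
    i <- i[use]; j <- j[use]; x <- x[use]
    if (!length(x)) stop("no usable entries between valid bins")
    d <- j - i
    ds <- sort(unique(d))
    vnum <- as.numeric(valid)
    nPairs <- vapply(ds, function(dd)
        sum(vnum[seq_len(n - dd)] * vnum[seq_len(n - dd) + dd]), numeric(1L))
    b <- rep(1, n)
    converged <- FALSE
    iter <- 0L
    while (iter < maxIter) {
        iter <- iter + 1L
        w <- x / (b[i + 1L] * b[j + 1L])
        s <- accumMarginal(i, j, w, n)
        if (decayAware) {
            fnum <- numeric(length(ds))
            agg <- rowsum(w, d)
            fnum[match(as.integer(rownames(agg)), ds)] <- agg[, 1L]
            f <- fnum / nPairs
            E <- numeric(n)
            for (di in seq_along(ds)) {
                dd <- ds[di]; fd <- f[di]
                if (fd == 0) next
                E[(dd + 1L):n] <- E[(dd + 1L):n] + fd * vnum[seq_len(n - dd)]
                E[seq_len(n - dd)] <- E[seq_len(n - dd)] + fd * vnum[(dd + 1L):n]
            }
            rel <- ifelse(valid & E > 0, s / E, 1)
            rel <- rel / mean(rel[valid])
        } else {
            rel <- s / mean(s[valid])
        }
        dev <- max(abs(rel[valid] - 1))
        b[valid] <- b[valid] * rel[valid]
        if (dev < tol) { converged <- TRUE; break }
    }
    b[!valid] <- NA_real_
    BiasVector(b, valid, converged, iter)
}

#' Export / import a contact matrix as 3-column text
#'
#' The interaction dialect `bin_i<TAB>bin_j<TAB>count` (0-based bins,
#' upper triangle), plus a `#` header with chromosome and bin count.
#'
#' @param cm a [ContactMatrix-class].
#' @param path file path.
#' @return `exportContacts` returns `path` invisibly; `importContacts`
#'   returns a [ContactMatrix-class].
#' @export
exportContacts <- function(cm, path) {
    hdr <- c(sprintf("# chrom=%s", cm@chrom), sprintf("# n_bins=%d", cm@nBins))
    writeLines(c(hdr, sprintf("%d\t%d\t%g", cm@bin1, cm@bin2, cm@counts)), path)
    invisible(path)
}

#' @rdname exportContacts
#' @export
importContacts <- function(path) {
    lines <- readLines(path)
    hdr <- grep("^#", lines, value = TRUE)
    chrom <- sub("^# chrom=", "", grep("^# chrom=", hdr, value = TRUE)[1L])
    nb <- as.integer(sub("^# n_bins=", "", grep("^# n_bins=", hdr, value = TRUE)[1L]))
    body <- lines[!grepl("^#", lines) & nzchar(lines)]
    if (!length(body))
        return(ContactMatrix(chrom, nb, integer(0), integer(0), numeric(0)))
    m <- do.call(rbind, lapply(strsplit(body, "\t"), as.numeric))
    ContactMatrix(chrom, nb, m[, 1L], m[, 2L], m[, 3L])
}

#' Export per-bin biases as 2-column text (`bin<TAB>bias`, NA for invalid)
#'
#' @param bias a [BiasVector-class].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
exportBiases <- function(bias, path) {
    writeLines(sprintf("%d\t%s", seq_along(bias@values) - 1L,
                       ifelse(bias@valid, sprintf("%.10g", bias@values), "NA")),
               path)
    invisible(path)
}
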