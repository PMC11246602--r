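# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    force(code)
}

# Stack clusters into one integer matrix per distinct size: list of
# size -> (n_clusters x size) matrix of bin indices.  Vectorises per-pair /
# per-subset enumeration over tens of thousands of clusters.
stackBySize <- function(clusters) {
    sizes <- lengths(clusters)
    out <- list()
    for (s in sort(unique(sizes))) {
        sel <- clusters[sizes == s]
        out[[as.character(s)]] <- matrix(unlist(sel, use.names = FALSE),
                                         ncol = s, byrow = TRUE)
    }
    out
}

# Weighted pool-adjacent-violators fit enforcing a non-increasing sequence.
pavaNonIncreasing <- function(y, w) {
    stopifnot(length(y) == length(w))
    n <- length(y)
    if (n <= 1L) return(y)
    vals <- numeric(n); wts <- numeric(n); len <- integer(n)
    top <- 0L
    for (i in seq_len(n)) {
        top <- top + 1L
        vals[top] <- y[i]; wts[top] <- w[i]; len[top] <- 1L
        while (top > 1L && vals[top - 1L] < vals[top]) {
            wsum <- wts[top - 1L] + wts[top]
            vals[top - 1L] <- (vals[top - 1L] * wts[top - 1L] +
                               vals[top] * wts[top]) / wsum
            wts[top - 1L] <- wsum
            len[top - 1L] <- len[top - 1L] + len[top]
            top <- top - 1L
        }
    }
    rep(vals[seq_len(top)], times = len[seq_len(top)])
}

# Accumulate entry weights into per-bin marginals (bins 0-based, n bins).
accumMarginal <- function(i, j, w, n) {
    s <- numeric(n)
    a <- rowsum(c(w, w), c(i, j))
    s[as.integer(rownames(a)) + 1L] <- a[, 1L]
    s
}

# Sort a list of integer vectors by length, then lexicographically.
orderItemsets <- function(sets) {
    if (length(sets) == 0L) return(integer(0))
    ks <- lengths(sets)
    kmax <- max(ks)
    pad <- vapply(sets, function(b) c(b, rep(-1L, kmax - length(b))), integer(kmax))
    if (kmax == 1L) pad <- matrix(pad, nrow = 1L)
    do.call(order, c(list(ks), lapply(seq_len(kmax), function(r) pad[r, ])))
}

itemsetKey <- function(bins) paste(bins, collapse = ",")
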