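# Independent brute-force oracles used across the suite.

# enumerate every k-subset (kmin..kmax) of every cluster and count supports
bruteItemsets <- function(clusters, minfreq, kmin, kmax) {
    keys <- unlist(lapply(clusters, function(cl) {
        if (length(cl) < kmin) return(NULL)
        ks <- kmin:min(kmax, length(cl))
        unlist(lapply(ks, function(k)
            apply(combn(cl, k), 2L, paste, collapse = ",")))
    }))
    if (is.null(keys)) return(data.frame(key = character(0), support = numeric(0)))
    tab <- table(keys)
    tab <- tab[tab >= minfreq]
    data.frame(key = names(tab), support = as.numeric(tab),
               stringsAsFactors = FALSE)
}

bruteSupport <- function(clusters, bins)
    sum(vapply(clusters, function(cl) all(bins %in% cl), logical(1L)))

# itemset data.frame from mineFrequent -> sorted key/support table
minedKeyTable <- function(fi) {
    df <- data.frame(key = vapply(fi$bins, paste, "", collapse = ","),
                     support = fi$support, stringsAsFactors = FALSE)
    df[order(df$key), , drop = FALSE]
}

# connectivity by boolean transitive closure (reachability matrix power)
closureConnected <- function(bins, edges1, edges2) {
    k <- length(bins)
    adj <- diag(TRUE, k)
    i1 <- match(edges1, bins); i2 <- match(edges2, bins)
    for (e in seq_along(i1)) {
        adj[i1[e], i2[e]] <- TRUE
        adj[i2[e], i1[e]] <- TRUE
    }
    for (step in seq_len(k)) adj <- adj | (adj %*% adj > 0)
    all(adj)
}

# random cluster set over nBins bins, sizes 2..maxSize
randomClusterSet <- function(nBins, nClusters, maxSize = 6L, seed = 1L,
                             minSize = 2L) {
    set.seed(seed)
    cl <- lapply(seq_len(nClusters), function(i) {
        s <- sample(minSize:maxSize, 1L)
        sort(sample.int(nBins, min(s, nBins)) - 1L)
    })
    cl <- cl[lengths(cl) >= 2L]
    BinnedClusterSet("chrR", 10000, as.integer(nBins), cl)
}

# direct summation of the upper binomial tail
bruteBinomTail <- function(obs, n, p) sum(dbinom(seq(obs, n), n, p))

# complete loop graph over given bins
completeLoopSet <- function(bins, chrom = "chrT", resolution = 10000) {
    pr <- t(combn(sort(bins), 2L))
    LoopSet(chrom, resolution,
            data.frame(bin1 = pr[, 1L], bin2 = pr[, 2L], observed = NA_real_,
                       expected = NA_real_, p_value = NA_real_,
                       q_value = NA_real_))
}

binsKey <- function(binsList) vapply(binsList, paste, "", collapse = ",")
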