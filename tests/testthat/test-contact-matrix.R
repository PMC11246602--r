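test_that("pairwise decomposition yields all k(k-1)/2 unordered pairs", {
    expect_equal(nrow(decomposePairwise(c(0, 2, 4, 8))), 6L)
    expect_equal(decomposePairwise(c(5, 1)), cbind(1L, 5L))
    bins <- c(3L, 7L, 10L, 15L, 21L, 40L)
    got <- decomposePairwise(bins)
    ref <- t(combn(bins, 2L))
    expect_equal(got[order(got[, 1L], got[, 2L]), ], ref)
    expect_error(decomposePairwise(7L), ">= 2")
})

test_that("contact matrix counts cluster co-occurrences exactly", {
    cs <- BinnedClusterSet("chr1", 1000, 10L,
                           list(c(0L, 1L), c(0L, 1L), c(0L, 2L)))
    cm <- buildContactMatrix(cs)
    cp <- contactPairs(cm)
    expect_equal(cp$count[cp$bin1 == 0 & cp$bin2 == 1], 2)
    expect_equal(cp$count[cp$bin1 == 0 & cp$bin2 == 2], 1)
    expect_false(any(cp$bin1 == 1 & cp$bin2 == 2))

    empty <- BinnedClusterSet("chr1", 1000, 10L, list())
    expect_equal(nrow(contactPairs(buildContactMatrix(empty))), 0L)
})

test_that("contact matrix matches the brute-force double loop and conserves pairs", {
    cs <- randomClusterSet(30, 50, maxSize = 7L, seed = 2)
    cm <- buildContactMatrix(cs)
    cp <- contactPairs(cm)
    ref <- matrix(0, 30, 30)
    for (cl in clusterBins(cs))
        for (a in seq_along(cl)) for (b in seq_along(cl))
            if (cl[a] < cl[b]) ref[cl[a] + 1, cl[b] + 1] <- ref[cl[a] + 1, cl[b] + 1] + 1
    got <- matrix(0, 30, 30)
    got[cbind(cp$bin1 + 1, cp$bin2 + 1)] <- cp$count
    expect_equal(got, ref)
    expect_equal(totalContacts(cm), sum(choose(lengths(clusterBins(cs)), 2)))

    # invariant to cluster order
    perm <- sample(numClusters(cs))
    cs2 <- BinnedClusterSet("chr1", 1000, 30L, clusterBins(cs)[perm])
    cp2 <- contactPairs(buildContactMatrix(cs2))
    expect_equal(cp2, cp)
})

test_that("balancing a near-uniform matrix returns biases close to 1", {
    n <- 30L
    pr <- t(combn(n, 2L)) - 1L
    cm <- ContactMatrix("chr1", n, pr[, 1L], pr[, 2L], rep(50, nrow(pr)))
    b <- iceBiases(cm)
    expect_true(all(validBins(b)))
    expect_equal(mean(biasValues(b)), 1, tolerance = 1e-8)
    expect_true(all(abs(biasValues(b) - 1) < 0.05))
})

test_that("balancing recovers an imposed diagonal distortion (D M0 D oracle)", {
    set.seed(4)
    n <- 40L
    pr <- t(combn(n, 2L)) - 1L
    base <- 200 / (1 + abs(pr[, 1L] - pr[, 2L]))
    cm0 <- ContactMatrix("chr1", n, pr[, 1L], pr[, 2L], round(base) + 1)
    b0 <- iceBiases(cm0, maxIter = 2000, tol = 1e-10)
    # exactly balanced matrix, then distort with known D
    m0 <- contactPairs(cm0)
    bal <- m0$count / (biasValues(b0)[m0$bin1 + 1] * biasValues(b0)[m0$bin2 + 1])
    D <- exp(rnorm(n, 0, 0.5))
    cmD <- ContactMatrix("chr1", n, m0$bin1, m0$bin2,
                         100 * bal * D[m0$bin1 + 1] * D[m0$bin2 + 1])
    bD <- iceBiases(cmD, maxIter = 2000, tol = 1e-10)
    expect_gt(cor(biasValues(bD), D / mean(D)), 0.99)
})

test_that("the balanced matrix satisfies the equal-visibility equations", {
    cs <- randomClusterSet(20, 200, maxSize = 5L, seed = 6)
    cm <- buildContactMatrix(cs)
    b <- iceBiases(cm, maxIter = 2000, tol = 1e-8)
    cp <- contactPairs(cm)
    far <- cp$bin2 - cp$bin1 > 1
    w <- cp$count[far] / (biasValues(b)[cp$bin1[far] + 1] *
                          biasValues(b)[cp$bin2[far] + 1])
    marg <- numeric(20)
    acc <- rowsum(c(w, w), c(cp$bin1[far], cp$bin2[far]))
    marg[as.integer(rownames(acc)) + 1] <- acc[, 1]
    marg <- marg[validBins(b)]
    expect_lt(max(abs(marg / mean(marg) - 1)), 1e-6)
})

test_that("degenerate matrices are rejected with informative errors", {
    expect_error(iceBiases(ContactMatrix("c", 5L, integer(0), integer(0),
                                         numeric(0))), "empty")
    nearOnly <- ContactMatrix("c", 5L, c(0L, 1L), c(1L, 2L), c(3, 4))
    expect_error(iceBiases(nearOnly), "degenerate")
})

test_that("contact matrix and bias text formats round-trip", {
    cs <- randomClusterSet(15, 40, seed = 3)
    cm <- buildContactMatrix(cs)
    f <- withr::local_tempfile()
    exportContacts(cm, f)
    back <- importContacts(f)
    expect_equal(contactPairs(back), contactPairs(cm))
    expect_equal(numBins(back), numBins(cm))

    b <- iceBiases(cm)
    fb <- withr::local_tempfile()
    exportBiases(b, fb)
    tab <- read.delim(fb, header = FALSE)
    expect_equal(tab$V2, round(biasValues(b), 10), tolerance = 1e-8)
})
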