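# a matrix whose counts follow a deterministic decay c0 / d
decayMatrix <- function(n, c0 = 600) {
    pr <- t(combn(n, 2L)) - 1L
    d <- pr[, 2L] - pr[, 1L]
    ContactMatrix("chr1", as.integer(n), pr[, 1L], pr[, 2L], round(c0 / d) + 1)
}

test_that("distance decay estimates are monotone and conserve contact mass", {
    cm <- decayMatrix(30)
    b <- unitBiases(30)
    dec <- estimateDecay(cm, b, nBands = 10)
    expect_true(all(diff(dec@prob) <= 1e-12))
    # conservation: per-pair probabilities times pair counts sum to 1
    expect_equal(sum(dec@prob * dec@nPairs), 1, tolerance = 1e-9)

    one <- estimateDecay(cm, b, nBands = 1)
    expect_equal(length(unique(one@prob)), 1L)
    expect_equal(unique(one@prob), 1 / sum(one@nPairs), tolerance = 1e-12)

    expect_error(estimateDecay(cm, b, minDist = 1), "minDist")
})

test_that("per-distance estimates match a brute-force groupby mean", {
    cm <- decayMatrix(30)
    b <- unitBiases(30)
    # one band per distance and a strictly decreasing profile: PAVA is a no-op
    dec <- estimateDecay(cm, b, nBands = 1000)
    cp <- contactPairs(cm)
    cp$d <- cp$bin2 - cp$bin1
    cp <- cp[cp$d >= 2, ]
    tot <- sum(cp$count)
    for (d in unique(cp$d)) {
        ref <- sum(cp$count[cp$d == d]) / (tot * (30 - d))
        expect_equal(dec@prob[dec@dist == d], ref, tolerance = 1e-12)
    }
})

test_that("a planted pair far above its band expectation is called significant", {
    set.seed(11)
    n <- 200L
    pr <- t(combn(n, 2L)) - 1L
    d <- pr[, 2L] - pr[, 1L]
    lam <- 40 / d
    x <- rpois(nrow(pr), lam)
    keep <- x > 0
    cm <- ContactMatrix("chr1", n, pr[keep, 1L], pr[keep, 2L], x[keep])
    # plant: multiply one mid-range pair tenfold above its expectation
    cp <- contactPairs(cm)
    target <- which(cp$bin1 == 50 & cp$bin2 == 90)
    if (!length(target)) {
        cp <- rbind(cp, data.frame(bin1 = 50L, bin2 = 90L, count = 0))
        target <- nrow(cp)
    }
    cp$count[target] <- round(10 * 40 / 40) + 5
    cm <- ContactMatrix("chr1", n, cp$bin1, cp$bin2, pmax(cp$count, 1))
    b <- unitBiases(n)
    dec <- estimateDecay(cm, b, nBands = 50)
    ls <- callLoops(cm, b, dec, qThreshold = 0.05)
    lp <- loopPairs(ls)
    expect_true(any(lp$bin1 == 50 & lp$bin2 == 90))
})

test_that("loop p-values match direct binomial tail summation", {
    cm <- decayMatrix(20, c0 = 100)
    b <- unitBiases(20)
    dec <- estimateDecay(cm, b, nBands = 8)
    ls <- callLoops(cm, b, dec, qThreshold = 1)  # keep everything
    lp <- loopPairs(ls)
    N <- dec@trials
    # direct summation oracle only feasible for moderate N
    expect_lte(N, 10000)
    for (r in sample(nrow(lp), 20)) {
        p <- dec@prob[dec@dist == (lp$bin2[r] - lp$bin1[r])]
        ref <- bruteBinomTail(lp$observed[r], N, p)
        expect_equal(lp$p_value[r], ref, tolerance = 1e-9)
    }
})

test_that("null data yields calibrated (conservative) loop p-values", {
    set.seed(21)
    n <- 150L
    pr <- t(combn(n, 2L)) - 1L
    d <- pr[, 2L] - pr[, 1L]
    x <- rpois(nrow(pr), 30 / d)
    keep <- x > 0
    cm <- ContactMatrix("chr1", n, pr[keep, 1L], pr[keep, 2L], x[keep])
    b <- unitBiases(n)
    dec <- estimateDecay(cm, b, nBands = 30)
    ls <- callLoops(cm, b, dec, qThreshold = 1)
    pv <- loopPairs(ls)$p_value
    for (alpha in c(0.01, 0.05)) {
        frac <- mean(pv < alpha)
        se <- sqrt(alpha * (1 - alpha) / length(pv))
        expect_lte(frac, alpha + 3 * se)
    }
})

test_that("loop calls are identical for unit biases and no bias structure", {
    cm <- decayMatrix(30)
    b1 <- unitBiases(30)
    b2 <- BiasVector(rep(2.5, 30))  # rescaling collapses to unit after mean-normalization
    dec1 <- estimateDecay(cm, b1, nBands = 10)
    dec2 <- estimateDecay(cm, b2, nBands = 10)
    expect_equal(loopPairs(callLoops(cm, b1, dec1, 0.5)),
                 loopPairs(callLoops(cm, b2, dec2, 0.5)))
})

test_that("BEDPE import maps anchors to bins and round-trips", {
    f <- withr::local_tempfile()
    writeLines(c("chr1\t10000\t20000\tchr1\t50000\t60000\t7",
                 "chr1\t30000\t40000\tchr2\t50000\t60000\t1",
                 "chr1\t50000\t60000\tchr1\t10000\t20000"), f)
    expect_message(ls <- importBedpe(f, 10000, 100L), "skipped")
    lp <- loopPairs(ls)
    expect_equal(nrow(lp), 1L)  # reversed duplicate collapses
    expect_equal(c(lp$bin1, lp$bin2), c(1L, 5L))

    fo <- withr::local_tempfile()
    exportBedpe(ls, fo)
    back <- importBedpe(fo, 10000, 100L)
    expect_equal(loopPairs(back)[c("bin1", "bin2")],
                 lp[c("bin1", "bin2")])

    writeLines("chr1\t100\t200\tchr1\t300", f)
    expect_error(importBedpe(f, 10000, 100L), "fewer than 6")
})
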