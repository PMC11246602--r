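test_that("size-specific distance distributions match the two-step decomposition", {
    cs <- BinnedClusterSet("chr1", 1000, 10L, list(c(0L, 1L, 2L)))
    d3 <- learnDistanceDistribution(cs, 3)
    expect_equal(d3$dist, c(1L, 2L))
    expect_equal(d3$prob, c(2 / 3, 1 / 3))

    # constant weights cancel: one size-5 cluster at k=3 gives the plain
    # pair-distance histogram
    cl <- c(0L, 3L, 4L, 8L, 9L)
    cs5 <- BinnedClusterSet("chr1", 1000, 10L, list(cl))
    d5 <- learnDistanceDistribution(cs5, 3)
    gaps <- apply(combn(cl, 2), 2, diff)
    ref <- table(gaps) / length(gaps)
    expect_equal(d5$prob, as.numeric(ref))
    expect_equal(d5$dist, as.integer(names(ref)))

    expect_error(learnDistanceDistribution(cs, 4), "no cluster of size")
    expect_error(learnDistanceDistribution(cs, 2), "k must be")
})

test_that("weighted pair decomposition equals explicit subset enumeration", {
    cs <- randomClusterSet(20, 30, maxSize = 7L, seed = 13)
    for (k in 4:5) {
        got <- learnDistanceDistribution(cs, k)
        # oracle: enumerate all k-subsets, then their 2-subsets
        gaps <- unlist(lapply(clusterBins(cs), function(cl) {
            if (length(cl) < k) return(NULL)
            unlist(apply(combn(cl, k), 2, function(s)
                apply(combn(s, 2), 2, diff), simplify = FALSE))
        }))
        ref <- table(gaps) / length(gaps)
        ord <- order(as.integer(names(ref)))
        expect_equal(got$dist, as.integer(names(ref))[ord])
        expect_equal(got$prob, as.numeric(ref)[ord], tolerance = 1e-12)
    }
})

test_that("trial counts are exact subset counts", {
    cs <- BinnedClusterSet("chr1", 1000, 30L,
                           list(0:3, 4:7, c(10L, 12L, 14L, 16L, 18L)))
    expect_equal(trialCount(cs, 3), 4 + 4 + 10)
    ref <- sum(vapply(clusterBins(cs), function(cl)
        if (length(cl) >= 3) ncol(combn(cl, 3)) else 0L, numeric(1)))
    expect_equal(trialCount(cs, 3), ref)
    expect_equal(trialCount(cs, 6), 0)
    cs1 <- BinnedClusterSet("chr1", 1000, 10L, list(c(0L, 1L, 2L)))
    expect_equal(trialCount(cs1, 3), 1)
})

test_that("candidate probability is the start term times adjacent-gap terms", {
    n <- 100L
    G <- 10L
    tab <- data.frame(dist = 1:G, prob = rep(1 / G, G))
    model <- new("BackgroundModel", chrom = "chr1", nBins = n,
                 dists = list(`3` = tab), trials = c(`3` = 1000),
                 interpolation = "interpolate")
    expect_equal(candidateProbability(c(10, 13, 20), model),
                 (1 / n) * (1 / G)^2)

    tab4 <- data.frame(dist = c(2L, 4L), prob = c(0.7, 0.3))
    m4 <- new("BackgroundModel", chrom = "chr1", nBins = n,
              dists = list(`4` = tab4), trials = c(`4` = 1000),
              interpolation = "interpolate")
    expect_equal(candidateProbability(c(0, 2, 4, 8), m4),
                 (1 / n) * 0.7 * 0.7 * 0.3)
    # order of input bins is irrelevant
    expect_equal(candidateProbability(c(8, 0, 4, 2), m4),
                 candidateProbability(c(0, 2, 4, 8), m4))
    expect_error(candidateProbability(c(0, 1, 2), m4), "no distance distribution")
})

test_that("total raw probability mass over all k-tuples stays below 1", {
    cs <- randomClusterSet(12, 40, maxSize = 5L, seed = 19)
    model <- buildBackgroundModel(cs, 3, interpolation = "zero")
    tuples <- combn(0:11, 3)
    total <- sum(apply(tuples, 2, candidateProbability, model = model))
    expect_lte(total, 1)
    expect_gt(total, 0)
})

test_that("unobserved gaps interpolate log-linearly with a power-law tail", {
    tab <- data.frame(dist = c(1L, 2L, 4L, 8L), prob = c(.4, .3, .2, .1))
    tab$prob <- tab$prob / sum(tab$prob)
    m <- new("BackgroundModel", chrom = "c", nBins = 50L,
             dists = list(`3` = tab), trials = c(`3` = 10),
             interpolation = "interpolate")
    p3 <- hyperloopR:::gapProbability(tab, 3L, "interpolate")
    # log-linear between d=2 and d=4
    ref <- exp(approx(log(tab$dist), log(tab$prob), xout = log(3))$y)
    expect_equal(p3, ref)
    # beyond the largest distance the estimate decreases
    p16 <- hyperloopR:::gapProbability(tab, 16L, "interpolate")
    expect_lt(p16, tab$prob[4])
    expect_gt(p16, 0)
    # zero mode vetoes
    expect_equal(hyperloopR:::gapProbability(tab, 3L, "zero"), 0)
})

test_that("binomial scoring is numerically stable and handles edge observations", {
    cs <- BinnedClusterSet("chr1", 1000, 100L,
                           list(c(0L, 5L, 9L), c(0L, 5L, 9L), c(2L, 3L, 4L)))
    model <- buildBackgroundModel(cs, 3)
    b <- unitBiases(100)

    # closed form: N = 10, p* = 0.5, observed 10 -> 2^-10
    modN <- new("BackgroundModel", chrom = "chr1", nBins = 1L,
                dists = list(`3` = data.frame(dist = 1L, prob = 1)),
                trials = c(`3` = 10), interpolation = "interpolate")
    cands <- data.frame(bins = I(list(c(0L, 1L, 2L))), support = 10)
    rec <- scoreCandidates(cands, modN, unitBiases(3))
    expect_equal(rec$p_star, 1)  # (1/1) * 1 * 1... clipped path unused: p = 1
    expect_equal(rec$p_value, 1)  # p* = 1 -> certain

    # direct closed form via the public surface with a crafted probability
    p <- 0.5
    expect_equal(pbinom(9, 10, p, lower.tail = FALSE), 2^-10)

    # observed 0 -> p-value 1
    cands0 <- data.frame(bins = I(list(c(0L, 5L, 9L))), support = 0)
    rec0 <- scoreCandidates(cands0, model, b)
    expect_equal(rec0$p_value, 1)

    # random cases vs direct summation (relative error <= 1e-9)
    set.seed(33)
    for (i in 1:25) {
        N <- sample(100:5000, 1)
        p <- runif(1, 1e-5, 0.01)
        obs <- sample(1:15, 1)
        got <- pbinom(obs - 1, N, p, lower.tail = FALSE)
        ref <- bruteBinomTail(obs, N, p)
        expect_equal(got, ref, tolerance = 1e-9)
    }
})

test_that("p-values decrease with observed count and biases act multiplicatively", {
    cs <- randomClusterSet(40, 200, maxSize = 5L, seed = 7)
    model <- buildBackgroundModel(cs, 3)
    b <- unitBiases(40)
    bins <- list(c(1L, 5L, 9L))
    pv <- vapply(c(1, 3, 6, 10), function(obs)
        scoreCandidates(data.frame(bins = I(bins), support = obs),
                        model, b)$p_value, numeric(1))
    expect_true(all(diff(pv) <= 0))

    # with all biases 1, corrected and raw quantities coincide
    rec <- scoreCandidates(data.frame(bins = I(bins), support = 3), model, b)
    expect_equal(rec$p_star, rec$p_raw)
    expect_equal(rec$expected, rec$p_raw * trialCount(cs, 3))

    # a non-unit bias enters as the product over member bins
    bv <- rep(1, 40); bv[c(2, 6, 10)] <- c(1.3, 0.7, 1.1)
    bias2 <- BiasVector(bv)
    rec2 <- scoreCandidates(data.frame(bins = I(bins), support = 3), model, bias2)
    expect_equal(rec2$p_star,
                 rec2$p_raw * prod(biasValues(bias2)[c(2, 6, 10)]))
})

test_that("grouped BH corrects within (chromosome, size) families", {
    recs <- data.frame(chrom = "c", k = 3L, p_value = c(0.01, 0.02, 0.04))
    got <- groupedBH(recs)
    expect_equal(got$q_value, c(0.03, 0.03, 0.04))

    one <- groupedBH(data.frame(chrom = "c", k = 3L, p_value = 0.2))
    expect_equal(one$q_value, 0.2)

    two <- data.frame(chrom = "c", k = c(3L, 3L, 3L, 4L, 4L, 4L),
                      p_value = rep(c(0.01, 0.02, 0.04), 2))
    gq <- groupedBH(two)$q_value
    expect_equal(gq[1:3], gq[4:6])
    # q is monotone in p within a group
    expect_true(all(diff(gq[1:3]) >= 0))
})
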