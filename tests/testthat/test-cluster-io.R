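test_that("SPRITE cluster files parse token-by-token with line-accurate errors", {
    f <- withr::local_tempfile()
    writeLines(c("C1\tchr1_10000 chr1_35000", "C2\tchr2_500 chr2_99999"), f)
    fr <- readSpriteClusters(f)
    expect_equal(nrow(fr), 4L)
    expect_equal(fr$cluster_id, c("C1", "C1", "C2", "C2"))
    expect_equal(fr$pos, c(10000, 35000, 500, 99999))

    writeLines(character(0), f)
    expect_equal(nrow(readSpriteClusters(f)), 0L)

    writeLines(c("C1\tchr1_100", "C2\tchr1_x"), f)
    expect_error(readSpriteClusters(f), "line 2")

    # chromosome names may contain underscores; position is the last field
    writeLines("C1\tchr1_gl000_500 chr1_gl000_900", f)
    fr <- readSpriteClusters(f)
    expect_equal(unique(fr$chrom), "chr1_gl000")
    expect_equal(fr$pos, c(500, 900))
})

test_that("Pore-C monomer tables use interval midpoints and keep read grouping", {
    f <- withr::local_tempfile()
    writeLines(c("read_id\tchrom\tstart\tend",
                 "r1\tchr1\t100\t300",
                 "r1\tchr1\t1000\t1001",
                 "r2\tchr2\t5\t5"), f)
    fr <- readPorecTable(f)
    expect_equal(fr$pos, c(200, 1000, 5))
    expect_equal(fr$cluster_id, c("r1", "r1", "r2"))

    writeLines(c("read_id\tchrom\tstart\tend", "r1\tchr1\t300\t100"), f)
    expect_error(readPorecTable(f), "start > end")

    writeLines(c("read_id\tchrom\tbegin\tend", "r1\tchr1\t1\t2"), f)
    expect_error(readPorecTable(f), "missing column")
})

test_that("binning floors to half-open bins, dedupes and splits per chromosome", {
    fr <- data.frame(cluster_id = "C1", chrom = "chr1",
                     pos = c(10000, 14000, 35000))
    out <- binAndSplit(fr, 10000, c(chr1 = 1e6))
    expect_equal(clusterBins(out$chr1)[[1L]], c(1L, 3L))
    expect_equal(numBins(out$chr1), 100L)

    # a cluster touching two chromosomes appears once per chromosome
    fr2 <- data.frame(cluster_id = "C1",
                      chrom = c("chr1", "chr1", "chr2", "chr2"),
                      pos = c(0, 20000, 5000, 90000))
    out2 <- binAndSplit(fr2, 10000, c(chr1 = 1e5, chr2 = 1e5))
    expect_setequal(names(out2), c("chr1", "chr2"))
    expect_equal(clusterBins(out2$chr2)[[1L]], c(0L, 9L))

    # single remaining bin on a chromosome drops that projection
    fr3 <- data.frame(cluster_id = c("C1", "C1", "C1"),
                      chrom = c("chr1", "chr2", "chr2"),
                      pos = c(100, 100, 50000))
    out3 <- binAndSplit(fr3, 10000, c(chr1 = 1e5, chr2 = 1e5))
    expect_null(out3$chr1)
    expect_equal(numClusters(out3$chr2), 1L)

    expect_error(binAndSplit(data.frame(cluster_id = "C", chrom = "chr1",
                                        pos = 2e6),
                             10000, c(chr1 = 1e6)), "out of range")
})

test_that("re-binning a binned set at the same resolution is a no-op", {
    cs <- randomClusterSet(40, 30, seed = 5)
    res <- binResolution(cs)
    fr <- data.frame(
        cluster_id = rep(clusterIds(cs), lengths(clusterBins(cs))),
        chrom = chromName(cs),
        pos = unlist(clusterBins(cs)) * res)
    out <- binAndSplit(fr, res, setNames(numBins(cs) * res, chromName(cs)))
    expect_equal(clusterBins(out[[chromName(cs)]]), unname(clusterBins(cs)))
})

test_that("cluster size filtering keeps the requested range in order", {
    cs <- BinnedClusterSet("chr1", 1000, 2000L,
                           list(0:1, 0:2, 0:999), c("a", "b", "c"))
    expect_equal(clusterIds(filterClusters(cs, 2, 100)), c("a", "b"))
    expect_equal(numClusters(filterClusters(cs, 2, .Machine$integer.max)), 3L)
    expect_equal(clusterIds(filterClusters(cs, 3, 100)), "b")
    expect_error(filterClusters(cs, 1, 10), "minSize")
})

test_that("the binned-cluster TSV dialect round-trips exactly", {
    cs <- randomClusterSet(25, 20, seed = 9)
    f <- withr::local_tempfile()
    writeBinnedClusters(cs, f)
    back <- readBinnedClusters(f)
    expect_equal(chromName(back), chromName(cs))
    expect_equal(binResolution(back), binResolution(cs))
    expect_equal(numBins(back), numBins(cs))
    expect_equal(clusterBins(back), unname(clusterBins(cs)))
    expect_equal(clusterIds(back), clusterIds(cs))
})
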