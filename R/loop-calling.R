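#' Estimate the distance decay of pairwise contact probability
#'
#' Bias-normalized counts \eqn{M_{ij} / (b_i b_j)} are pooled into
#' `nBands` equal-occupancy distance bands; the per-band contact
#' probability is the band's share of normalized contacts divided by the
#' number of possible valid bin pairs in the band. A weighted
#' pool-adjacent-violators fit enforces a monotone non-increasing decay,
#' the expected behaviour of random polymer looping.
#'
#' @param cm a [ContactMatrix-class].
#' @param bias a [BiasVector-class] (use [unitBiases()] to skip correction).
#' @param nBands number of equal-occupancy distance bands.
#' @param minDist minimum distance (bin units) modelled; must be >= 2,
#'   consistent with the `|i - j| > 1` balancing mask.
#' @param maxDist maximum distance modelled (default: chromosome span).
#' @return A [DistanceDecay-class].
#' @export
estimateDecay <- function(cm, bias, nBands = 100L, minDist = 2L, maxDist = NULL) {
    if (minDist < 2L) stop("minDist must be >= 2")
    if (nBands < 1L) stop("nBands must be >= 1")
    n <- cm@nBins
    if (is.null(maxDist)) maxDist <- n - 1L
    maxDist <- min(maxDist, n - 1L)
    valid <- bias@valid
    d <- cm@bin2 - cm@bin1
    sel <- d >= minDist & d <= maxDist & valid[cm@bin1 + 1L] & valid[cm@bin2 + 1L]
    if (!any(sel)) stop("no contacts in the modelled distance range")
    b <- bias@values
    w <- cm@counts[sel] / (b[cm@bin1[sel] + 1L] * b[cm@bin2[sel] + 1L])
    dSel <- d[sel]

    dSeq <- minDist:maxDist
    pairs <- vapply(dSeq, function(dd)
        sum(valid[seq_len(n - dd)] & valid[seq_len(n - dd) + dd]), numeric(1L))
    keep <- pairs > 0
    dSeq <- dSeq[keep]; pairs <- pairs[keep]

    mass <- numeric(length(dSeq))
    agg <- rowsum(w, dSel)
    mass[match(as.integer(rownames(agg)), dSeq)] <- agg[, 1L]
    total <- sum(mass)
    if (total <= 0) stop("no contacts in the modelled distance range")

    pos <- cumsum(mass) - mass / 2
    band <- pmin(as.integer(nBands), pmax(1L, as.integer(ceiling(pos / total * nBands))))
    bandMass <- rowsum(mass, band)
    bandPairs <- rowsum(pairs, band)
    bandProb <- bandMass[, 1L] / (total * bandPairs[, 1L])
    bandProb <- pavaNonIncreasing(bandProb, bandPairs[, 1L])
    prob <- bandProb[match(band, sort(unique(band)))]

    new("DistanceDecay", dist = as.integer(dSeq), prob = as.numeric(prob),
        nPairs = as.numeric(pairs), trials = sum(cm@counts[sel]),
        minDist = as.integer(minDist), maxDist = as.integer(maxDist))
}

#' Call significant pairwise loops with a distance-decay binomial test
#'
#' For every stored bin pair in the modelled distance range, the
#' per-experiment success probability is
#' \eqn{p_{ij} = P(d) \, b_i \, b_j} and the trial count is the total
#' contact count in range; the p-value is the upper-tail binomial
#' probability of observing at least the recorded count, and
#' Benjamini-Hochberg correction is applied over all tested pairs of the
#' chromosome.
#'
#' @param cm a [ContactMatrix-class].
#' @param bias a [BiasVector-class].
#' @param decay a [DistanceDecay-class] from [estimateDecay()].
#' @param qThreshold q-value cutoff defining the loop set.
#' @return A [LoopSet-class] of pairs with `q_value <= qThreshold`.
#' @export
callLoops <- function(cm, bias, decay, qThreshold = 0.05) {
    d <- cm@bin2 - cm@bin1
    valid <- bias@valid
    sel <- d >= decay@minDist & d <= decay@maxDist &
        valid[cm@bin1 + 1L] & valid[cm@bin2 + 1L]
    i <- cm@bin1[sel]; j <- cm@bin2[sel]; x <- cm@counts[sel]
    pd <- decay@prob[match(d[sel], decay@dist)]
    b <- bias@values
    p <- pd * b[i + 1L] * b[j + 1L]
    if (any(p >= 1)) {
        warning(sum(p >= 1), " pair probabilities clipped to 1 (pathological bias)")
        p <- pmin(p, 1)
    }
    N <- decay@trials
    pval <- pbinom(x - 1, N, p, lower.tail = FALSE)
    qval <- p.adjust(pval, method = "BH")
    keep <- qval <= qThreshold
    loops <- data.frame(bin1 = i[keep], bin2 = j[keep], observed = x[keep],
                        expected = (p * N)[keep], p_value = pval[keep],
                        q_value = qval[keep])
    loops <- loops[order(loops$bin1, loops$bin2), , drop = FALSE]
    rownames(loops) <- NULL
    LoopSet(cm@chrom, NA_real_, loops, qThreshold, nTested = length(x))
}

#' Import / export loops in BEDPE format
#'
#' `importBedpe` maps each anchor to the bin containing its midpoint and
#' collapses duplicate pairs; inter-chromosomal rows (and rows on other
#' chromosomes than `chrom`, if given) are skipped with a message.
#' `exportBedpe` writes each loop as one BEDPE row whose anchors are the
#' full bins, with the q-value in the score column.
#'
#' @param path BEDPE file path (6+ tab-separated columns
#'   `chrom1 start1 end1 chrom2 start2 end2 [score ...]`, no header).
#' @param resolution bin width in bp used to map anchors to bins.
#' @param nBins number of bins on the chromosome.
#' @param chrom restrict to this chromosome (default: the first chromosome
#'   seen in the file).
#' @return `importBedpe` returns a [LoopSet-class] (observed/expected and
#'   p/q columns are `NA` for imported loops); `exportBedpe` returns `path`
#'   invisibly.
#' @export
importBedpe <- function(path, resolution, nBins, chrom = NULL) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !grepl("^#", lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(parts) < 6L)
    if (length(bad))
        stop(sprintf("line %d: BEDPE row with fewer than 6 columns", bad[1L]))
    c1 <- vapply(parts, `[`, "", 1L); c2 <- vapply(parts, `[`, "", 4L)
    num <- function(k) {
        v <- suppressWarnings(as.numeric(vapply(parts, `[`, "", k)))
        if (anyNA(v) && length(v))
            stop(sprintf("line %d: non-numeric BEDPE coordinate", which(is.na(v))[1L]))
        v
    }
    s1 <- num(2L); e1 <- num(3L); s2 <- num(5L); e2 <- num(6L)
    if (is.null(chrom)) chrom <- c1[1L]
    intra <- c1 == c2 & c1 == chrom
    if (any(!intra))
        message(sum(!intra), " BEDPE rows skipped (inter-chromosomal or other chromosome)")
    b1 <- floor(floor((s1 + e1) / 2) / resolution)[intra]
    b2 <- floor(floor((s2 + e2) / 2) / resolution)[intra]
    lo <- pmin(b1, b2); hi <- pmax(b1, b2)
    ok <- lo >= 0 & hi < nBins & lo < hi
    pairs <- unique(data.frame(bin1 = as.integer(lo[ok]), bin2 = as.integer(hi[ok])))
    pairs <- pairs[order(pairs$bin1, pairs$bin2), , drop = FALSE]
    loops <- data.frame(pairs, observed = NA_real_, expected = NA_real_,
                        p_value = NA_real_, q_value = NA_real_)
    rownames(loops) <- NULL
    LoopSet(chrom, resolution, loops, NA_real_, nTested = nrow(loops))
}

#' @rdname importBedpe
#' @param ls a [LoopSet-class].
#' @export
exportBedpe <- function(ls, path) {
    res <- ls@resolution
    if (is.na(res)) stop("LoopSet has no resolution; set it before export")
    lp <- ls@loops
    score <- ifelse(is.na(lp$q_value), ".", sprintf("%.6g", lp$q_value))
    rows <- sprintf("%s\t%d\t%d\t%s\t%d\t%d\t%s",
                    ls@chrom, as.integer(lp$bin1 * res), as.integer((lp$bin1 + 1) * res),
                    ls@chrom, as.integer(lp$bin2 * res), as.integer((lp$bin2 + 1) * res),
                    score)
    writeLines(rows, path)
    invisible(path)
}
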