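#' Read a SPRITE-style cluster file
#'
#' Each line holds one cluster: a barcode followed by whitespace-separated
#' fragment tokens of the form `chrom_position` (the position is the last
#' underscore-separated field, so chromosome names may themselves contain
#' underscores).
#'
#' @param path path to the cluster file.
#' @return A data.frame of fragments with columns `cluster_id`, `chrom`,
#'   `pos`, one row per token, in file order.
#' @examples
#' f <- tempfile()
#' writeLines(c("C1\tchr1_10000 chr1_35000", "C2\tchr2_500"), f)
#' readSpriteClusters(f)
#' @export
readSpriteClusters <- function(path) {
    lines <- readLines(path)
    out <- vector("list", length(lines))
    for (ln in seq_along(lines)) {
        if (!nzchar(trimws(lines[ln]))) next
        tok <- strsplit(trimws(lines[ln]), "[ \t]+")[[1L]]
        id <- tok[1L]
        frags <- tok[-1L]
        if (!length(frags)) next
        us <- regexpr("_[^_]*$", frags)
        if (any(us < 0))
            stop(sprintf("line %d: fragment token without '_' separator", ln))
        chrom <- substr(frags, 1L, us - 1L)
        pos <- suppressWarnings(as.numeric(substr(frags, us + 1L, nchar(frags))))
        if (any(!nzchar(chrom)) || any(is.na(pos)) || any(pos != floor(pos)))
            stop(sprintf("line %d: malformed fragment token (expected chrom_integer)", ln))
        out[[ln]] <- data.frame(cluster_id = id, chrom = chrom, pos = pos)
    }
    out <- out[!vapply(out, is.null, logical(1L))]
    if (!length(out))
        return(data.frame(cluster_id = character(0), chrom = character(0),
                          pos = numeric(0)))
    do.call(rbind, out)
}

#' Read a Pore-C-style monomer alignment table
#'
#' A TSV with header columns `read_id`, `chrom`, `start`, `end`, one aligned
#' monomer per row. Each monomer becomes a fragment at the interval midpoint
#' `floor((start + end) / 2)`; rows sharing a `read_id` form one cluster.
#'
#' @param path path to the TSV file.
#' @return A data.frame of fragments with columns `cluster_id`, `chrom`,
#'   `pos`, in row order.
#' @export
readPorecTable <- function(path) {
    tab <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("read_id", "chrom", "start", "end")
    miss <- setdiff(need, names(tab))
    if (length(miss))
        stop("monomer table is missing column(s): ", paste(miss, collapse = ", "))
    bad <- which(tab$start > tab$end)
    if (length(bad))
        stop(sprintf("row %d: start > end", bad[1L]))
    data.frame(cluster_id = as.character(tab$read_id), chrom = tab$chrom,
               pos = floor((tab$start + tab$end) / 2))
}

#' Assign fragments to bins and split clusters by chromosome
#'
#' Fragments are assigned to 0-based, half-open bins
#' `[i * resolution, (i + 1) * resolution)`. Within each (cluster,
#' chromosome) pair the bin list is deduplicated and sorted; only the
#' intra-chromosomal projection of each cluster is kept, and projections
#' with fewer than 2 distinct bins are dropped.
#'
#' @param fragments data.frame with columns `cluster_id`, `chrom`, `pos`
#'   (from [readSpriteClusters()] or [readPorecTable()]).
#' @param resolution bin width in bp.
#' @param chromSizes named numeric vector of chromosome lengths in bp.
#' @return A named list of [BinnedClusterSet-class], one per chromosome with
#'   at least one retained cluster.
#' @examples
#' fr <- data.frame(cluster_id = "C1", chrom = "chr1",
#'                  pos = c(10000, 14000, 35000))
#' binAndSplit(fr, 10000, c(chr1 = 1e6))
#' @export
binAndSplit <- function(fragments, resolution, chromSizes) {
    stopifnot(resolution > 0)
    miss <- setdiff(unique(fragments$chrom), names(chromSizes))
    if (length(miss))
        stop("chromosome(s) absent from chromSizes: ", paste(miss, collapse = ", "))
    bad <- fragments$pos >= chromSizes[fragments$chrom] | fragments$pos < 0
    if (any(bad))
        stop(sprintf("fragment coordinate out of range on %s (pos %g)",
                     fragments$chrom[which(bad)[1L]], fragments$pos[which(bad)[1L]]))
    bin <- as.integer(floor(fragments$pos / resolution))
    out <- list()
    for (chr in intersect(names(chromSizes), unique(fragments$chrom))) {
        sel <- fragments$chrom == chr
        ids <- fragments$cluster_id[sel]
        # first-appearance order of clusters on this chromosome
        lev <- unique(ids)
        bl <- split(bin[sel], factor(ids, levels = lev))
        bl <- lapply(bl, function(b) sort(unique(b)))
        keep <- lengths(bl) >= 2L
        if (!any(keep)) next
        out[[chr]] <- BinnedClusterSet(chr, resolution,
                                       as.integer(ceiling(chromSizes[[chr]] / resolution)),
                                       bl[keep], lev[keep])
    }
    out
}

#' Filter clusters by size
#'
#' Keeps clusters whose bin count lies in `[minSize, maxSize]`, preserving
#' order. Very large clusters (e.g. giant SPRITE clusters spanning whole
#' compartments) are routinely removed before mining.
#'
#' @param cs a [BinnedClusterSet-class].
#' @param minSize minimum cluster size (>= 2).
#' @param maxSize maximum cluster size.
#' @return The filtered [BinnedClusterSet-class].
#' @export
filterClusters <- function(cs, minSize = 2L, maxSize = 1000L) {
    if (minSize < 2L) stop("minSize must be >= 2")
    if (maxSize < minSize) stop("maxSize must be >= minSize")
    sz <- lengths(cs@clusters)
    keep <- sz >= minSize & sz <= maxSize
    BinnedClusterSet(cs@chrom, cs@resolution, cs@nBins,
                     cs@clusters[keep], cs@clusterIds[keep])
}

#' Write / read a BinnedClusterSet in the package's TSV dialect
#'
#' One row per cluster: `cluster_id<TAB>comma-separated bin indices`, with
#' `#`-prefixed header lines carrying chromosome, resolution and bin count
#' so the file round-trips exactly.
#'
#' @param cs a [BinnedClusterSet-class].
#' @param path output (input) file path.
#' @return `writeBinnedClusters` returns `path` invisibly;
#'   `readBinnedClusters` returns a [BinnedClusterSet-class].
#' @export
writeBinnedClusters <- function(cs, path) {
    hdr <- c(sprintf("# chrom=%s", cs@chrom),
             sprintf("# resolution=%g", cs@resolution),
             sprintf("# n_bins=%d", cs@nBins))
    rows <- paste0(cs@clusterIds, "\t",
                   vapply(cs@clusters, function(b) paste(b, collapse = ","), ""))
    writeLines(c(hdr, rows), path)
    invisible(path)
}

#' @rdname writeBinnedClusters
#' @export
readBinnedClusters <- function(path) {
    lines <- readLines(path)
    hdr <- grep("^#", lines, value = TRUE)
    getv <- function(key) {
        m <- grep(paste0("^# ", key, "="), hdr, value = TRUE)
        if (!length(m)) stop("missing '", key, "' header in ", path)
        sub(paste0("^# ", key, "="), "", m[1L])
    }
    body <- lines[!grepl("^#", lines) & nzchar(lines)]
    parts <- strsplit(body, "\t", fixed = TRUE)
    ids <- vapply(parts, `[`, "", 1L)
    bins <- lapply(parts, function(p) as.integer(strsplit(p[2L], ",")[[1L]]))
    BinnedClusterSet(getv("chrom"), as.numeric(getv("resolution")),
                     as.integer(getv("n_bins")), bins, ids)
}
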