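#' Gap between genomic intervals and point positions
#'
#' Distance convention used by all proximity rules in the package (the
#' distal-promoter filter and the enhancer-gene linkage): the *gap to the
#' half-open interval*.  In 0-based half-open coordinates `[start, end)`
#' and a 0-based position `p`, the distance is `0` if `p` lies inside the
#' interval, `start - p` if `p < start`, and `p - end` if `p >= end`.
#' Positions on a different chromosome are infinitely far away (`Inf`
#' sentinel, not an error), so cross-chromosome pairs never pass a distance
#' cutoff.
#'
#' Note this is half-open BED arithmetic, not base-to-base distance: for a
#' position just right of the interval the gap is one less than the
#' distance to the last contained base.  The convention is fixed so that
#' the 1.5-kb and 10-kb filters are bit-reproducible.
#'
#' @param x `GRanges` of intervals.
#' @param pos `GRanges` of width-1 positions (e.g. TSSs).  `x` and `pos`
#'   are recycled to a common length and compared elementwise.
#' @return numeric vector of gaps in bp (`Inf` for cross-chromosome pairs).
#' @examples
#' library(GenomicRanges)
#' a <- GRanges("chr1", IRanges(1001, 2000))   # [1000, 2000) in BED terms
#' p <- GRanges("chr1", IRanges(2501, 2501))   # 0-based position 2500
#' intervalDistance(a, p)                      # 500
#' @export
intervalDistance <- function(x, pos) {
    n <- max(length(x), length(pos))
    if (length(x) != n) x <- rep(x, length.out = n)
    if (length(pos) != n) pos <- rep(pos, length.out = n)
    stopifnot(all(width(pos) == 1L))
    p1 <- start(pos)
    d <- as.numeric(pmax(start(x) - p1, p1 - end(x) - 1L, 0L))
    d[as.character(seqnames(x)) != as.character(seqnames(pos))] <- Inf
    d
}

#' Minimum gap from each interval to a set of positions
#'
#' For every interval, the minimum [intervalDistance()] over all positions
#' (typically all TSSs).  Intervals on chromosomes with no position get
#' `Inf`.  Implemented with a sorted-neighbour search so it scales to
#' genome-wide peak sets.
#'
#' @param x `GRanges` of intervals.
#' @param pos `GRanges` of width-1 positions.
#' @return numeric vector, one minimum gap per interval.
#' @export
minDistanceToPositions <- function(x, pos) {
    stopifnot(all(width(pos) == 1L))
    out <- rep(Inf, length(x))
    if (length(x) == 0L || length(pos) == 0L) return(out)
    xs <- as.character(seqnames(x))
    ps <- as.character(seqnames(pos))
    for (chr in unique(xs)) {
        ix <- which(xs == chr)
        pp <- sort(start(pos)[ps == chr])
        if (length(pp) == 0L) next
        s <- start(x)[ix]; e <- end(x)[ix]
        # nearest position <= e and nearest position > e; a position inside
        # or left of the interval minimises via start-p / 0, right via p-e-1
        idx <- findInterval(e, pp)               # last pp <= e
        gapL <- ifelse(idx >= 1L,
                       pmax(s - pp[pmax(idx, 1L)], 0L), Inf)
        gapR <- ifelse(idx < length(pp),
                       pp[pmin(idx + 1L, length(pp))] - e - 1L, Inf)
        out[ix] <- pmin(gapL, pmax(gapR, 0L))
    }
    out
}

#' Merge overlapping or touching intervals
#'
#' Union-preserving merge: overlapping intervals and intervals that touch
#' (BED end of one equals BED start of the next) collapse into one.  The
#' result is sorted by (chromosome, start).  Thin wrapper over
#' `GenomicRanges::reduce()`, which implements exactly this semantics;
#' exposed under a stable name because enhancer-region construction depends
#' on it.
#'
#' @param x `GRanges`.
#' @return sorted, disjoint `GRanges` covering the same bases.
#' @export
mergeIntervals <- function(x) {
    r <- reduce(x, ignore.strand = TRUE)
    # deterministic chromosome order regardless of input seqlevel order
    GenomeInfoDb::seqlevels(r) <- sort(GenomeInfoDb::seqlevels(r))
    sort(r, ignore.strand = TRUE)
}

# cumulative count C(z) = reads in [0, z) of one chromosome's bins,
# pro-rating the partial bin so that region sums are exactly additive
.cumCount <- function(counts, binSize, z) {
    cs <- c(0, cumsum(counts))
    n <- length(counts)
    z <- pmax(z, 0)
    i <- pmin(floor(z / binSize), n)          # full bins before z
    frac <- pmin(pmax(z - i * binSize, 0), binSize) / binSize
    extra <- ifelse(i < n, counts[pmin(i + 1L, n)] * frac, 0)
    cs[i + 1L] + extra
}

#' Total read signal over regions
#'
#' Sum of bin counts overlapping each region, with partial bins counted
#' pro-rata by overlap fraction (so the signal is exactly additive over any
#' partition of a region).  Regions extending beyond the binned portion of
#' a chromosome contribute 0 for the uncovered part; a region on a
#' chromosome absent from the track is an error (annotation/track
#' mismatch).
#'
#' @param track a [BinnedTrack-class].
#' @param regions `GRanges`.
#' @return numeric vector of raw (fractional) read counts, one per region.
#' @export
setGeneric("regionSignal",
           function(track, regions) standardGeneric("regionSignal"))

#' @rdname regionSignal
#' @export
setMethod("regionSignal", "BinnedTrack", function(track, regions) {
    if (length(regions) == 0L) return(numeric(0L))
    chroms <- as.character(seqnames(regions))
    bad <- setdiff(unique(chroms), names(track@counts))
    if (length(bad))
        stop("chromosome(s) not present in track: ", paste(bad, collapse = ", "))
    out <- numeric(length(regions))
    s0 <- start(regions) - 1          # 0-based half-open [s0, e0)
    e0 <- end(regions)
    for (chr in unique(chroms)) {
        ix <- which(chroms == chr)
        cnt <- track@counts[[chr]]
        out[ix] <- .cumCount(cnt, track@binSize, e0[ix]) -
            .cumCount(cnt, track@binSize, s0[ix])
    }
    out
})

#' Reads per kilobase per million mapped reads
#'
#' `count * 1e9 / (regionLength * totalReads)` — the normalisation used for
#' all enhancer signal totals, heatmaps and aggregate profiles.
#'
#' @param count raw read count(s) over the region.
#' @param regionLength region length(s) in bp (> 0).
#' @param totalReads library size (> 0).
#' @return RPKM value(s).
#' @examples
#' rpkm(10, 1000, 1e6)  # 10
#' @export
rpkm <- function(count, regionLength, totalReads) {
    if (any(regionLength <= 0)) stop("'regionLength' must be positive")
    if (any(totalReads <= 0)) stop("'totalReads' must be positive")
    count * 1e9 / (regionLength * totalReads)
}

#' Pool replicate tracks
#'
#' Bin-wise sum of counts; library sizes add.  Used to merge the two
#' knockdown siRNA replicates into a single pooled knockdown track before
#' differential classification.  All tracks must share bin size and
#' chromosome layout.
#'
#' @param tracks list of [BinnedTrack-class] objects (or several tracks as
#'   `...`).
#' @param ... tracks given individually instead of as a list.
#' @return pooled [BinnedTrack-class].
#' @export
poolTracks <- function(tracks, ...) {
    if (is(tracks, "BinnedTrack")) tracks <- c(list(tracks), list(...))
    stopifnot(length(tracks) >= 1L,
              all(vapply(tracks, is, logical(1L), "BinnedTrack")))
    ref <- tracks[[1L]]
    for (t in tracks[-1L]) {
        if (t@binSize != ref@binSize)
            stop("tracks have different bin sizes")
        if (!identical(names(t@counts), names(ref@counts)) ||
            !identical(lengths(t@counts), lengths(ref@counts)))
            stop("tracks have different chromosome layouts")
    }
    counts <- ref@counts
    for (t in tracks[-1L])
        counts <- Map(`+`, counts, t@counts)
    BinnedTrack(counts, binSize = ref@binSize,
                totalReads = sum(vapply(tracks, libSize, numeric(1L))))
}

#' Build a region-centred RPKM signal matrix
#'
#' For each region a window of `2 * flank` bp centred on the region
#' midpoint is split into `nBins` equal cells; each cell's value is the
#' RPKM of its span in `track`.  Windows running off the chromosome start
#' are clipped at 0 and the missing part contributes 0 signal.  Rows are
#' ordered by decreasing total signal of `orderBy` (default: `track`
#' itself; conventionally the control H3K4me1 track) over the *region*,
#' ties broken by (chromosome, start).
#'
#' @param track [BinnedTrack-class] quantified in the matrix cells.
#' @param regions `GRanges` of regions (e.g. enhancers).
#' @param flank half-window in bp (default 2000).
#' @param nBins cells per window (default 80).
#' @param orderBy [BinnedTrack-class] whose region totals define row order.
#' @return a [SignalMatrix-class].
#' @export
signalMatrix <- function(track, regions, flank = 2000L, nBins = 80L,
                         orderBy = track) {
    stopifnot(is(track, "BinnedTrack"), nBins >= 1L, flank >= 1L)
    flank <- as.integer(flank); nBins <- as.integer(nBins)
    ord <- order(-regionSignal(orderBy, regions),
                 as.character(seqnames(regions)), start(regions))
    regions <- regions[ord]
    binWidth <- 2 * flank / nBins
    vals <- matrix(0, nrow = length(regions), ncol = nBins)
    if (length(regions)) {
        centre0 <- floor((start(regions) - 1 + end(regions)) / 2)
        chroms <- as.character(seqnames(regions))
        bad <- setdiff(unique(chroms), names(track@counts))
        if (length(bad))
            stop("chromosome(s) not present in track: ",
                 paste(bad, collapse = ", "))
        edges <- seq(-flank, flank, length.out = nBins + 1L)
        for (chr in unique(chroms)) {
            ix <- which(chroms == chr)
            cnt <- track@counts[[chr]]
            # cumulative counts at all cell edges for all windows at once
            z <- outer(centre0[ix], edges, `+`)
            cc <- matrix(.cumCount(cnt, track@binSize, as.vector(z)),
                         nrow = length(ix))
            vals[ix, ] <- cc[, -1L, drop = FALSE] - cc[, -ncol(cc), drop = FALSE]
        }
        vals <- rpkm(vals, binWidth, libSize(track))
    }
    new("SignalMatrix", regions = regions, flank = flank, nBins = nBins,
        binWidth = binWidth, values = vals)
}

#' Aggregate (average) profile of a signal matrix
#'
#' Column-wise arithmetic mean of the RPKM matrix — the average-signal
#' curve conventionally drawn over a heatmap.
#'
#' @param x a [SignalMatrix-class].
#' @return numeric vector of length `nBins`.
#' @export
setGeneric("aggregateProfile", function(x) standardGeneric("aggregateProfile"))

#' @rdname aggregateProfile
#' @export
setMethod("aggregateProfile", "SignalMatrix", function(x) {
    colMeans(x@values)
})
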