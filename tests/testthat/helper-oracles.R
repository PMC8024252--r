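# Shared fixture builders and independent brute-force oracles.  The
# oracles deliberately work on 0-based coordinates with per-base masks and
# explicit loops, sharing no code with the package's interval machinery.

library(GenomicRanges)

# GRanges from 0-based half-open coordinates (BED convention)
gr0 <- function(chrom, start0, end0) {
    GRanges(chrom, IRanges(start0 + 1L, end0))
}

# width-1 TSS GRanges at 0-based positions
tssAt <- function(chrom, pos0, ids = sprintf("g%03d", seq_along(pos0))) {
    g <- GRanges(chrom, IRanges(pos0 + 1L, pos0 + 1L))
    mcols(g)$gene_id <- ids
    g
}

# spec gap convention, scalar, 0-based
oracleGap <- function(s0, e0, p0) {
    if (p0 >= s0 && p0 < e0) 0L
    else if (p0 < s0) s0 - p0
    else p0 - e0
}

# minimum |p - base| over contained bases (the base-enumeration distance;
# differs from oracleGap by at most 1 on the right side)
oracleBaseDistance <- function(s0, e0, p0) {
    min(abs(p0 - (s0:(e0 - 1L))))
}

# union of intervals via a per-base occupancy mask, one chromosome
oracleMergeChrom <- function(s0, e0, genomeLen) {
    mask <- logical(genomeLen)
    for (i in seq_along(s0)) mask[(s0[i] + 1L):e0[i]] <- TRUE
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    data.frame(start0 = starts[keep] - 1L, end0 = ends[keep])
}

oracleMerge <- function(gr, genomeLen) {
    out <- NULL
    for (chr in unique(as.character(seqnames(gr)))) {
        ix <- as.character(seqnames(gr)) == chr
        d <- oracleMergeChrom(start(gr)[ix] - 1L, end(gr)[ix], genomeLen)
        d$chrom <- chr
        out <- rbind(out, d)
    }
    out <- out[order(out$chrom, out$start0), ]
    gr0(out$chrom, out$start0, out$end0)
}

# exhaustive active-enhancer oracle: per-base co-occurrence + full TSS
# scan.  A peak of one mark is kept iff any of its bases carries the other
# mark (a K4me1 peak overlapping some K27ac peak is always selected, so a
# K27ac peak overlapping any K4me1 base overlaps a selected peak).
oracleEnhancers <- function(k4, k27, tss, genomeLen, minGap = 1500) {
    out <- GRanges()
    chroms <- unique(c(as.character(seqnames(k4)),
                       as.character(seqnames(k27))))
    for (chr in chroms) {
        i4 <- which(as.character(seqnames(k4)) == chr)
        i27 <- which(as.character(seqnames(k27)) == chr)
        if (!length(i4) || !length(i27)) next
        m4 <- m27 <- logical(genomeLen)
        for (i in i4) m4[start(k4)[i]:end(k4)[i]] <- TRUE
        for (i in i27) m27[start(k27)[i]:end(k27)[i]] <- TRUE
        selected <- logical(genomeLen)
        for (i in i4) {
            bases <- start(k4)[i]:end(k4)[i]
            if (any(m27[bases])) selected[bases] <- TRUE
        }
        for (i in i27) {
            bases <- start(k27)[i]:end(k27)[i]
            if (any(m4[bases])) selected[bases] <- TRUE
        }
        if (!any(selected)) next
        r <- rle(selected)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        for (j in which(r$values)) {
            s0 <- starts[j] - 1L
            e0 <- ends[j]
            gaps <- vapply(seq_along(tss), function(t) {
                if (as.character(seqnames(tss))[t] != chr) return(Inf)
                oracleGap(s0, e0, start(tss)[t] - 1L)
            }, numeric(1L))
            if (!length(gaps) || min(gaps) >= minGap)
                out <- c(out, gr0(chr, s0, e0))
        }
    }
    sort(out)
}

# uniform-count track: every bin of every chromosome the same count
uniformTrack <- function(chroms = c(chr1 = 100L), countPerBin = 10,
                         binSize = 100L, totalReads = NULL) {
    counts <- lapply(chroms, function(n) rep(countPerBin, n))
    names(counts) <- names(chroms)
    BinnedTrack(counts, binSize = binSize, totalReads = totalReads)
}

# track with given per-region totals: each region must be bin-aligned;
# counts spread uniformly over the region's bins
plantedTrack <- function(regions, totals, chromBins, binSize = 50L,
                         totalReads = NULL) {
    counts <- lapply(chromBins, function(n) rep(0, n))
    for (i in seq_along(regions)) {
        chr <- as.character(seqnames(regions))[i]
        b0 <- (start(regions)[i] - 1L) %/% binSize
        nb <- width(regions)[i] %/% binSize
        counts[[chr]][(b0 + 1L):(b0 + nb)] <-
            counts[[chr]][(b0 + 1L):(b0 + nb)] + totals[i] / nb
    }
    BinnedTrack(counts, binSize = binSize, totalReads = totalReads)
}

# planted enhancer intervals of a TruthManifest as GRanges
.truthGr <- function(manifest) {
    e <- manifest$enhancers
    gr0(e$chrom, e$start, e$end)
}

# light-weight "chrom:start-end" keys for fast equality checks in loops
regionsKey <- function(gr) {
    paste0(as.character(seqnames(gr)), ":", start(gr), "-", end(gr))
}

# mask-union oracle emitting keys directly (no GRanges construction)
oracleMergeKey <- function(gr, genomeLen) {
    out <- character(0)
    sn <- as.character(seqnames(gr))
    for (chr in sort(unique(sn))) {
        ix <- sn == chr
        d <- oracleMergeChrom(start(gr)[ix] - 1L, end(gr)[ix], genomeLen)
        out <- c(out, paste0(chr, ":", d$start0 + 1L, "-", d$end0))
    }
    out
}

# coordinate-only view for comparisons (ignores seqinfo/seqlevel order)
regionsDf <- function(gr) {
    df <- data.frame(chrom = as.character(seqnames(gr)),
                     start = start(gr), end = end(gr))
    rownames(df) <- NULL
    df
}

randomIntervals <- function(n, chroms = c("chrA", "chrB"),
                            genomeLen = 1e4, maxWidth = 500) {
    s0 <- sample.int(genomeLen - maxWidth - 1L, n, replace = TRUE)
    w <- sample.int(maxWidth, n, replace = TRUE)
    gr0(sample(chroms, n, replace = TRUE), s0, s0 + w)
}
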