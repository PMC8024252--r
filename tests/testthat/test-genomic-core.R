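test_that("interval-to-point gap follows the half-open convention", {
    a <- gr0("chr1", 1000, 2000)
    expect_identical(intervalDistance(a, tssAt("chr1", 1500)), 0)
    # right side: half-open gap is 500; base-enumeration distance is 501
    expect_identical(intervalDistance(a, tssAt("chr1", 2500)), 500)
    expect_equal(oracleBaseDistance(1000, 2000, 2500), 501)
    # left side: gap equals base distance
    expect_identical(intervalDistance(a, tssAt("chr1", 400)), 600)
    expect_equal(oracleBaseDistance(1000, 2000, 400), 600)
    # boundary bases
    expect_identical(intervalDistance(a, tssAt("chr1", 1000)), 0)
    expect_identical(intervalDistance(a, tssAt("chr1", 1999)), 0)
    expect_identical(intervalDistance(a, tssAt("chr1", 2000)), 0) # p - end = 0
    # different chromosome is an Inf sentinel, not an error
    expect_identical(intervalDistance(a, tssAt("chr2", 1500)), Inf)
})

test_that("gap matches the scalar oracle on random cases", {
    set.seed(42)
    for (i in 1:200) {
        s0 <- sample.int(5000, 1); w <- sample.int(800, 1)
        p0 <- sample.int(8000, 1) - 1L
        got <- intervalDistance(gr0("c", s0, s0 + w), tssAt("c", p0))
        expect_equal(got, oracleGap(s0, s0 + w, p0))
    }
})

test_that("minDistanceToPositions equals exhaustive minimum", {
    set.seed(43)
    for (i in 1:30) {
        x <- randomIntervals(20)
        pos <- tssAt(sample(c("chrA", "chrB"), 15, TRUE),
                     sample.int(1.1e4, 15))
        got <- minDistanceToPositions(x, pos)
        want <- vapply(seq_along(x), function(j) {
            min(intervalDistance(rep(x[j], length(pos)), pos))
        }, numeric(1L))
        expect_equal(got, want)
    }
    expect_identical(minDistanceToPositions(gr0("chrZ", 0, 10),
                                            tssAt("chrA", 5)), Inf)
})

test_that("mergeIntervals unions overlapping and touching intervals", {
    expect_equal(mergeIntervals(c(gr0("c", 10, 20), gr0("c", 15, 30))),
                 gr0("c", 10, 30))
    expect_equal(mergeIntervals(c(gr0("c", 10, 20), gr0("c", 20, 25))),
                 gr0("c", 10, 25))
    # non-touching stay apart
    expect_length(mergeIntervals(c(gr0("c", 10, 20), gr0("c", 21, 25))), 2L)
})

test_that("mergeIntervals equals the per-base occupancy oracle", {
    set.seed(44)
    for (i in 1:25) {
        x <- randomIntervals(50)
        expect_equal(regionsDf(mergeIntervals(x)), regionsDf(oracleMerge(x, 1.2e4)))
    }
})

test_that("regionSignal sums bins with pro-rata partial overlap", {
    tr <- uniformTrack(c(chr1 = 100L), countPerBin = 10, binSize = 100L)
    # 3 aligned bins
    expect_equal(regionSignal(tr, gr0("chr1", 200, 500)), 30)
    # half a bin of count 8
    tr8 <- BinnedTrack(list(chr1 = c(8, 0)), binSize = 100L, totalReads = 8)
    expect_equal(regionSignal(tr8, gr0("chr1", 0, 50)), 4)
    # fully outside covered bins
    expect_equal(regionSignal(tr, gr0("chr1", 20000, 20300)), 0)
    # unknown chromosome signals annotation/track mismatch
    expect_error(regionSignal(tr, gr0("chrX", 0, 100)), "chrX")
})

test_that("regionSignal is additive over partitions", {
    set.seed(45)
    tr <- BinnedTrack(list(c1 = runif(200, 0, 50)), binSize = 50L)
    for (i in 1:50) {
        s0 <- sample.int(8000, 1); e0 <- s0 + sample.int(1500, 1)
        cuts <- sort(c(s0, e0, sample(s0:e0, 3)))
        whole <- regionSignal(tr, gr0("c1", s0, e0))
        parts <- sum(vapply(seq_len(length(cuts) - 1L), function(k) {
            if (cuts[k] == cuts[k + 1L]) return(0)
            regionSignal(tr, gr0("c1", cuts[k], cuts[k + 1L]))
        }, numeric(1L)))
        expect_equal(parts, whole, tolerance = 1e-9)
    }
})

test_that("rpkm formula, guards and scale invariance", {
    expect_equal(rpkm(10, 1000, 1e6), 10)
    expect_equal(rpkm(0, 500, 1e7), 0)
    expect_equal(rpkm(24, 800, 3e6), rpkm(48, 800, 6e6))
    expect_error(rpkm(1, 0, 1e6), "regionLength")
    expect_error(rpkm(1, 100, 0), "totalReads")
})

test_that("poolTracks sums bins and library sizes", {
    set.seed(46)
    mk <- function() BinnedTrack(list(a = rpois(40, 5), b = rpois(25, 2)),
                                 binSize = 50L)
    t1 <- mk(); t2 <- mk(); t3 <- mk()
    pooled <- poolTracks(list(t1, t2, t3))
    expect_equal(trackCounts(pooled)$a,
                 trackCounts(t1)$a + trackCounts(t2)$a + trackCounts(t3)$a)
    expect_equal(libSize(pooled), libSize(t1) + libSize(t2) + libSize(t3))
    # self-pooling leaves RPKM over any region unchanged
    reg <- gr0("a", 100, 1600)
    selfPool <- poolTracks(list(t1, t1))
    expect_equal(rpkm(regionSignal(selfPool, reg), width(reg),
                      libSize(selfPool)),
                 rpkm(regionSignal(t1, reg), width(reg), libSize(t1)))
    # zero track only adds library size
    zero <- BinnedTrack(list(a = rep(0, 40), b = rep(0, 25)),
                        binSize = 50L, totalReads = 1000)
    p0 <- poolTracks(list(t1, zero))
    expect_equal(trackCounts(p0), trackCounts(t1))
    expect_equal(libSize(p0), libSize(t1) + 1000)
    # layout mismatch is an error
    bad <- BinnedTrack(list(a = rpois(41, 5)), binSize = 50L, totalReads = 1e3)
    expect_error(poolTracks(list(t1, bad)), "layout")
    expect_error(poolTracks(list(t1, BinnedTrack(list(a = rep(1, 40),
                                                      b = rep(1, 25)),
                                                 binSize = 25L))),
                 "bin size")
})

test_that("signalMatrix windows, ordering and aggregate profile", {
    tr <- uniformTrack(c(chr1 = 400L), countPerBin = 5, binSize = 50L)
    regions <- gr0("chr1", c(4000, 9000, 14000), c(4400, 9600, 15000))
    sm <- signalMatrix(tr, regions, flank = 1000, nBins = 20)
    v <- matrixValues(sm)
    # uniform track: every cell identical, aggregate flat
    expect_true(all(abs(v - v[1, 1]) < 1e-12))
    expect_equal(aggregateProfile(sm), rep(v[1, 1], 20))
    expect_equal(v[1, 1], rpkm(5 * 2, 100, libSize(tr)))  # 100-bp cells

    # single region: aggregate equals its own row
    sm1 <- signalMatrix(tr, regions[2], flank = 500, nBins = 10)
    expect_equal(aggregateProfile(sm1), as.numeric(matrixValues(sm1)[1, ]))

    # row order: permutation of regions, descending ordering-track totals
    set.seed(47)
    tr2 <- BinnedTrack(list(chr1 = runif(400, 0, 20)), binSize = 50L)
    sm2 <- signalMatrix(tr2, regions, flank = 1000, nBins = 8)
    ord <- matrixRegions(sm2)
    expect_setequal(start(ord), start(regions))
    totals <- regionSignal(tr2, ord)
    expect_true(all(diff(totals) <= 1e-9))
})

test_that("signalMatrix clips windows at the chromosome start", {
    tr <- uniformTrack(c(chr1 = 100L), countPerBin = 10, binSize = 100L)
    sm <- signalMatrix(tr, gr0("chr1", 0, 200), flank = 1000, nBins = 10)
    v <- matrixValues(sm)
    # window is [-900, 1100): first cells fall before base 0 and read 0
    expect_equal(v[1, 1], 0)
    expect_gt(v[1, 10], 0)
})

test_that("signalMatrix matches a naive per-cell oracle on random regions", {
    set.seed(48)
    tr <- BinnedTrack(list(c1 = rpois(500, 6)), binSize = 50L)
    regions <- randomIntervals(5, chroms = "c1", genomeLen = 2e4,
                               maxWidth = 900)
    flank <- 400; nBins <- 16
    sm <- signalMatrix(tr, regions, flank = flank, nBins = nBins)
    reg <- matrixRegions(sm)
    want <- t(vapply(seq_along(reg), function(i) {
        c0 <- floor((start(reg)[i] - 1 + end(reg)[i]) / 2)
        edges <- seq(c0 - flank, c0 + flank, length.out = nBins + 1L)
        vapply(seq_len(nBins), function(j) {
            lo <- max(edges[j], 0); hi <- max(edges[j + 1L], 0)
            cnt <- if (hi > lo) regionSignal(tr, gr0("c1", lo, hi)) else 0
            rpkm(cnt, 2 * flank / nBins, libSize(tr))
        }, numeric(1L))
    }, numeric(nBins)))
    expect_equal(matrixValues(sm), want, tolerance = 1e-9)
    expect_equal(aggregateProfile(sm), colMeans(want), tolerance = 1e-9)
})

test_that("BinnedTrack validity rejects malformed tracks", {
    expect_error(BinnedTrack(list(chr1 = c(-1, 2)), binSize = 50L),
                 "non-negative")
    expect_error(BinnedTrack(list(chr1 = c(1, 2)), binSize = 0L),
                 "binSize")
    expect_error(BinnedTrack(list(chr1 = c(1, 2)), binSize = 50L,
                             totalReads = 1), "totalReads")
})
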