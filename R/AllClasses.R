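#' @import methods
#' @importFrom GenomicRanges GRanges granges seqnames start end width strand
#'   reduce findOverlaps resize sort
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<- DataFrame queryHits subjectHits
NULL

#' Fixed-bin read-count signal track
#'
#' A `BinnedTrack` stores per-chromosome read counts in fixed-width bins
#' together with the library size (total mapped reads).  Bin `i` of a
#' chromosome covers the 0-based half-open interval
#' `[(i-1) * binSize, i * binSize)`.  It is the single source of all signal
#' quantification in the package: region totals, RPKM, heatmap matrices and
#' aggregate profiles are all computed from it.
#'
#' @slot binSize single positive integer, bin width in bp.
#' @slot counts named list (one element per chromosome) of non-negative
#'   numeric vectors of per-bin read counts.
#' @slot totalReads single positive number, the library size used for RPKM
#'   normalisation.  Must be at least the sum of all bin counts (the binned
#'   portion may cover only part of the genome).
#'
#' @seealso [regionSignal()], [rpkm()], [poolTracks()], [signalMatrix()]
#' @export
setClass("BinnedTrack",
    representation(binSize = "integer", counts = "list",
                   totalReads = "numeric"))

setValidity("BinnedTrack", function(object) {
    msg <- character()
    if (length(object@binSize) != 1L || is.na(object@binSize) ||
        object@binSize < 1L)
        msg <- c(msg, "'binSize' must be a single positive integer")
    nm <- names(object@counts)
    if (is.null(nm) || any(!nzchar(nm)) || anyDuplicated(nm))
        msg <- c(msg, "'counts' must be a named list with unique, non-empty chromosome names")
    if (!all(vapply(object@counts, is.numeric, logical(1L))))
        msg <- c(msg, "'counts' elements must be numeric vectors")
    else if (any(vapply(object@counts, function(x) any(x < 0 | is.na(x)),
                        logical(1L))))
        msg <- c(msg, "bin counts must be non-negative and non-missing")
    if (length(object@totalReads) != 1L || is.na(object@totalReads) ||
        object@totalReads <= 0)
        msg <- c(msg, "'totalReads' must be a single positive number")
    else {
        tot <- sum(vapply(object@counts, sum, numeric(1L)))
        # small tolerance: counts may be stored as doubles
        if (object@totalReads < tot - 1e-6)
            msg <- c(msg, "'totalReads' must be >= the sum of all bin counts")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a BinnedTrack
#'
#' @param counts named list of per-chromosome numeric vectors of bin counts.
#' @param binSize bin width in bp (default 50, the package-wide default
#'   resolution).
#' @param totalReads library size; defaults to the sum of all bin counts
#'   (i.e. the binned region is the whole mapped library).
#' @return a [BinnedTrack-class] object.
#' @examples
#' tr <- BinnedTrack(list(chr1 = rep(10, 100)), binSize = 50)
#' libSize(tr)
#' @export
BinnedTrack <- function(counts, binSize = 50L, totalReads = NULL) {
    if (is.null(totalReads))
        totalReads <- sum(vapply(counts, sum, numeric(1L)))
    new("BinnedTrack", binSize = as.integer(binSize),
        counts = lapply(counts, as.numeric), totalReads = as.numeric(totalReads))
}

#' @describeIn BinnedTrack bin width in bp.
#' @param x,object a `BinnedTrack`.
#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))

#' @rdname BinnedTrack
#' @export
setMethod("binSize", "BinnedTrack", function(x) x@binSize)

#' @describeIn BinnedTrack library size (total mapped reads).
#' @export
setGeneric("libSize", function(x) standardGeneric("libSize"))

#' @rdname BinnedTrack
#' @export
setMethod("libSize", "BinnedTrack", function(x) x@totalReads)

#' @describeIn BinnedTrack named list of per-chromosome bin-count vectors.
#' @export
setGeneric("trackCounts", function(x) standardGeneric("trackCounts"))

#' @rdname BinnedTrack
#' @export
setMethod("trackCounts", "BinnedTrack", function(x) x@counts)

setMethod("show", "BinnedTrack", function(object) {
    nbin <- sum(lengths(object@counts))
    cat("BinnedTrack with", length(object@counts), "chromosome(s),",
        nbin, "bins of", object@binSize, "bp\n")
    cat("  library size:", format(object@totalReads, big.mark = ","),
        "reads;", format(round(sum(vapply(object@counts, sum, numeric(1L)))),
                         big.mark = ","),
        "reads in bins\n")
})

#' Region-by-position RPKM signal matrix
#'
#' Holds the values behind an enhancer heatmap / aggregate profile: one row
#' per region (window = region centre +/- `flank`, split into `nBins` equal
#' cells), one column per cell, each cell the RPKM of that cell's span.
#' Rows are ordered by decreasing total signal of the ordering track over
#' the region itself (conventionally H3K4me1), ties broken by genomic
#' position.
#'
#' @slot regions `GRanges` of the (reordered) source regions.
#' @slot flank half-window width in bp.
#' @slot nBins number of cells per window.
#' @slot binWidth cell width in bp (`2 * flank / nBins`).
#' @slot values numeric matrix, `length(regions)` x `nBins`, RPKM.
#' @seealso [signalMatrix()], [aggregateProfile()]
#' @export
setClass("SignalMatrix",
    representation(regions = "GRanges", flank = "integer", nBins = "integer",
                   binWidth = "numeric", values = "matrix"))

setValidity("SignalMatrix", function(object) {
    msg <- character()
    if (nrow(object@values) != length(object@regions))
        msg <- c(msg, "row count of 'values' must equal number of regions")
    if (ncol(object@values) != object@nBins)
        msg <- c(msg, "column count of 'values' must equal 'nBins'")
    if (any(object@values < 0 | is.na(object@values)))
        msg <- c(msg, "matrix values must be non-negative and non-missing")
    if (object@flank < 1L || object@nBins < 1L)
        msg <- c(msg, "'flank' and 'nBins' must be positive")
    if (length(msg)) msg else TRUE
})

setMethod("show", "SignalMatrix", function(object) {
    cat("SignalMatrix:", length(object@regions), "regions x", object@nBins,
        "bins (window +/-", object@flank, "bp, cell", object@binWidth,
        "bp)\n")
    cat("  RPKM range:", signif(min(object@values), 4), "-",
        signif(max(object@values), 4), "\n")
})

#' @describeIn SignalMatrix the RPKM value matrix.
#' @param x,object a `SignalMatrix`.
#' @export
setGeneric("matrixValues", function(x) standardGeneric("matrixValues"))

#' @rdname SignalMatrix
#' @export
setMethod("matrixValues", "SignalMatrix", function(x) x@values)

#' @describeIn SignalMatrix the (reordered) regions.
#' @export
setGeneric("matrixRegions", function(x) standardGeneric("matrixRegions"))

#' @rdname SignalMatrix
#' @export
setMethod("matrixRegions", "SignalMatrix", function(x) x@regions)
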