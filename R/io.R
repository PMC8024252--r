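#' @importFrom rtracklayer import export
#' @importFrom utils read.csv read.delim write.table
#' @importFrom jsonlite write_json read_json toJSON fromJSON
NULL

#' Read peak calls from BED / narrowPeak
#'
#' BED intervals are converted to 1-based `GRanges` by rtracklayer; extra
#' narrowPeak columns are preserved as metadata columns and otherwise
#' ignored by the pipeline.
#'
#' @param path BED3+ or narrowPeak file.
#' @return `GRanges` of peaks.
#' @export
readPeaks <- function(path) {
    if (grepl("\\.narrowPeak$", path, ignore.case = TRUE))
        import(path, format = "BED",
               extraCols = c(signalValue = "numeric", pValue = "numeric",
                             qValue = "numeric", peak = "integer"))
    else
        import(path, format = "BED")
}

#' Read a fixed-bin signal track from bedGraph
#'
#' The bedGraph must tile chromosomes in intervals aligned to the bin grid
#' (each interval a multiple of `binSize`, starting on a bin boundary);
#' runs of equal value spanning several bins are expanded.  Bins absent
#' from the file are 0.  Because bedGraph carries no library size, pass
#' `totalReads` explicitly when the binned region does not cover the whole
#' mapped library.
#'
#' @param path bedGraph file.
#' @param binSize bin width in bp; inferred from the first interval when
#'   `NULL`.
#' @param totalReads library size; defaults to the sum of counts in the
#'   file.
#' @return a [BinnedTrack-class].
#' @export
readBedGraphTrack <- function(path, binSize = NULL, totalReads = NULL) {
    gr <- import(path, format = "bedGraph")
    if (length(gr) == 0L) stop("empty bedGraph: ", path)
    if (is.null(binSize)) {
        w <- width(gr)
        binSize <- min(w)
    }
    binSize <- as.integer(binSize)
    if (any((start(gr) - 1L) %% binSize != 0L) ||
        any(width(gr) %% binSize != 0L))
        stop("bedGraph intervals are not aligned to a ", binSize,
             "-bp bin grid")
    chroms <- as.character(seqnames(gr))
    counts <- lapply(split(seq_along(gr), chroms), function(ix) {
        lastBin <- max(end(gr)[ix]) %/% binSize
        v <- numeric(lastBin)
        for (i in ix) {
            b0 <- (start(gr)[i] - 1L) %/% binSize
            nb <- width(gr)[i] %/% binSize
            v[(b0 + 1L):(b0 + nb)] <- gr$score[i]
        }
        v
    })
    BinnedTrack(counts, binSize = binSize, totalReads = totalReads)
}

#' Write a BinnedTrack as bedGraph
#'
#' Runs of equal-valued bins are collapsed into single intervals (zero
#' runs included), so sparse tracks stay small.
#'
#' @param track a [BinnedTrack-class].
#' @param path output bedGraph path.
#' @return `path`, invisibly.
#' @export
writeBedGraphTrack <- function(track, path) {
    bs <- binSize(track)
    rows <- lapply(names(trackCounts(track)), function(chr) {
        r <- rle(trackCounts(track)[[chr]])
        ends <- cumsum(r$lengths) * bs
        starts <- ends - r$lengths * bs
        data.frame(chrom = chr, start = starts, end = ends, score = r$values)
    })
    df <- do.call(rbind, rows)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    invisible(path)
}

#' Read TSS annotation
#'
#' Accepts BED6 (TSS = strand-aware 5' end of the interval: BED start for
#' `+`, BED end - 1 for `-`; gene id from the name column) or a 4-column
#' TSV `gene_id, chrom, strand, tss` with a header, `tss` being the
#' 0-based TSS position.
#'
#' @param path annotation file.
#' @param format `"auto"` (by extension), `"bed"` or `"tsv"`.
#' @return width-1 `GRanges` with a `gene_id` metadata column.
#' @export
readTss <- function(path, format = c("auto", "bed", "tsv")) {
    format <- match.arg(format)
    if (format == "auto")
        format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed"
                  else "tsv"
    if (format == "bed") {
        gr <- import(path, format = "BED")
        tss <- resize(gr, width = 1L, fix = "start", ignore.strand = FALSE)
        mcols(tss) <- DataFrame(gene_id = gr$name)
    } else {
        df <- read.delim(path, stringsAsFactors = FALSE)
        stopifnot(all(c("gene_id", "chrom", "strand", "tss") %in% names(df)))
        tss <- GRanges(df$chrom, IRanges(df$tss + 1L, df$tss + 1L),
                       strand = df$strand)
        mcols(tss) <- DataFrame(gene_id = df$gene_id)
    }
    if (anyDuplicated(mcols(tss)$gene_id))
        stop("duplicate gene ids in TSS annotation")
    tss
}

#' Read an FPKM expression table with a sample-condition map
#'
#' @param valuesPath TSV with header `gene_id` followed by one column per
#'   sample.
#' @param conditionsPath two-column TSV (`sample`, `condition`) mapping
#'   every sample column to `control` / `kd1` / `kd2`.
#' @return expression `SummarizedExperiment` (see [expressionTable()]).
#' @export
readExpressionTable <- function(valuesPath, conditionsPath) {
    df <- read.delim(valuesPath, stringsAsFactors = FALSE, check.names = FALSE)
    stopifnot(names(df)[1L] == "gene_id")
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df$gene_id
    cm <- read.delim(conditionsPath, stringsAsFactors = FALSE)
    stopifnot(all(c("sample", "condition") %in% names(cm)))
    idx <- match(colnames(m), cm$sample)
    if (anyNA(idx)) stop("sample(s) missing from condition map: ",
                         paste(colnames(m)[is.na(idx)], collapse = ", "))
    expressionTable(m, cm$condition[idx])
}

#' Read a long-format qPCR Ct table
#'
#' @param path CSV with columns `sample`, `primer_pair`, `ct`,
#'   `replicate`.
#' @return `data.frame`.
#' @export
readCtTable <- function(path) {
    ct <- read.csv(path, stringsAsFactors = FALSE)
    stopifnot(all(c("sample", "primer_pair", "ct", "replicate") %in%
                  names(ct)))
    ct
}

.statusCodes <- c(stable = 0L, down_both = 1L, down_k4me1_only = 2L,
                  down_k27ac_only = 3L, up_both = 4L, mixed = 5L)

#' Write classified enhancers as BED6+ and TSV
#'
#' The BED name column carries the H3K4me1 rank and the score column a
#' numeric combined-status code (stable 0, down_both 1, down_k4me1_only 2,
#' down_k27ac_only 3, up_both 4, mixed 5).  The companion TSV holds the
#' full per-condition totals, ratios and statuses; a JSON summary of
#' counts per combined status is written alongside.
#'
#' @param enhancers classified, ranked enhancer `GRanges`.
#' @param prefix output path prefix; writes `<prefix>.bed`,
#'   `<prefix>.tsv`, `<prefix>_summary.json`.
#' @return named character vector of the written paths, invisibly.
#' @export
writeEnhancers <- function(enhancers, prefix) {
    df <- as.data.frame(enhancers)
    bed <- data.frame(chrom = df$seqnames, start = df$start - 1L,
                      end = df$end,
                      name = if (!is.null(df$rank)) df$rank
                             else seq_len(nrow(df)),
                      score = if (!is.null(df$combinedStatus))
                                  unname(.statusCodes[df$combinedStatus])
                              else 0L,
                      strand = ".")
    paths <- c(bed = paste0(prefix, ".bed"), tsv = paste0(prefix, ".tsv"),
               json = paste0(prefix, "_summary.json"))
    write.table(bed, paths["bed"], sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    write.table(df, paths["tsv"], sep = "\t", quote = FALSE,
                row.names = FALSE)
    counts <- as.list(table(factor(df$combinedStatus,
                                   levels = names(.statusCodes))))
    write_json(counts, paths["json"], auto_unbox = TRUE)
    invisible(paths)
}

#' Write a signal matrix as TSV plus a JSON geometry sidecar
#'
#' @param x a [SignalMatrix-class].
#' @param path output TSV path; the sidecar is written to `<path>.json`.
#' @return the TSV path, invisibly.
#' @export
writeSignalMatrix <- function(x, path) {
    reg <- matrixRegions(x)
    df <- data.frame(region = sprintf("%s:%d-%d", seqnames(reg),
                                      start(reg) - 1L, end(reg)),
                     matrixValues(x), check.names = FALSE)
    colnames(df) <- c("region", paste0("bin", seq_len(x@nBins)))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    write_json(list(flank = x@flank, nBins = x@nBins, binWidth = x@binWidth,
                    nRegions = length(reg)),
               paste0(path, ".json"), auto_unbox = TRUE)
    invisible(path)
}
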