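#' Analysis thresholds for the enhancer-target pipeline
#'
#' Bundles every tunable threshold of the pipeline with the published
#' defaults: enhancer peaks must lie at least `distalMinTssGap` (1.5 kb)
#' from every TSS; differential enhancers are called at a
#' `enhancerFoldChange` (1.2-fold) change of total region signal;
#' enhancer-gene links require a TSS gap of at most `linkMaxDistance`
#' (10 kb); DEGs are called at `degFoldChange` (1.5-fold) on FPKM after
#' excluding genes below `minFpkm` (1) in all samples.  Pseudocounts guard
#' the two ratios: `signalPseudocount` raw reads are added to region totals
#' before RPKM normalisation, `fpkmPseudocount` FPKM before expression
#' ratios.
#'
#' @param distalMinTssGap minimum gap (bp) from an enhancer boundary to
#'   every TSS (inclusive `>=`).
#' @param enhancerFoldChange fold-change threshold for enhancer signal
#'   (`> 1`; "down" means ratio `<= 1/enhancerFoldChange`, inclusive).
#' @param linkMaxDistance maximum enhancer-TSS gap (bp) for a link
#'   (inclusive `<=`).
#' @param degFoldChange fold-change threshold for DEG calls (`> 1`,
#'   inclusive on both sides).
#' @param minFpkm expression floor: genes below this in *all* samples are
#'   excluded.
#' @param signalPseudocount raw reads added to each region total before
#'   normalisation.
#' @param fpkmPseudocount FPKM added to condition means before the ratio.
#' @return a validated named list of class `AnalysisConfig`.
#' @examples
#' cfg <- analysisConfig()
#' cfg$linkMaxDistance
#' @export
analysisConfig <- function(distalMinTssGap = 1500,
                           enhancerFoldChange = 1.2,
                           linkMaxDistance = 10000,
                           degFoldChange = 1.5,
                           minFpkm = 1.0,
                           signalPseudocount = 1.0,
                           fpkmPseudocount = 0.01) {
    cfg <- list(distalMinTssGap = distalMinTssGap,
                enhancerFoldChange = enhancerFoldChange,
                linkMaxDistance = linkMaxDistance,
                degFoldChange = degFoldChange,
                minFpkm = minFpkm,
                signalPseudocount = signalPseudocount,
                fpkmPseudocount = fpkmPseudocount)
    if (any(vapply(cfg, function(x) !is.numeric(x) || length(x) != 1L ||
                       is.na(x) || x <= 0, logical(1L))))
        stop("all AnalysisConfig values must be single positive numbers")
    if (enhancerFoldChange <= 1 || degFoldChange <= 1)
        stop("fold-change thresholds must be > 1")
    structure(cfg, class = "AnalysisConfig")
}

#' Identify active enhancers from co-occurring distal histone-mark peaks
#'
#' An active enhancer is a region with overlapping H3K4me1 and H3K27ac
#' peaks whose boundaries are distal to all promoters.  Candidate regions
#' are the merged union of every H3K4me1 peak that overlaps at least one
#' H3K27ac peak together with those overlapping H3K27ac peaks; a merged
#' region is retained only if its gap (see [intervalDistance()]) to every
#' TSS is at least `cfg$distalMinTssGap` (default 1.5 kb).  H3K4me1 peaks
#' with no H3K27ac support never seed an enhancer.
#'
#' @param k4me1Peaks,k27acPeaks `GRanges` of called peaks for each mark
#'   (typically control-condition calls).
#' @param tss `GRanges` of width-1 TSS positions (see [readTss()]).
#' @param cfg an [analysisConfig()].
#' @param regionFrom `"union"` (default) takes the merged union of both
#'   marks' co-overlapping peaks as the enhancer region; `"k4me1"` uses
#'   only the supported H3K4me1 peaks.
#' @return sorted `GRanges` of enhancer regions.
#' @export
identifyActiveEnhancers <- function(k4me1Peaks, k27acPeaks, tss,
                                    cfg = analysisConfig(),
                                    regionFrom = c("union", "k4me1")) {
    regionFrom <- match.arg(regionFrom)
    empty <- GRanges()
    if (length(k4me1Peaks) == 0L || length(k27acPeaks) == 0L) return(empty)
    hits <- findOverlaps(k4me1Peaks, k27acPeaks, ignore.strand = TRUE)
    if (length(hits) == 0L) return(empty)
    k4sel <- k4me1Peaks[unique(queryHits(hits))]
    parts <- if (regionFrom == "union") {
        k27sel <- k27acPeaks[unique(subjectHits(hits))]
        c(granges(k4sel), granges(k27sel))
    } else granges(k4sel)
    regions <- mergeIntervals(parts)
    if (length(tss)) {
        gap <- minDistanceToPositions(regions, tss)
        regions <- regions[gap >= cfg$distalMinTssGap]
    }
    regions
}

#' Rank enhancers by total H3K4me1 signal
#'
#' Rank 1 is the enhancer with the largest control-condition H3K4me1 RPKM
#' total; ties are broken by (chromosome, start).  The rank is stored in
#' `mcols(x)$rank` (and mirrored in `name`-friendly form when exported).
#'
#' @param enhancers `GRanges` of enhancer regions.
#' @param k4me1Control control-condition H3K4me1 [BinnedTrack-class].
#' @return `enhancers` with added metadata columns `k4me1Rpkm` and `rank`.
#' @export
rankEnhancers <- function(enhancers, k4me1Control) {
    sig <- rpkm(regionSignal(k4me1Control, enhancers), width(enhancers),
                libSize(k4me1Control))
    ord <- order(-sig, as.character(seqnames(enhancers)), start(enhancers))
    rk <- integer(length(sig)); rk[ord] <- seq_along(ord)
    mcols(enhancers)$k4me1Rpkm <- sig
    mcols(enhancers)$rank <- rk
    enhancers
}

.markStatus <- function(ratio, fc) {
    ifelse(ratio <= 1 / fc, "down", ifelse(ratio >= fc, "up", "stable"))
}

.combinedStatus <- function(k4, k27) {
    ifelse(k4 == "down" & k27 == "down", "down_both",
    ifelse(k4 == "up" & k27 == "up", "up_both",
    ifelse(k4 == "down" & k27 == "stable", "down_k4me1_only",
    ifelse(k27 == "down" & k4 == "stable", "down_k27ac_only",
    ifelse((k4 == "up" & k27 == "down") | (k4 == "down" & k27 == "up"),
           "mixed", "stable")))))
}

#' Classify enhancer signal change after knockdown
#'
#' For each mark, the total signal over the enhancer region is computed in
#' the control and (pooled) knockdown tracks, a pseudocount of
#' `cfg$signalPseudocount` raw reads is added, and both totals are RPKM
#' normalised (the pooled knockdown library is roughly twice the control
#' depth, so depth normalisation is essential).  A mark is "down" when
#' knockdown/control `<= 1/enhancerFoldChange`, "up" when
#' `>= enhancerFoldChange`, else "stable".  The combined status is a pure
#' function of the two per-mark statuses: `down_both`, `up_both`,
#' `down_k4me1_only` / `down_k27ac_only` (one down, other stable), `mixed`
#' (one up, one down), otherwise `stable`.
#'
#' @param enhancers `GRanges` of enhancer regions.
#' @param tracks nested list
#'   `list(k4me1 = list(control =, knockdown =), k27ac = list(...))` of
#'   [BinnedTrack-class] objects; a `knockdown` element that is itself a
#'   list of replicate tracks is pooled with [poolTracks()].
#' @param cfg an [analysisConfig()].
#' @return `enhancers` with per-mark per-condition RPKM totals, ratios,
#'   per-mark statuses and `combinedStatus` metadata columns.
#' @export
classifyEnhancers <- function(enhancers, tracks, cfg = analysisConfig()) {
    stopifnot(all(c("k4me1", "k27ac") %in% names(tracks)))
    if (any(width(enhancers) == 0L)) stop("zero-length enhancer region")
    for (mark in c("k4me1", "k27ac")) {
        tr <- tracks[[mark]]
        stopifnot(all(c("control", "knockdown") %in% names(tr)))
        kd <- tr$knockdown
        if (is.list(kd)) kd <- poolTracks(kd)
        sNc <- rpkm(regionSignal(tr$control, enhancers) + cfg$signalPseudocount,
                    width(enhancers), libSize(tr$control))
        sKd <- rpkm(regionSignal(kd, enhancers) + cfg$signalPseudocount,
                    width(enhancers), libSize(kd))
        ratio <- sKd / sNc
        mcols(enhancers)[[paste0(mark, "Control")]] <- sNc
        mcols(enhancers)[[paste0(mark, "Knockdown")]] <- sKd
        mcols(enhancers)[[paste0(mark, "Ratio")]] <- ratio
        mcols(enhancers)[[paste0(mark, "Status")]] <-
            .markStatus(ratio, cfg$enhancerFoldChange)
    }
    mcols(enhancers)$combinedStatus <-
        .combinedStatus(mcols(enhancers)$k4me1Status,
                        mcols(enhancers)$k27acStatus)
    enhancers
}

#' Link enhancers to genes by nearest-TSS distance
#'
#' Gene-centric assignment: for each gene the minimal gap (see
#' [intervalDistance()]) to any enhancer is computed; a link is emitted iff
#' that minimum is at most `cfg$linkMaxDistance` (10 kb).  Each gene links
#' to exactly one enhancer — its nearest; ties go to the enhancer earlier
#' in (chromosome, start) order.
#'
#' @param enhancers `GRanges` of enhancer regions (assumed sorted; the
#'   returned index refers to this object).
#' @param tss `GRanges` of width-1 TSS positions with a `gene_id` metadata
#'   column.
#' @param cfg an [analysisConfig()].
#' @param enhancerCentric if `TRUE`, reduce the links to at most one gene
#'   per enhancer (its nearest linked gene, ties by `gene_id`); the default
#'   gene-centric rule keeps one link per gene instead.
#' @return `DataFrame` with columns `gene_id`, `enhancer` (integer index
#'   into `enhancers`) and `distance` (bp).
#' @export
linkEnhancersToGenes <- function(enhancers, tss, cfg = analysisConfig(),
                                 enhancerCentric = FALSE) {
    out <- DataFrame(gene_id = character(0L), enhancer = integer(0L),
                     distance = numeric(0L))
    if (length(enhancers) == 0L || length(tss) == 0L) return(out)
    es <- as.character(seqnames(enhancers))
    ts <- as.character(seqnames(tss))
    gene <- character(0L); enh <- integer(0L); dist <- numeric(0L)
    for (chr in unique(ts)) {
        gi <- which(ts == chr)
        ei <- which(es == chr)
        if (length(ei) == 0L) next
        eiOrd <- ei[order(start(enhancers)[ei], end(enhancers)[ei])]
        s <- start(enhancers)[eiOrd]; e <- end(enhancers)[eiOrd]
        for (g in gi) {
            p1 <- start(tss)[g]
            d <- pmax(s - p1, p1 - e - 1L, 0L)
            m <- min(d)
            if (m <= cfg$linkMaxDistance) {
                gene <- c(gene, mcols(tss)$gene_id[g])
                enh <- c(enh, eiOrd[which.min(d)])  # first in genomic order
                dist <- c(dist, m)
            }
        }
    }
    res <- DataFrame(gene_id = gene, enhancer = enh, distance = dist)
    if (enhancerCentric && nrow(res)) {
        # keep, per enhancer, only its closest gene (ties: first gene_id);
        # gene-centric links to other enhancers are retained unchanged
        sp <- split(seq_len(nrow(res)), res$enhancer)
        keep <- vapply(sp, function(i) {
            i[order(res$distance[i], res$gene_id[i])][1L]
        }, integer(1L))
        res <- res[sort(keep), , drop = FALSE]
    }
    res[order(res$gene_id), , drop = FALSE]
}
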