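#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

#' Build an expression SummarizedExperiment from an FPKM matrix
#'
#' Thin constructor wrapping a gene x sample FPKM matrix and per-sample
#' condition labels into a `SummarizedExperiment` with assay `"fpkm"`.
#' Conditions must include `"control"` and at least one knockdown label
#' (conventionally `"kd1"` and `"kd2"` for the two siRNAs).
#'
#' @param fpkm numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns.
#' @param condition character vector of per-sample condition labels.
#' @return a `SummarizedExperiment`.
#' @export
expressionTable <- function(fpkm, condition) {
    fpkm <- as.matrix(fpkm)
    if (any(fpkm < 0)) stop("FPKM values must be non-negative")
    if (length(condition) != ncol(fpkm))
        stop("one condition label per sample required")
    if (!"control" %in% condition)
        stop("conditions must include 'control'")
    if (is.null(rownames(fpkm)) && nrow(fpkm) > 0L)
        stop("'fpkm' must carry gene ids as rownames")
    SummarizedExperiment(assays = list(fpkm = fpkm),
                         colData = DataFrame(condition = condition))
}

#' Remove genes below the expression floor in every sample
#'
#' A gene is retained iff its maximum FPKM over *all* samples is at least
#' `cfg$minFpkm` (default 1); equivalently, genes with FPKM below the
#' floor in all samples are excluded.  Row order is preserved.
#'
#' @param se expression `SummarizedExperiment` (assay `"fpkm"`).
#' @param cfg an [analysisConfig()].
#' @return the filtered `SummarizedExperiment`.
#' @export
filterExpressed <- function(se, cfg = analysisConfig()) {
    m <- assay(se, "fpkm")
    if (nrow(m) == 0L) return(se)
    keep <- apply(m, 1L, max) >= cfg$minFpkm
    se[keep, ]
}

#' Call differentially expressed genes for one knockdown condition
#'
#' Per gene, the fold change is
#' `(mean FPKM in knockdown + fpkmPseudocount) / (mean FPKM in control +
#' fpkmPseudocount)` (replicates averaged per condition when present).
#' Direction is `"up"` when fold `>= degFoldChange` (1.5), `"down"` when
#' fold `<= 1/degFoldChange`, else `"unchanged"`.  The table should have
#' been filtered with [filterExpressed()] first.
#'
#' @param se filtered expression `SummarizedExperiment`.
#' @param knockdown condition label of the knockdown samples (e.g.
#'   `"kd1"`).
#' @param cfg an [analysisConfig()].
#' @return `data.frame` with `gene_id`, `fold`, `direction`.
#' @export
callDegs <- function(se, knockdown, cfg = analysisConfig()) {
    cond <- colData(se)$condition
    if (!knockdown %in% cond)
        stop("unknown condition label: ", knockdown)
    m <- assay(se, "fpkm")
    mc <- rowMeans(m[, cond == "control", drop = FALSE])
    mk <- rowMeans(m[, cond == knockdown, drop = FALSE])
    fold <- (mk + cfg$fpkmPseudocount) / (mc + cfg$fpkmPseudocount)
    dir <- ifelse(fold >= cfg$degFoldChange, "up",
                  ifelse(fold <= 1 / cfg$degFoldChange, "down", "unchanged"))
    data.frame(gene_id = rownames(m), fold = fold, direction = dir,
               row.names = NULL)
}

#' Direction-consistent overlap of two knockdown DEG sets
#'
#' Genes called in the same direction by both siRNAs form the overlaps
#' (the Venn intersections); genes called in opposite directions are
#' excluded from both and counted separately.
#'
#' @param callsKd1,callsKd2 DEG tables from [callDegs()] over the same
#'   gene universe.
#' @return list with character vectors `up` and `down` (the overlaps),
#'   `opposite` (direction-discordant genes) and a named integer vector
#'   `counts` with per-siRNA and overlap tallies.
#' @export
overlapDegs <- function(callsKd1, callsKd2) {
    up1 <- callsKd1$gene_id[callsKd1$direction == "up"]
    dn1 <- callsKd1$gene_id[callsKd1$direction == "down"]
    up2 <- callsKd2$gene_id[callsKd2$direction == "up"]
    dn2 <- callsKd2$gene_id[callsKd2$direction == "down"]
    list(up = intersect(up1, up2),
         down = intersect(dn1, dn2),
         opposite = union(intersect(up1, dn2), intersect(dn1, up2)),
         counts = c(upKd1 = length(up1), downKd1 = length(dn1),
                    upKd2 = length(up2), downKd2 = length(dn2),
                    upOverlap = length(intersect(up1, up2)),
                    downOverlap = length(intersect(dn1, dn2)),
                    opposite = length(union(intersect(up1, dn2),
                                            intersect(dn1, up2)))))
}

#' Relative expression by the delta-delta-Ct method
#'
#' Fold change of condition B relative to condition A from qPCR cycle
#' thresholds, normalised to a reference gene (conventionally beta-actin):
#' `efficiency ^ -((ctTargetB - ctRefB) - (ctTargetA - ctRefA))`.
#' Amplification efficiency defaults to 2 (perfect doubling per cycle).
#'
#' @param ctTargetA,ctRefA target/reference Ct in condition A.
#' @param ctTargetB,ctRefB target/reference Ct in condition B.
#' @param efficiency per-cycle amplification factor (default 2).
#' @return fold change(s) of B versus A.
#' @examples
#' relativeExpressionDdct(20, 15, 21, 15)  # 0.5: one cycle later = halved
#' @export
relativeExpressionDdct <- function(ctTargetA, ctRefA, ctTargetB, ctRefB,
                                   efficiency = 2) {
    stopifnot(efficiency > 1)
    ddct <- (ctTargetB - ctRefB) - (ctTargetA - ctRefA)
    efficiency^(-ddct)
}
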