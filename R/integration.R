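#' Nominate direct target genes from the repressed-enhancer/DEG funnel
#'
#' The final funnel stage: a gene is a candidate direct target iff it is
#' (i) downregulated consistently in both knockdowns (member of the DEG
#' down-overlap) and (ii) linked (nearest enhancer within 10 kb) to an
#' enhancer whose combined status is in `repressedStatuses` (default
#' `"down_both"`, i.e. both histone marks reduced).  Candidates are sorted
#' by enhancer distance (ascending), ties by gene id.
#'
#' @param downOverlap character vector of down-overlap gene ids (from
#'   [overlapDegs()]).
#' @param links `DataFrame` from [linkEnhancersToGenes()] computed against
#'   the same `enhancers` object.
#' @param enhancers classified enhancer `GRanges` (from
#'   [classifyEnhancers()], with a `combinedStatus` column).
#' @param repressedStatuses statuses counting as "repressed"; add
#'   `"down_k4me1_only"` to widen the funnel to all H3K4me1-down enhancers.
#' @param degsKd1,degsKd2 optional DEG tables ([callDegs()]) used to attach
#'   per-siRNA fold changes to the candidates.
#' @return `data.frame` with `gene_id`, `enhancer` (index), `distance`,
#'   and (when DEG tables are given) `foldKd1`, `foldKd2`.
#' @export
nominateTargets <- function(downOverlap, links, enhancers,
                            repressedStatuses = "down_both",
                            degsKd1 = NULL, degsKd2 = NULL) {
    if (nrow(links) == 0L || length(enhancers) == 0L)
        return(data.frame(gene_id = character(0L), enhancer = integer(0L),
                          distance = numeric(0L)))
    if (max(links$enhancer) > length(enhancers) || min(links$enhancer) < 1L)
        stop("link references an enhancer index outside the enhancer set")
    status <- mcols(enhancers)$combinedStatus
    if (is.null(status))
        stop("'enhancers' carries no combinedStatus; run classifyEnhancers()")
    keep <- links$gene_id %in% downOverlap &
        status[links$enhancer] %in% repressedStatuses
    res <- as.data.frame(links[keep, , drop = FALSE])
    res <- res[order(res$distance, res$gene_id), , drop = FALSE]
    rownames(res) <- NULL
    if (!is.null(degsKd1))
        res$foldKd1 <- degsKd1$fold[match(res$gene_id, degsKd1$gene_id)]
    if (!is.null(degsKd2))
        res$foldKd2 <- degsKd2$fold[match(res$gene_id, degsKd2$gene_id)]
    res
}

#' Fraction of a gene set present in an annotation list
#'
#' `|genes intersect annotation| / |genes|` — e.g. the share of
#' migration-related genes among overlap DEGs.  The annotation list is a
#' user-supplied gene-id set (curated lists are external inputs, never
#' bundled).  By convention the fraction of an empty gene set is 0.
#'
#' @param genes character vector of gene ids (duplicates ignored).
#' @param annotation character vector of annotated gene ids.
#' @return a single number in `[0, 1]`.
#' @examples
#' annotateGeneSetFraction(c("A", "B", "C", "D"), c("B", "D"))  # 0.5
#' @export
annotateGeneSetFraction <- function(genes, annotation) {
    genes <- unique(genes)
    if (length(genes) == 0L) return(0)
    length(intersect(genes, annotation)) / length(genes)
}
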