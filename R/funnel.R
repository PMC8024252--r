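#' Run the full enhancer-to-target-gene funnel
#'
#' Orchestrates the pipeline end to end: active-enhancer identification
#' (co-occurring distal peaks), H3K4me1 ranking, differential
#' classification against the pooled knockdown tracks, enhancer-gene
#' linkage, expression-floor filtering, per-siRNA DEG calls,
#' direction-consistent overlap, and candidate nomination.  All thresholds
#' come from `cfg`.
#'
#' @param k4me1Peaks,k27acPeaks peak `GRanges` per mark.
#' @param tss width-1 TSS `GRanges` with `gene_id`.
#' @param tracks nested track list as for [classifyEnhancers()].
#' @param expr expression `SummarizedExperiment` with conditions
#'   `control`, `kd1`, `kd2`.
#' @param cfg an [analysisConfig()].
#' @param repressedStatuses enhancer statuses treated as repressed when
#'   nominating candidates (default `"down_both"`).
#' @return a `FunnelReport`: list with the classified `enhancers`,
#'   `links`, DEG tables `degsKd1`/`degsKd2`, `overlaps`, `candidates`,
#'   and a named integer vector `counts` of every funnel stage.
#' @export
runFunnel <- function(k4me1Peaks, k27acPeaks, tss, tracks, expr,
                      cfg = analysisConfig(),
                      repressedStatuses = "down_both") {
    enh <- identifyActiveEnhancers(k4me1Peaks, k27acPeaks, tss, cfg)
    if (length(enh)) {
        enh <- rankEnhancers(enh, tracks$k4me1$control)
        enh <- classifyEnhancers(enh, tracks, cfg)
    }
    links <- linkEnhancersToGenes(enh, tss, cfg)
    exprF <- filterExpressed(expr, cfg)
    degs1 <- callDegs(exprF, "kd1", cfg)
    degs2 <- callDegs(exprF, "kd2", cfg)
    ov <- overlapDegs(degs1, degs2)
    cand <- nominateTargets(ov$down, links, enh, repressedStatuses,
                            degsKd1 = degs1, degsKd2 = degs2)
    status <- if (length(enh)) mcols(enh)$combinedStatus else character(0L)
    counts <- c(activeEnhancers = length(enh),
                downK4me1 = sum(if (length(enh))
                    mcols(enh)$k4me1Status == "down" else logical(0L)),
                downK27ac = sum(if (length(enh))
                    mcols(enh)$k27acStatus == "down" else logical(0L)),
                downBoth = sum(status == "down_both"),
                upBoth = sum(status == "up_both"),
                linkedGenes = nrow(links),
                expressedGenes = nrow(exprF),
                ov$counts,
                candidates = nrow(cand))
    structure(list(enhancers = enh, links = links, degsKd1 = degs1,
                   degsKd2 = degs2, overlaps = ov, candidates = cand,
                   counts = counts, config = unclass(cfg),
                   repressedStatuses = repressedStatuses),
              class = "FunnelReport")
}

#' @export
print.FunnelReport <- function(x, ...) {
    cat("Enhancer-target funnel\n")
    cat(sprintf("  active enhancers        %6d\n", x$counts["activeEnhancers"]))
    cat(sprintf("  H3K4me1 down            %6d\n", x$counts["downK4me1"]))
    cat(sprintf("  both marks down         %6d\n", x$counts["downBoth"]))
    cat(sprintf("  genes linked (<=%g bp)  %6d\n",
                x$config$linkMaxDistance, x$counts["linkedGenes"]))
    cat(sprintf("  DEG down overlap        %6d\n", x$counts["downOverlap"]))
    cat(sprintf("  candidate targets       %6d\n", x$counts["candidates"]))
    if (nrow(x$candidates)) {
        cat("  nearest candidates:\n")
        print(utils::head(x$candidates, 5L))
    }
    invisible(x)
}

#' Simulate a study and run the funnel on it
#'
#' Convenience wrapper: [simulateStudy()] then [runFunnel()], returning
#' the report with the simulation attached (for truth evaluation with
#' [evaluateRecovery()]).
#'
#' @param simCfg a [simConfig()].
#' @param cfg an [analysisConfig()].
#' @param repressedStatuses passed to [runFunnel()].
#' @return a `FunnelReport` with an extra `sim` element.
#' @export
runFunnelSim <- function(simCfg = simConfig(), cfg = analysisConfig(),
                         repressedStatuses = "down_both") {
    sim <- simulateStudy(simCfg)
    rep <- runFunnel(sim$peaks$k4me1, sim$peaks$k27ac, sim$tss, sim$tracks,
                     sim$expr, cfg, repressedStatuses)
    rep$sim <- sim
    rep
}

#' Score pipeline recovery against the planted truth
#'
#' Compares a funnel report with the generating `TruthManifest`:
#' candidate precision/recall against the planted target genes (coupled
#' gene, affected enhancer, planted down-DEG), and per-enhancer
#' `down_both` sensitivity (affected enhancers recovered) and
#' false-positive rate (unaffected enhancers called down), matching
#' enhancers to the truth by coordinate overlap.
#'
#' @param report a `FunnelReport` (typically from [runFunnelSim()]).
#' @param manifest the `TruthManifest`; defaults to the one attached to
#'   the report.
#' @return named numeric vector: `precision`, `recall`,
#'   `downBothSensitivity`, `downBothFpr`, `nPlantedTargets`,
#'   `nCandidates`, `nAffectedEnhancers`, `nUnaffectedEnhancers`.
#' @export
evaluateRecovery <- function(report, manifest = report$sim$manifest) {
    g <- manifest$genes
    truth <- g$gene_id[g$coupled & g$plantedDeg == "down"]
    cand <- report$candidates$gene_id
    tp <- length(intersect(cand, truth))
    precision <- if (length(cand)) tp / length(cand) else NA_real_
    recall <- if (length(truth)) tp / length(truth) else NA_real_

    enhTruth <- .df2gr(manifest$enhancers)
    called <- report$enhancers
    sens <- fpr <- NA_real_
    nAff <- sum(manifest$enhancers$affected)
    nUn <- sum(!manifest$enhancers$affected)
    if (length(called)) {
        hits <- findOverlaps(enhTruth, called, ignore.strand = TRUE)
        down <- rep(FALSE, length(enhTruth))
        down[queryHits(hits)] <-
            mcols(called)$combinedStatus[subjectHits(hits)] == "down_both"
        if (nAff) sens <- sum(down & manifest$enhancers$affected) / nAff
        if (nUn) fpr <- sum(down & !manifest$enhancers$affected) / nUn
    }
    c(precision = precision, recall = recall,
      downBothSensitivity = sens, downBothFpr = fpr,
      nPlantedTargets = length(truth), nCandidates = length(cand),
      nAffectedEnhancers = nAff, nUnaffectedEnhancers = nUn)
}

#' Write a funnel report as JSON (+ optional candidates TSV)
#'
#' The JSON mirrors the stage counts of the published funnel (active
#' enhancers, per-mark down calls, both-marks-down, linked genes, DEG
#' counts and overlaps, candidates) with the config echo, so runs are
#' directly comparable.
#'
#' @param report a `FunnelReport`.
#' @param path output JSON path.
#' @param candidatesTsv optional path for a candidates TSV.
#' @return `path`, invisibly.
#' @export
writeRunReport <- function(report, path, candidatesTsv = NULL) {
    out <- list(counts = as.list(report$counts),
                config = report$config,
                repressedStatuses = report$repressedStatuses,
                candidates = report$candidates)
    write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
    if (!is.null(candidatesTsv))
        write.table(report$candidates, candidatesTsv, sep = "\t",
                    quote = FALSE, row.names = FALSE)
    invisible(path)
}
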