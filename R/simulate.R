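#' @importFrom stats rpois rlnorm rnorm runif sd
NULL

#' Configuration for the synthetic study generator
#'
#' Describes the planted ground truth the generator emulates: a genome of
#' gene/enhancer blocks; enhancers carrying both histone marks; a coupled
#' subset of genes within 10 kb of their enhancer (one planted at exactly
#' 7,000 bp, mirroring the geometry of the motivating TNS3 case); decoy
#' promoter-proximal peaks that the distal filter must remove; H3K4me1-only
#' peaks that the co-occurrence rule must reject; a knockdown condition
#' with two replicate ChIP tracks (so the pooled knockdown library is
#' about twice the control depth) in which affected enhancers lose a
#' multiplicative fraction of both marks; and an FPKM table for control
#' plus two knockdown siRNAs with planted fold changes, decoy DEGs and
#' sub-floor genes.
#'
#' @param nChroms number of chromosomes.
#' @param nEnhancers number of enhancer/gene blocks.
#' @param nExtraGenes gene-only blocks (hosts for decoy DEGs, planted
#'   up-DEGs and sub-floor genes).
#' @param blockSize bp per block.
#' @param enhancerWidth enhancer width in bp.
#' @param binSize track bin width in bp.
#' @param fractionCoupled fraction of enhancers whose gene TSS lies within
#'   10 kb (the rest are placed beyond it).
#' @param fractionAffected fraction of enhancers losing signal after
#'   knockdown.
#' @param fractionDecoyPromoter fraction of genes receiving a
#'   promoter-proximal peak of both marks.
#' @param fractionK4Only fraction of blocks receiving an H3K4me1-only
#'   peak.
#' @param enhancerEffect multiplicative factor in `(0, 1]` applied to the
#'   knockdown enrichment of affected enhancers (both marks).
#' @param expressionEffect fold applied to coupled-affected genes'
#'   knockdown expression (down) and planted up-DEGs (up).
#' @param backgroundRate expected reads per bin outside features.
#' @param enhancerEnrichment additional expected reads per bin inside
#'   features.
#' @param kdReps number of knockdown replicate tracks (pooled downstream).
#' @param baseFpkm,baseLogSd log-normal parameters of baseline expression.
#' @param noiseCv coefficient of variation of per-sample multiplicative
#'   log-normal expression noise.
#' @param fractionDecoyDeg,fractionUpDeg,fractionLowExpr fractions of the
#'   extra genes planted as down-DEGs without a nearby enhancer, up-DEGs,
#'   and sub-1-FPKM genes respectively.
#' @param qpcrDeltaCt Ct advantage of the interacting 3C primer pair.
#' @param qpcrKdShift Ct penalty of the interacting pair after knockdown.
#' @param qpcrNoiseSd Gaussian replicate noise on Ct values.
#' @param qpcrReps qPCR replicates.
#' @param seed integer seed; identical config + seed gives bit-identical
#'   output.
#' @return a validated named list of class `SimConfig`.
#' @export
simConfig <- function(nChroms = 2L, nEnhancers = 200L, nExtraGenes = 60L,
                      blockSize = 30000L, enhancerWidth = 1000L,
                      binSize = 50L,
                      fractionCoupled = 0.8, fractionAffected = 0.1,
                      fractionDecoyPromoter = 0.3, fractionK4Only = 0.2,
                      enhancerEffect = 0.5, expressionEffect = 2,
                      backgroundRate = 0.5, enhancerEnrichment = 10,
                      kdReps = 2L,
                      baseFpkm = 20, baseLogSd = 1, noiseCv = 0.1,
                      fractionDecoyDeg = 0.3, fractionUpDeg = 0.2,
                      fractionLowExpr = 0.2,
                      qpcrDeltaCt = 2, qpcrKdShift = 1, qpcrNoiseSd = 0.05,
                      qpcrReps = 3L, seed = 1L) {
    cfg <- as.list(environment())
    fr <- c(fractionCoupled, fractionAffected, fractionDecoyPromoter,
            fractionK4Only, fractionDecoyDeg, fractionUpDeg,
            fractionLowExpr)
    if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
    if (enhancerEffect <= 0 || enhancerEffect > 1)
        stop("'enhancerEffect' must be in (0, 1]")
    if (backgroundRate < 0 || enhancerEnrichment < 0)
        stop("rates must be non-negative")
    if (fractionDecoyDeg + fractionUpDeg + fractionLowExpr > 1)
        stop("extra-gene class fractions must sum to at most 1")
    if (nEnhancers < 1L) stop("need at least one enhancer")
    structure(cfg, class = "SimConfig")
}

# fixed within-block layout (0-based offsets); kept well clear of block
# boundaries so no feature of one block comes within 1.5 kb of another
# block's TSS
.layout <- list(k4onlyStart = 1000L, k4onlyWidth = 1000L,
                enhancerStart = 12000L,
                coupledRange = c(2500L, 9500L),
                uncoupledRange = c(11000L, 14000L),
                extraTss = 15000L, decoyHalf = 400L, margin = 2000L)

.seedOffset <- function(seed, k) as.integer((seed + k) %% .Machine$integer.max)

#' Place genes, enhancers and decoy peaks with known geometry
#'
#' Lays out one enhancer + gene per block with a controlled TSS gap
#' (coupled genes at 2.5-9.5 kb, one forced to exactly 7,000 bp; uncoupled
#' genes beyond 10 kb), gene-only blocks for the extra genes, decoy
#' promoter peaks within the 1.5-kb exclusion zone of their TSS, and
#' H3K4me1-only peaks.  All placements are non-overlapping by
#' construction; the block size is checked for feasibility.
#'
#' @param cfg a [simConfig()].
#' @return a `TruthManifest`: list with data frames `genes`, `enhancers`,
#'   `decoys`, `k4only` (0-based half-open coordinates), the id of the
#'   7,000-bp planted gene (`tns3Like`), `chromLengths` and the config
#'   echo.
#' @export
simulateAnnotation <- function(cfg = simConfig()) {
    set.seed(.seedOffset(cfg$seed, 0L))
    L <- .layout
    maxEnd <- L$enhancerStart + cfg$enhancerWidth + L$uncoupledRange[2L] +
        L$margin
    if (maxEnd > cfg$blockSize)
        stop("blockSize ", cfg$blockSize, " too small for layout needing ",
             maxEnd, " bp per block")
    nBlocks <- cfg$nEnhancers + cfg$nExtraGenes
    perChrom <- ceiling(nBlocks / cfg$nChroms)
    chrom <- paste0("chr", (seq_len(nBlocks) - 1L) %/% perChrom + 1L)
    offset <- ((seq_len(nBlocks) - 1L) %% perChrom) * cfg$blockSize
    chromLengths <- stats::setNames(
        rep(perChrom * cfg$blockSize + 1000L, cfg$nChroms),
        paste0("chr", seq_len(cfg$nChroms)))

    nE <- cfg$nEnhancers
    coupled <- rep(FALSE, nE)
    coupled[sample.int(nE, round(cfg$fractionCoupled * nE))] <- TRUE
    coupled[1L] <- TRUE                       # block 1 hosts the 7-kb gene
    affected <- rep(FALSE, nE)
    affected[sample.int(nE, round(cfg$fractionAffected * nE))] <- TRUE
    affected[1L] <- TRUE
    dist <- integer(nE)
    dist[coupled] <- sample(seq(L$coupledRange[1L], L$coupledRange[2L]),
                            sum(coupled), replace = TRUE)
    dist[!coupled] <- sample(seq(L$uncoupledRange[1L], L$uncoupledRange[2L]),
                             sum(!coupled), replace = TRUE)
    dist[1L] <- 7000L

    enhStart <- offset[seq_len(nE)] + L$enhancerStart
    enhEnd <- enhStart + cfg$enhancerWidth
    pairedTss <- enhEnd + dist
    geneId <- sprintf("gene%04d", seq_len(nBlocks))
    tss <- c(pairedTss, offset[-seq_len(nE)] + L$extraTss)
    strand <- sample(c("+", "-"), nBlocks, replace = TRUE)

    nX <- cfg$nExtraGenes
    extraClass <- rep("background", nX)
    if (nX > 0L) {
        pool <- sample.int(nX)
        nDn <- round(cfg$fractionDecoyDeg * nX)
        nUp <- round(cfg$fractionUpDeg * nX)
        nLo <- round(cfg$fractionLowExpr * nX)
        extraClass[pool[seq_len(nDn)]] <- "decoyDeg"
        if (nUp) extraClass[pool[nDn + seq_len(nUp)]] <- "upDeg"
        if (nLo) extraClass[pool[nDn + nUp + seq_len(nLo)]] <- "lowExpr"
    }
    plantedDeg <- c(ifelse(coupled & affected, "down", "none"),
                    ifelse(extraClass == "decoyDeg", "down",
                           ifelse(extraClass == "upDeg", "up", "none")))
    lowExpr <- c(rep(FALSE, nE), extraClass == "lowExpr")

    genes <- data.frame(
        gene_id = geneId, chrom = chrom, tss = tss, strand = strand,
        paired_enhancer = c(seq_len(nE), rep(NA_integer_, nX)),
        coupled = c(coupled, rep(FALSE, nX)),
        distance = c(dist, rep(NA_integer_, nX)),
        plantedDeg = plantedDeg, lowExpr = lowExpr,
        stringsAsFactors = FALSE)
    enhancers <- data.frame(
        enhancer_id = sprintf("enh%04d", seq_len(nE)),
        chrom = chrom[seq_len(nE)], start = enhStart, end = enhEnd,
        affected = affected, gene_id = geneId[seq_len(nE)],
        coupled = coupled, distance = dist, stringsAsFactors = FALSE)

    hasDecoy <- runif(nBlocks) < cfg$fractionDecoyPromoter
    decoys <- data.frame(chrom = chrom[hasDecoy],
                         start = tss[hasDecoy] - L$decoyHalf,
                         end = tss[hasDecoy] + L$decoyHalf,
                         gene_id = geneId[hasDecoy],
                         stringsAsFactors = FALSE)
    hasK4 <- runif(nBlocks) < cfg$fractionK4Only
    k4only <- data.frame(chrom = chrom[hasK4],
                         start = offset[hasK4] + L$k4onlyStart,
                         end = offset[hasK4] + L$k4onlyStart + L$k4onlyWidth,
                         stringsAsFactors = FALSE)

    structure(list(genes = genes, enhancers = enhancers, decoys = decoys,
                   k4only = k4only, tns3Like = geneId[1L],
                   chromLengths = as.list(chromLengths),
                   config = unclass(cfg)),
              class = "TruthManifest")
}

.df2gr <- function(df) {
    if (nrow(df) == 0L) return(GRanges())
    GRanges(df$chrom, IRanges(df$start + 1L, df$end))
}

#' TSS annotation from a truth manifest
#'
#' @param manifest a `TruthManifest` from [simulateAnnotation()].
#' @return width-1 `GRanges` with `gene_id`, as produced by [readTss()].
#' @export
manifestTss <- function(manifest) {
    g <- manifest$genes
    tss <- GRanges(g$chrom, IRanges(g$tss + 1L, g$tss + 1L),
                   strand = g$strand)
    mcols(tss) <- DataFrame(gene_id = g$gene_id)
    tss
}

# expected-rate vector per chromosome, pro-rating feature edges over bins
.rateVectors <- function(manifest, regions, rates, bg, binSize) {
    out <- lapply(manifest$chromLengths, function(len) {
        rep(bg, ceiling(len / binSize))
    })
    for (i in seq_len(nrow(regions))) {
        chr <- regions$chrom[i]
        v <- out[[chr]]
        s <- regions$start[i]; e <- regions$end[i]
        b0 <- s %/% binSize          # 0-based first bin index
        b1 <- (e - 1L) %/% binSize   # last bin
        for (b in b0:b1) {
            ov <- min(e, (b + 1L) * binSize) - max(s, b * binSize)
            v[b + 1L] <- v[b + 1L] + rates[i] * ov / binSize
        }
        out[[chr]] <- v
    }
    out
}

#' Simulate histone-mark ChIP-seq tracks and peak calls
#'
#' Bin counts are Poisson: `backgroundRate` outside features,
#' `backgroundRate + enhancerEnrichment` inside enhancers, decoy promoter
#' peaks and (for H3K4me1) the mark-only peaks.  In the knockdown
#' replicates the enrichment of affected enhancers is multiplied by
#' `enhancerEffect` for both marks.  Peak calling is out of scope, so the
#' planted feature intervals are emitted as the "called" peak sets
#' (H3K4me1: enhancers + decoys + H3K4me1-only peaks; H3K27ac: enhancers +
#' decoys).
#'
#' @param cfg a [simConfig()].
#' @param manifest the matching `TruthManifest`.
#' @return list with `peaks` (`GRanges` per mark) and `tracks`
#'   (`list(k4me1 = list(control =, knockdown = list(...)), k27ac = ...)`
#'   of [BinnedTrack-class]; `knockdown` holds `kdReps` replicate tracks).
#' @export
simulateChipseq <- function(cfg, manifest) {
    set.seed(.seedOffset(cfg$seed, 1L))
    enh <- manifest$enhancers
    featForMark <- list(
        k4me1 = rbind(enh[, c("chrom", "start", "end")],
                      manifest$decoys[, c("chrom", "start", "end")],
                      manifest$k4only),
        k27ac = rbind(enh[, c("chrom", "start", "end")],
                      manifest$decoys[, c("chrom", "start", "end")]))
    nE <- nrow(enh)
    tracks <- list()
    for (mark in c("k4me1", "k27ac")) {
        feats <- featForMark[[mark]]
        baseRates <- rep(cfg$enhancerEnrichment, nrow(feats))
        kdRates <- baseRates
        kdRates[seq_len(nE)][enh$affected] <-
            cfg$enhancerEnrichment * cfg$enhancerEffect
        rvControl <- .rateVectors(manifest, feats, baseRates,
                                  cfg$backgroundRate, cfg$binSize)
        rvKd <- .rateVectors(manifest, feats, kdRates,
                             cfg$backgroundRate, cfg$binSize)
        draw <- function(rv) BinnedTrack(
            lapply(rv, function(mu) rpois(length(mu), mu)),
            binSize = cfg$binSize)
        tracks[[mark]] <- list(
            control = draw(rvControl),
            knockdown = lapply(seq_len(cfg$kdReps), function(i) draw(rvKd)))
    }
    list(peaks = list(k4me1 = .df2gr(featForMark$k4me1),
                      k27ac = .df2gr(featForMark$k27ac)),
         tracks = tracks)
}

#' Simulate an FPKM expression table with planted fold changes
#'
#' Baseline expression is log-normal; genes planted "down" (coupled genes
#' of affected enhancers, plus enhancer-free decoy DEGs) have both
#' knockdown samples divided by `expressionEffect`, planted "up" genes
#' multiplied by it; every sample then receives independent multiplicative
#' log-normal noise with coefficient of variation `noiseCv`.  A planted
#' fraction of genes sits below 1 FPKM in all samples to exercise the
#' expression floor.
#'
#' @param cfg a [simConfig()].
#' @param manifest the matching `TruthManifest`.
#' @return expression `SummarizedExperiment` with samples `control`,
#'   `kd1`, `kd2` (see [expressionTable()]).
#' @export
simulateExpression <- function(cfg, manifest) {
    set.seed(.seedOffset(cfg$seed, 2L))
    g <- manifest$genes
    n <- nrow(g)
    base <- rlnorm(n, meanlog = log(cfg$baseFpkm), sdlog = cfg$baseLogSd)
    base[g$lowExpr] <- runif(sum(g$lowExpr), 0.05, 0.5)
    eff <- ifelse(g$plantedDeg == "down", 1 / cfg$expressionEffect,
                  ifelse(g$plantedDeg == "up", cfg$expressionEffect, 1))
    mu <- cbind(control = base, kd1 = base * eff, kd2 = base * eff)
    if (cfg$noiseCv > 0) {
        sdlog <- sqrt(log(1 + cfg$noiseCv^2))
        noise <- matrix(rlnorm(n * 3L, meanlog = -sdlog^2 / 2, sdlog = sdlog),
                        nrow = n)
        mu <- mu * noise
    }
    rownames(mu) <- g$gene_id
    expressionTable(mu, condition = c("control", "kd1", "kd2"))
}

#' Simulate 3C and ChIP-qPCR Ct tables
#'
#' 3C: promoter primer pairs P1-P5 against the enhancer primer, with the
#' interacting pair (P3) `qpcrDeltaCt` cycles ahead of the flat pairs in
#' the control and shifted back by `qpcrKdShift` cycles after knockdown,
#' plus the non-cut-site reference pair `N`.  ChIP-qPCR: IP and input Cts
#' for both marks on the enhancer, with the knockdown IP one
#' percent-input halving behind the control.  Gaussian replicate noise
#' `qpcrNoiseSd` on every Ct.
#'
#' @param cfg a [simConfig()].
#' @return list with data frames `c3` (long `sample, primer_pair, ct,
#'   replicate` layout) and `chip` (`sample, mark, ct_ip, ct_input,
#'   replicate`), plus `inputFraction` used for the ChIP table.
#' @export
simulateQpcr <- function(cfg = simConfig()) {
    set.seed(.seedOffset(cfg$seed, 3L))
    pairs <- c(paste0("P", 1:5), "N")
    baseCt <- c(rep(32, 5), 26)
    reps <- seq_len(cfg$qpcrReps)
    c3 <- do.call(rbind, lapply(c("siNC", "siMLL3"), function(smp) {
        ct <- baseCt
        ct[3L] <- ct[3L] - cfg$qpcrDeltaCt +
            if (smp == "siMLL3") cfg$qpcrKdShift else 0
        do.call(rbind, lapply(reps, function(r) {
            data.frame(sample = smp, primer_pair = pairs,
                       ct = ct + rnorm(length(ct), 0, cfg$qpcrNoiseSd),
                       replicate = r)
        }))
    }))
    inputFraction <- 0.01
    chip <- do.call(rbind, lapply(c("siNC", "siMLL3"), function(smp) {
        do.call(rbind, lapply(c("H3K4me1", "H3K27ac"), function(mark) {
            pct <- if (smp == "siNC") 2 else 1    # one-cycle drop after kd
            ctInput <- 24
            ctIp <- ctInput - log2(pct / (100 * inputFraction))
            data.frame(sample = smp, mark = mark,
                       ct_ip = ctIp + rnorm(cfg$qpcrReps, 0, cfg$qpcrNoiseSd),
                       ct_input = ctInput +
                           rnorm(cfg$qpcrReps, 0, cfg$qpcrNoiseSd),
                       replicate = reps)
        }))
    }))
    rownames(c3) <- rownames(chip) <- NULL
    list(c3 = c3, chip = chip, inputFraction = inputFraction)
}

#' Simulate a complete study
#'
#' Runs [simulateAnnotation()], [simulateChipseq()],
#' [simulateExpression()] and [simulateQpcr()] under one seed.
#'
#' @param cfg a [simConfig()].
#' @return list with `manifest`, `tss`, `peaks`, `tracks`, `expr`,
#'   `qpcr`.
#' @export
simulateStudy <- function(cfg = simConfig()) {
    manifest <- simulateAnnotation(cfg)
    chip <- simulateChipseq(cfg, manifest)
    list(manifest = manifest, tss = manifestTss(manifest),
         peaks = chip$peaks, tracks = chip$tracks,
         expr = simulateExpression(cfg, manifest),
         qpcr = simulateQpcr(cfg))
}

#' Serialize / restore a truth manifest
#'
#' JSON round trip is lossless for all planted truth (coordinates, flags,
#' distances, class labels, chromosome lengths, config echo).
#'
#' @param manifest a `TruthManifest`.
#' @param path JSON file path.
#' @return `writeManifest` returns `path` invisibly; `readManifest` the
#'   restored `TruthManifest`.
#' @export
writeManifest <- function(manifest, path) {
    write_json(unclass(manifest), path, auto_unbox = TRUE, digits = NA,
               null = "null")
    invisible(path)
}

#' @rdname writeManifest
#' @export
readManifest <- function(path) {
    m <- fromJSON(path, simplifyDataFrame = TRUE)
    for (nm in c("genes", "enhancers", "decoys", "k4only")) {
        m[[nm]] <- as.data.frame(m[[nm]], stringsAsFactors = FALSE)
        if (nrow(m[[nm]]) && "paired_enhancer" %in% names(m[[nm]]))
            m[[nm]]$paired_enhancer <- as.integer(m[[nm]]$paired_enhancer)
    }
    structure(m, class = "TruthManifest")
}

#' Write simulated study inputs to disk in standard formats
#'
#' Emits exactly the file types the analysis readers consume: peak BEDs,
#' per-track bedGraphs, the FPKM TSV + condition map, qPCR CSVs and the
#' manifest JSON.
#'
#' @param sim result of [simulateStudy()].
#' @param dir output directory (created if missing).
#' @return named list of written paths, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    p <- list()
    for (mark in names(sim$peaks)) {
        pk <- sim$peaks[[mark]]
        path <- file.path(dir, paste0("peaks_", mark, ".bed"))
        df <- data.frame(chrom = as.character(seqnames(pk)),
                         start = start(pk) - 1L, end = end(pk))
        write.table(df, path, sep = "\t", quote = FALSE,
                    row.names = FALSE, col.names = FALSE)
        p[[paste0("peaks_", mark)]] <- path
    }
    for (mark in names(sim$tracks)) {
        tr <- sim$tracks[[mark]]
        p[[paste0(mark, "_control")]] <- writeBedGraphTrack(
            tr$control, file.path(dir, paste0(mark, "_control.bedGraph")))
        for (i in seq_along(tr$knockdown))
            p[[paste0(mark, "_kd", i)]] <- writeBedGraphTrack(
                tr$knockdown[[i]],
                file.path(dir, paste0(mark, "_kd", i, ".bedGraph")))
    }
    tssPath <- file.path(dir, "tss.tsv")
    g <- sim$manifest$genes
    write.table(data.frame(gene_id = g$gene_id, chrom = g$chrom,
                           strand = g$strand, tss = g$tss),
                tssPath, sep = "\t", quote = FALSE, row.names = FALSE)
    p$tss <- tssPath
    m <- assay(sim$expr, "fpkm")
    exprPath <- file.path(dir, "fpkm.tsv")
    write.table(data.frame(gene_id = rownames(m), m, check.names = FALSE),
                exprPath, sep = "\t", quote = FALSE, row.names = FALSE)
    p$fpkm <- exprPath
    condPath <- file.path(dir, "conditions.tsv")
    write.table(data.frame(sample = colnames(m),
                           condition = colData(sim$expr)$condition),
                condPath, sep = "\t", quote = FALSE, row.names = FALSE)
    p$conditions <- condPath
    c3Path <- file.path(dir, "qpcr_3c.csv")
    utils::write.csv(sim$qpcr$c3, c3Path, row.names = FALSE, quote = FALSE)
    p$qpcr3c <- c3Path
    chipPath <- file.path(dir, "qpcr_chip.csv")
    utils::write.csv(sim$qpcr$chip, chipPath, row.names = FALSE,
                     quote = FALSE)
    p$qpcrChip <- chipPath
    p$manifest <- writeManifest(sim$manifest, file.path(dir, "manifest.json"))
    invisible(p)
}
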