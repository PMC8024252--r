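#' ChIP-qPCR enrichment as percent of input
#'
#' Enrichment relative to the input chromatin:
#' `100 * inputFraction * 2^(ctInput - ctIp)`.  The `inputFraction` is the
#' share of chromatin kept as input (e.g. 0.01 for a 1% input); it adjusts
#' the input Ct by `log2(1/inputFraction)` cycles.  One cycle of IP
#' advantage doubles the percentage.
#'
#' @param ctIp Ct of the immunoprecipitated sample.
#' @param ctInput Ct of the input sample.
#' @param inputFraction fraction of chromatin used as input, in `(0, 1]`.
#'   The dilution used in a given experiment is a required user parameter.
#' @param efficiency per-cycle amplification factor (default 2).
#' @return percent-of-input value(s).
#' @examples
#' chipPercentInput(25, 25, 1)     # 100
#' chipPercentInput(24, 25, 0.01)  # 2
#' @export
chipPercentInput <- function(ctIp, ctInput, inputFraction, efficiency = 2) {
    if (any(inputFraction <= 0) || any(inputFraction > 1))
        stop("'inputFraction' must be in (0, 1]")
    stopifnot(efficiency > 1)
    100 * inputFraction * efficiency^(ctInput - ctIp)
}

#' Relative crosslinking frequency from a 3C assay
#'
#' Crosslinking frequency of a ligation-junction primer pair relative to a
#' reference pair that does not span a restriction (DpnII) cut site:
#' `2^(ctRefPair - ctPair)`.  Values are comparable across primer pairs
#' within one sample; a plate-wide Ct offset cancels.
#'
#' @param ctPair Ct of the junction primer pair.
#' @param ctRefPair Ct of the non-cut-site reference pair in the same
#'   sample.
#' @param efficiency per-cycle amplification factor (default 2).
#' @return relative crosslinking frequency value(s).
#' @examples
#' c3RelativeFrequency(28, 28)  # 1
#' c3RelativeFrequency(30, 28)  # 0.25
#' @export
c3RelativeFrequency <- function(ctPair, ctRefPair, efficiency = 2) {
    stopifnot(efficiency > 1)
    efficiency^(ctRefPair - ctPair)
}

#' Summarise replicated Ct measurements into relative values
#'
#' Groups a long Ct table by `(sample, primer_pair)`, transforms to
#' relative crosslinking frequency against the sample's reference pair,
#' and reports one row per group.  The point estimate is the transform of
#' the mean Ct difference (replicates are averaged on the Ct scale before
#' transformation); the dispersion column `sd` is the standard deviation
#' of the per-replicate transformed values, matching the mean +/- SD
#' presentation conventional for these assays.
#'
#' @param ct `data.frame` with columns `sample`, `primer_pair`, `ct`,
#'   `replicate` (the CSV layout read by [utils::read.csv()]).
#' @param refPair name of the reference primer pair present in every
#'   sample.
#' @param efficiency per-cycle amplification factor (default 2).
#' @return `data.frame` with `sample`, `primer_pair`, `relative`, `sd`.
#' @export
summarize3C <- function(ct, refPair = "N", efficiency = 2) {
    stopifnot(all(c("sample", "primer_pair", "ct", "replicate") %in%
                  names(ct)))
    out <- do.call(rbind, lapply(split(ct, ct$sample), function(d) {
        ref <- d[d$primer_pair == refPair, ]
        if (nrow(ref) == 0L)
            stop("sample '", d$sample[1L], "' has no reference pair '",
                 refPair, "'")
        do.call(rbind, lapply(split(d, d$primer_pair), function(g) {
            point <- c3RelativeFrequency(mean(g$ct), mean(ref$ct), efficiency)
            # per-replicate values (matched by replicate id when possible)
            refCt <- ref$ct[match(g$replicate, ref$replicate)]
            refCt[is.na(refCt)] <- mean(ref$ct)
            per <- c3RelativeFrequency(g$ct, refCt, efficiency)
            data.frame(sample = g$sample[1L], primer_pair = g$primer_pair[1L],
                       relative = point,
                       sd = if (length(per) > 1L) stats::sd(per) else NA_real_)
        }))
    }))
    rownames(out) <- NULL
    out
}
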