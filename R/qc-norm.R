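#' Quality-control and normalization configuration
#'
#' Thresholds for the detection-p / bead-count filters, the stratified
#' background adjustment, and the beta computation.
#'
#' @param sampleFailFrac a sample is retained iff its fraction of failed
#'   probe calls is *below* this (default 0.05: "fewer than 5% of sites").
#' @param probeFailFrac a probe is removed iff its fraction of samples with
#'   failed calls *exceeds* this (default 0.05: "more than 5% of samples").
#' @param detectionAlpha detection p-value cut separating good from failed
#'   calls (default 0.05).
#' @param failDirection `"above"` (conventional: a call fails when
#'   detection p >= `detectionAlpha`) or `"below"` (the literal
#'   opposite reading; exposed because published filter wordings differ).
#' @param minBeads minimum acceptable bead count (default 3; a count of
#'   exactly 3 is acceptable).
#' @param beadcountFailFrac a probe is removed when the fraction of samples
#'   with bead count < `minBeads` reaches this (inclusive; default 0.05).
#' @param betaOffsetAlpha intensity offset in the beta denominator
#'   (default 100, the de facto Illumina constant).
#' @param backgroundPercentile percentile (0-100) used to equalize type I
#'   and type II channel backgrounds (default 5).
#' @return a validated named list of class `NormConfig`.
#' @export
normConfig <- function(sampleFailFrac = 0.05, probeFailFrac = 0.05,
                       detectionAlpha = 0.05, failDirection = c("above", "below"),
                       minBeads = 3L, beadcountFailFrac = 0.05,
                       betaOffsetAlpha = 100, backgroundPercentile = 5) {
  failDirection <- match.arg(failDirection)
  for (p in c(sampleFailFrac, probeFailFrac, detectionAlpha,
              beadcountFailFrac))
    stopIfNot(p > 0 && p < 1, "QC fractions/thresholds must lie in (0, 1)")
  stopIfNot(betaOffsetAlpha >= 0, "betaOffsetAlpha must be >= 0")
  stopIfNot(backgroundPercentile > 0 && backgroundPercentile < 100,
            "backgroundPercentile must lie in (0, 100)")
  structure(list(sampleFailFrac = sampleFailFrac,
                 probeFailFrac = probeFailFrac,
                 detectionAlpha = detectionAlpha,
                 failDirection = failDirection,
                 minBeads = as.integer(minBeads),
                 beadcountFailFrac = beadcountFailFrac,
                 betaOffsetAlpha = betaOffsetAlpha,
                 backgroundPercentile = backgroundPercentile),
            class = "NormConfig")
}

asNormConfig <- function(cfg) {
  if (is.null(cfg)) return(normConfig())
  if (inherits(cfg, "NormConfig")) return(cfg)
  do.call(normConfig, cfg)
}

failedCalls <- function(dp, cfg) {
  if (cfg$failDirection == "above") dp >= cfg$detectionAlpha
  else dp < cfg$detectionAlpha
}

#' Detection-p-value sample filter
#'
#' A sample is retained iff the fraction of its probes with a failed
#' detection call is strictly below `sampleFailFrac`. Run this before
#' [filterProbes()].
#'
#' @param data a [MethylIntensitySet-class].
#' @param cfg a [normConfig()] list (or NULL for defaults).
#' @return `list(data = filtered set, report = `[QCReport-class]`)`.
#' @export
filterSamples <- function(data, cfg = normConfig()) {
  cfg <- asNormConfig(cfg)
  fracFailed <- colMeans(failedCalls(detectionP(data), cfg))
  keep <- fracFailed < cfg$sampleFailFrac
  if (!any(keep))
    stop("all samples failed the detection-p filter; review detectionAlpha/",
         "sampleFailFrac", call. = FALSE)
  removed <- if (all(keep)) emptyRemoval() else data.frame(
    id = colnames(data)[!keep],
    reason = sprintf("detection failure fraction %.4f >= %.3f",
                     fracFailed[!keep], cfg$sampleFailFrac))
  list(data = data[, keep],
       report = QCReport(samplesRemoved = removed,
                         nSamplesRetained = sum(keep),
                         nProbesRetained = nrow(data)))
}

#' Detection-p-value and bead-count probe filter
#'
#' A probe is removed when the fraction of samples with failed detection
#' calls strictly exceeds `probeFailFrac`, or when the fraction of samples
#' with bead count below `minBeads` reaches `beadcountFailFrac`
#' (inclusive). Run after [filterSamples()]; both filters are idempotent.
#'
#' @inheritParams filterSamples
#' @return `list(data = filtered set, report = `[QCReport-class]`)`.
#' @export
filterProbes <- function(data, cfg = normConfig()) {
  cfg <- asNormConfig(cfg)
  fracFailed <- rowMeans(failedCalls(detectionP(data), cfg))
  fracLowBead <- rowMeans(beadCount(data) < cfg$minBeads)
  badDet <- fracFailed > cfg$probeFailFrac
  badBead <- fracLowBead >= cfg$beadcountFailFrac
  keep <- !(badDet | badBead)
  if (!any(keep))
    stop("all probes removed by QC; review thresholds", call. = FALSE)
  reason <- ifelse(badDet & badBead, "detection+beadcount",
                   ifelse(badDet, "detection", "beadcount"))
  removed <- if (all(keep)) emptyRemoval() else
    data.frame(id = rownames(data)[!keep], reason = reason[!keep])
  list(data = data[keep, ],
       report = QCReport(probesRemoved = removed,
                         nSamplesRetained = ncol(data),
                         nProbesRetained = sum(keep)))
}

#' Confirm monozygosity from SNP-control probes
#'
#' Each SNP-control probe yields a tri-modal beta; genotypes are called
#' 0/1/2 by thresholding (`< low`, between, `> high`) and each pair's
#' concordance is the fraction of SNP probes on which the twins' calls
#' agree. MZ pairs should be near 1; unrelated individuals with uniform
#' genotypes agree about 1/3 of the time.
#'
#' @param betas beta matrix (probes x samples).
#' @param man a probe manifest flagging SNP-control probes.
#' @param design a [PairedDesign-class].
#' @param low,high genotype call thresholds on the beta scale.
#' @param minConcordance pass threshold (default 0.9).
#' @return a `data.frame` with columns `pair_id`, `concordance`, `pass`.
#' @export
checkMonozygosity <- function(betas, man, design, low = 0.2, high = 0.8,
                              minConcordance = 0.9) {
  snp <- intersect(man$probe_id[man$is_snp_control], rownames(betas))
  if (length(snp) == 0)
    stop("no SNP-control probes present in the beta matrix", call. = FALSE)
  calls <- matrix(1L, length(snp), ncol(betas),
                  dimnames = list(snp, colnames(betas)))
  b <- betas[snp, , drop = FALSE]
  calls[b < low] <- 0L
  calls[b > high] <- 2L
  conc <- colMeans(calls[, affectedSamples(design), drop = FALSE] ==
                     calls[, unaffectedSamples(design), drop = FALSE])
  data.frame(pair_id = pairIds(design), concordance = unname(conc),
             pass = unname(conc) >= minConcordance)
}

#' Stratified background adjustment and quantile normalization
#'
#' Two stages, applied separately to the methylated and unmethylated
#' channels. Stage 1 equalizes type I and type II backgrounds: per sample
#' and channel, type I intensities are shifted by the difference between
#' the type II and type I `backgroundPercentile` quantiles (floored at 0).
#' Stage 2 quantile-normalizes each (channel x design type) stratum across
#' samples, replacing each sample's values by rank-matched means of the
#' sorted values (average ranks for ties; delegated to
#' [limma::normalizeQuantiles]). Detection p-values and bead counts pass
#' through unchanged. This follows the spirit of the dasen method: between-
#' sample quantile normalization within chemistry strata after background
#' equalization, without dasen's normal-exponential background model.
#'
#' @param data a [MethylIntensitySet-class]; every probe needs a design type.
#' @param cfg a [normConfig()] list.
#' @return a [MethylIntensitySet-class] with adjusted `M` and `U`.
#' @export
normalizeDasen <- function(data, cfg = normConfig()) {
  cfg <- asNormConfig(cfg)
  if (ncol(data) < 2)
    stop("normalization needs at least 2 samples per stratum", call. = FALSE)
  man <- manifest(data)
  type <- man$design_type[match(rownames(data), man$probe_id)]
  stopIfNot(all(type %in% c("I", "II")),
            "every probe needs design_type I or II for normalization")
  pb <- cfg$backgroundPercentile / 100
  adjust <- function(x) {
    iI <- type == "I"; iII <- type == "II"
    if (any(iI) && any(iII)) {
      shift <- apply(x[iII, , drop = FALSE], 2, stats::quantile, probs = pb) -
        apply(x[iI, , drop = FALSE], 2, stats::quantile, probs = pb)
      x[iI, ] <- pmax(sweep(x[iI, , drop = FALSE], 2, shift, "+"), 0)
    }
    for (tt in c("I", "II")) {
      rows <- type == tt
      if (sum(rows) >= 1)
        x[rows, ] <- limma::normalizeQuantiles(x[rows, , drop = FALSE],
                                               ties = TRUE)
    }
    x
  }
  out <- data
  SummarizedExperiment::assay(out, "M") <- adjust(methylated(data))
  SummarizedExperiment::assay(out, "U") <- adjust(unmethylated(data))
  out
}

#' Compute beta values
#'
#' The standard Illumina estimate \eqn{\beta = M / (M + U + \alpha)} with
#' offset \eqn{\alpha} (default 100) guarding against division by zero and
#' stabilizing low-intensity probes.
#'
#' @param data a [MethylIntensitySet-class] (raw or normalized).
#' @param cfg a [normConfig()] list; only `betaOffsetAlpha` is used.
#' @return a numeric matrix of betas in \[0, 1\] (probes x samples).
#' @export
computeBetas <- function(data, cfg = normConfig()) {
  cfg <- asNormConfig(cfg)
  M <- methylated(data); U <- unmethylated(data)
  M / (M + U + cfg$betaOffsetAlpha)
}
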