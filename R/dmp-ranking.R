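#' Per-probe paired t-test of affected vs cotwin betas
#'
#' For probe-wise within-pair differences \eqn{d_j = \beta_{aff,j} -
#' \beta_{unaff,j}}, reports the mean difference (delta beta), the paired t
#' statistic \eqn{t = \bar d / (s_d / \sqrt n)} with the (n-1)-denominator
#' SD, and the two-sided Student-t p-value on n-1 degrees of freedom.
#' Degenerate probes with \eqn{s_d = 0} get p = 1 (and t = 0) when
#' \eqn{\bar d = 0}, or the smallest representable p (flagged) otherwise.
#'
#' @param betas beta matrix (probes x samples).
#' @param design a [PairedDesign-class] with at least 2 pairs.
#' @param probes optional subset of probe ids.
#' @return a `data.frame` with columns `probe_id`, `delta_beta`, `t_stat`,
#'   `p_value`, `degenerate`.
#' @export
pairedTTest <- function(betas, design, probes = NULL) {
  stopIfNot(nPairs(design) >= 2, "paired t-test needs >= 2 pairs")
  missing <- setdiff(c(affectedSamples(design), unaffectedSamples(design)),
                     colnames(betas))
  stopIfNot(length(missing) == 0, "sample columns missing from betas: ",
            paste(utils::head(missing, 3), collapse = ", "))
  if (!is.null(probes)) {
    absent <- setdiff(probes, rownames(betas))
    stopIfNot(length(absent) == 0, "probes missing from betas: ",
              paste(utils::head(absent, 3), collapse = ", "))
    betas <- betas[probes, , drop = FALSE]
  }
  d <- betas[, affectedSamples(design), drop = FALSE] -
    betas[, unaffectedSamples(design), drop = FALSE]
  n <- ncol(d)
  m <- rowMeans(d)
  s <- sqrt(rowVariances(d))
  t <- m / (s / sqrt(n))
  p <- 2 * stats::pt(-abs(t), df = n - 1)
  degenerate <- s == 0
  zeroNull <- degenerate & m == 0
  t[zeroNull] <- 0; p[zeroNull] <- 1
  sat <- degenerate & m != 0
  t[sat] <- sign(m[sat]) * Inf
  p[sat] <- .Machine$double.xmin
  data.frame(probe_id = rownames(betas), delta_beta = unname(m),
             t_stat = unname(t), p_value = unname(p),
             degenerate = unname(degenerate))
}

#' Summed-rank DMP prioritization from precomputed statistics
#'
#' Probes are ranked separately by paired-test p-value (ascending,
#' average-tie ranks) and by effect magnitude |delta beta| (largest first),
#' and the two ranks are summed. The final ordering is by ascending rank
#' sum, ties broken by ascending p-value and then probe id. Bonferroni and
#' Benjamini-Hochberg adjusted p-values are appended for reference; the
#' headline ordering itself carries no multiplicity correction.
#'
#' @param probeIds character vector of probe ids.
#' @param deltaBeta mean affected-minus-cotwin beta differences.
#' @param pValue two-sided paired-test p-values.
#' @return a `data.frame` of DMP records ordered by `final_rank`, with
#'   columns `probe_id`, `delta_beta`, `p_value`, `p_rank`, `effect_rank`,
#'   `rank_sum`, `final_rank`, `p_bonferroni`, `p_bh`.
#' @export
rankFromStats <- function(probeIds, deltaBeta, pValue) {
  stopIfNot(length(probeIds) >= 2, "ranking needs >= 2 probes")
  pRank <- avgRank(pValue)
  effectRank <- avgRank(-abs(deltaBeta))
  rankSum <- pRank + effectRank
  out <- data.frame(probe_id = probeIds, delta_beta = deltaBeta,
                    p_value = pValue, p_rank = pRank,
                    effect_rank = effectRank, rank_sum = rankSum,
                    p_bonferroni = pmin(pValue * length(pValue), 1),
                    p_bh = stats::p.adjust(pValue, "BH"))
  out <- out[order(out$rank_sum, out$p_value, out$probe_id), ]
  out$final_rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("probe_id", "delta_beta", "p_value", "p_rank", "effect_rank",
          "rank_sum", "final_rank", "p_bonferroni", "p_bh")]
}

#' Summed-rank DMP prioritization
#'
#' Runs [pairedTTest()] across all probes and feeds the results to
#' [rankFromStats()]. SNP-control probes should be excluded from `betas`
#' before calling (the pipeline does this from the manifest).
#'
#' @inheritParams pairedTTest
#' @return a DMP record `data.frame` (see [rankFromStats()]) with a
#'   `t_stat` column added.
#' @export
rankDmps <- function(betas, design) {
  stats <- pairedTTest(betas, design)
  out <- rankFromStats(stats$probe_id, stats$delta_beta, stats$p_value)
  out$t_stat <- stats$t_stat[match(out$probe_id, stats$probe_id)]
  out
}

welchRows <- function(x, y) {
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- rowVariances(x); v2 <- rowVariances(y)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  degenerate <- se2 == 0
  t[degenerate & (m1 == m2)] <- 0
  p[degenerate & (m1 == m2)] <- 1
  p[degenerate & (m1 != m2)] <- .Machine$double.xmin
  list(meanDiff = m1 - m2, t = t, df = df, p = p)
}

#' Targeted case-control replication test
#'
#' Welch two-sample t-test of case vs control betas at nominated probes
#' (e.g. testing twin-nominated DMPs in an independent case-control
#' tissue collection). No multiple-testing correction is applied: this is
#' a targeted replication of a short, pre-specified probe list.
#'
#' @param betas beta matrix (probes x samples) for the replication cohort.
#' @param caseIds,controlIds sample columns per group (>= 2 each).
#' @param probes probe ids to test.
#' @return a `data.frame` with columns `probe_id`, `mean_diff`
#'   (case minus control), `t_stat`, `p_value`, `n_case`, `n_control`.
#' @export
caseControlTest <- function(betas, caseIds, controlIds, probes) {
  stopIfNot(length(caseIds) >= 2 && length(controlIds) >= 2,
            "each group needs >= 2 samples")
  stopIfNot(all(probes %in% rownames(betas)), "probes missing from betas")
  w <- welchRows(betas[probes, caseIds, drop = FALSE],
                 betas[probes, controlIds, drop = FALSE])
  data.frame(probe_id = probes, mean_diff = unname(w$meanDiff),
             t_stat = unname(w$t), p_value = unname(w$p),
             n_case = length(caseIds), n_control = length(controlIds))
}

#' Sex-difference check on within-pair effects
#'
#' Welch t-test comparing within-pair beta differences between male and
#' female twin pairs, per nominated probe. Used to verify that top-ranked
#' DMPs are not driven by one sex.
#'
#' @param betas beta matrix.
#' @param design a [PairedDesign-class].
#' @param sheet the sample sheet giving each sample's sex.
#' @param probes probe ids to test.
#' @return a `data.frame` with columns `probe_id`, `mean_diff_m_f`,
#'   `p_value`, `n_male_pairs`, `n_female_pairs`.
#' @export
sexDifferenceCheck <- function(betas, design, sheet, probes) {
  sex <- sheet$sex[match(affectedSamples(design), sheet$sample_id)]
  stopIfNot(sum(sex == "M") >= 2 && sum(sex == "F") >= 2,
            "need >= 2 male and >= 2 female pairs")
  stopIfNot(all(probes %in% rownames(betas)), "probes missing from betas")
  d <- betas[probes, affectedSamples(design), drop = FALSE] -
    betas[probes, unaffectedSamples(design), drop = FALSE]
  w <- welchRows(d[, sex == "M", drop = FALSE],
                 d[, sex == "F", drop = FALSE])
  data.frame(probe_id = probes, mean_diff_m_f = unname(w$meanDiff),
             p_value = unname(w$p),
             n_male_pairs = sum(sex == "M"),
             n_female_pairs = sum(sex == "F"))
}
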