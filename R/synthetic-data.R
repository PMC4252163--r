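#' Configure the synthetic twin-pair generator
#'
#' Defaults emulate the study design the package targets: 18 MZ pairs
#' (13 female, 5 male) profiled on a 450K-style array, with 50 planted
#' differentially methylated positions at `|delta| = 0.07` on the beta
#' scale and twin-with-phenotype noise variance inflated by
#' `varInflationLambda = 2` at 10% of probes. Probe-level baselines follow
#' the canonical bimodal 450K beta distribution (mixture of
#' Beta(2,18)/Beta(5,5)/Beta(18,2) with weights 0.4/0.2/0.4). The logit
#' noise scale `sigma = 0.16` and pair-effect scale `tau = 0.10` are calibrated jointly so that realized within-pair
#' difference SDs fall around 0.02-0.07 across the mixture and planted
#' effects of 0.07 on the beta scale remain detectable by a paired t-test
#' at 18 pairs, the least favourable (mid-methylation) probes yielding
#' p-values of order 1e-4 to 1e-3.
#'
#' @param nPairs number of twin pairs.
#' @param nProbes total probes including SNP controls.
#' @param nSnpProbes number of tri-modal SNP-control probes (65 on the 450K).
#' @param fracTypeII fraction of probes on Infinium type II chemistry.
#' @param seed integer seed; identical seeds give bit-identical datasets.
#' @param mixtureWeights,mixtureShape1,mixtureShape2 three-component beta
#'   mixture for probe baselines (low/mid/high methylation).
#' @param tau SD of the pair-shared random effect on the logit-beta scale.
#' @param sigma SD of per-twin noise on the logit-beta scale.
#' @param dmpSetSize number of planted DMPs.
#' @param delta planted affected-minus-cotwin effect on the beta scale;
#'   signs are randomized per probe.
#' @param varInflationLambda variance multiplier (>= 1) applied to the
#'   affected twin's noise at inflated probes.
#' @param fracVarInflated fraction of non-SNP probes with inflated variance.
#' @param totalIntensityLogMean,totalIntensityLogSd log-normal model for
#'   total intensity per (probe, sample).
#' @param typeIOffset additive channel background applied to type I probe
#'   intensities (gives the background-equalization stage work to do).
#' @param detectionFailRate per-(probe, sample) probability of a detection
#'   failure (p-value resampled from Uniform(0,1)).
#' @param beadcountMean mean bead count; counts are 1 + Poisson(mean - 1).
#' @param mzMode if `TRUE`, SNP-control genotypes are shared within a pair
#'   (monozygotic twins); if `FALSE`, drawn independently per twin.
#' @param snpNoiseSd beta-scale noise around SNP-probe genotype centers.
#' @param phenoSd SD of simulated SMFQ scores around their group means.
#' @return a validated [SimConfig-class] object.
#' @export
simConfig <- function(nPairs = 18L, nProbes = 20000L, nSnpProbes = 65L,
                      fracTypeII = 0.72, seed = 1L,
                      mixtureWeights = c(0.4, 0.2, 0.4),
                      mixtureShape1 = c(2, 5, 18),
                      mixtureShape2 = c(18, 5, 2),
                      tau = 0.10, sigma = 0.16,
                      dmpSetSize = 50L, delta = 0.07,
                      varInflationLambda = 2, fracVarInflated = 0.1,
                      totalIntensityLogMean = log(3000),
                      totalIntensityLogSd = 0.3,
                      typeIOffset = 300,
                      detectionFailRate = 0.002, beadcountMean = 14,
                      mzMode = TRUE, snpNoiseSd = 0.02, phenoSd = 2) {
  new("SimConfig",
      nPairs = as.integer(nPairs), nProbes = as.integer(nProbes),
      nSnpProbes = as.integer(nSnpProbes), fracTypeII = fracTypeII,
      seed = as.integer(seed), mixtureWeights = mixtureWeights,
      mixtureShape1 = mixtureShape1, mixtureShape2 = mixtureShape2,
      tau = tau, sigma = sigma, dmpSetSize = as.integer(dmpSetSize),
      delta = delta, varInflationLambda = varInflationLambda,
      fracVarInflated = fracVarInflated,
      totalIntensityLogMean = totalIntensityLogMean,
      totalIntensityLogSd = totalIntensityLogSd, typeIOffset = typeIOffset,
      detectionFailRate = detectionFailRate, beadcountMean = beadcountMean,
      mzMode = mzMode, snpNoiseSd = snpNoiseSd, phenoSd = phenoSd)
}

snpGenotypeCenters <- c(0.05, 0.5, 0.95)

#' Simulate a twin-pair methylation dataset with known ground truth
#'
#' Generative model, per probe \eqn{i} and pair \eqn{j}: a baseline
#' methylation level \eqn{m_i} is drawn from the beta mixture; a
#' pair-shared effect \eqn{a_{ij} \sim N(0, \tau^2)} and per-twin noise
#' \eqn{e \sim N(0, \sigma^2)} act on the logit scale, the affected twin's
#' noise variance being multiplied by \eqn{\lambda} at variance-inflated
#' probes. True betas are the inverse logit of the sum. At planted DMPs the
#' affected twin's beta is additionally shifted by the signed beta-scale
#' effect (clipped to \[0.001, 0.999\]). Intensities: total
#' \eqn{T \sim} log-normal, \eqn{M = \mathrm{round}(\beta T)},
#' \eqn{U = \mathrm{round}((1-\beta) T)}, with an additive channel
#' background added to type I probes. Detection p-values are
#' Uniform(0, 0.001) for good measurements and Uniform(0, 1) for failures;
#' bead counts are \eqn{1 + } Poisson. SNP-control probes get tri-modal
#' betas centered at (0.05, 0.5, 0.95) by genotype, shared within a pair
#' when `mzMode`.
#'
#' Randomness is split into fixed per-stage sub-streams derived from the
#' seed, so e.g. phenotype draws do not shift when `nProbes` changes.
#'
#' @param cfg a [SimConfig-class] from [simConfig()].
#' @return a list with elements `manifest`, `sheet` (sample sheet `data.frame`),
#'   `data` (a [MethylIntensitySet-class]), and `truth` — a list holding
#'   `dmpProbeIds`, `trueDelta` (named, signed), `varInflatedProbeIds`,
#'   `snpGenotypes` (SNP probes x samples matrix of 0/1/2) and `trueBeta`
#'   (the noise-free-chemistry methylation fractions actually used to
#'   synthesize intensities).
#' @export
simulateDataset <- function(cfg) {
  stopIfNot(is(cfg, "SimConfig"), "cfg must be a SimConfig")
  validObject(cfg)
  nP <- cfg@nProbes; nSnp <- cfg@nSnpProbes; nAuto <- nP - nSnp
  nPair <- cfg@nPairs; nSamp <- 2L * nPair

  ## stage 1: manifest + sample sheet -------------------------------------
  set.seed(stageSeed(cfg@seed, 1L))
  probeIds <- c(sprintf("cg%08d", seq_len(nAuto)),
                sprintf("rs%08d", seq_len(nSnp)))
  chrom <- sample(paste0("chr", 1:22), nP, replace = TRUE)
  # positions: mixture of short (CpG-island-like) and long gaps, cumulated
  # per chromosome so nearby probes exist for region calling
  pos <- integer(nP)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    gaps <- ifelse(stats::runif(length(idx)) < 0.3,
                   sample(20:400, length(idx), replace = TRUE),
                   sample(1000:100000, length(idx), replace = TRUE))
    pos[idx] <- 1000L + cumsum(gaps)
  }
  man <- data.frame(
    probe_id = probeIds, chrom = chrom, pos = pos,
    design_type = ifelse(stats::runif(nP) < cfg@fracTypeII, "II", "I"),
    is_snp_control = c(rep(FALSE, nAuto), rep(TRUE, nSnp)),
    strand = sample(c("+", "-"), nP, replace = TRUE))
  man <- validateManifest(man)

  pairIdsV <- sprintf("pair%03d", seq_len(nPair))
  nFemale <- round(13 / 18 * nPair)
  sexes <- rep(c("F", "M"), c(nFemale, nPair - nFemale))
  affectedIsA <- sample(c(TRUE, FALSE), nPair, replace = TRUE)
  sheet <- data.frame(
    sample_id = as.vector(rbind(paste0(pairIdsV, "_A"),
                                paste0(pairIdsV, "_B"))),
    pair_id = rep(pairIdsV, each = 2),
    status = as.vector(rbind(ifelse(affectedIsA, "affected", "unaffected"),
                             ifelse(affectedIsA, "unaffected", "affected"))),
    sex = rep(sexes, each = 2),
    batch = rep(sprintf("array%03d", seq_len(nPair)), each = 2))
  sheet <- validateSampleSheet(sheet)
  design <- buildDesign(sheet)
  affCols <- match(affectedSamples(design), sheet$sample_id)
  unaffCols <- match(unaffectedSamples(design), sheet$sample_id)

  ## stage 2: true betas, autosomal probes --------------------------------
  set.seed(stageSeed(cfg@seed, 2L))
  comp <- sample.int(3L, nAuto, replace = TRUE, prob = cfg@mixtureWeights)
  baseline <- clipRange(
    stats::rbeta(nAuto, cfg@mixtureShape1[comp], cfg@mixtureShape2[comp]),
    0.01, 0.99)
  autoIds <- probeIds[seq_len(nAuto)]
  inflIds <- sample(autoIds, round(cfg@fracVarInflated * nAuto))
  dmpIds <- sample(autoIds, cfg@dmpSetSize)
  dmpSign <- sample(c(-1, 1), cfg@dmpSetSize, replace = TRUE)
  trueDelta <- stats::setNames(dmpSign * cfg@delta, dmpIds)

  sdAff <- rep(cfg@sigma, nAuto)
  sdAff[autoIds %in% inflIds] <- cfg@sigma * sqrt(cfg@varInflationLambda)
  lg <- logit(baseline)
  pairEff <- matrix(stats::rnorm(nAuto * nPair, sd = cfg@tau), nAuto, nPair)
  eUn <- matrix(stats::rnorm(nAuto * nPair, sd = cfg@sigma), nAuto, nPair)
  eAf <- matrix(stats::rnorm(nAuto * nPair), nAuto, nPair) * sdAff
  betaUn <- invLogit(lg + pairEff + eUn)
  betaAf <- invLogit(lg + pairEff + eAf)
  shift <- match(dmpIds, autoIds)
  betaAf[shift, ] <- clipRange(betaAf[shift, ] + trueDelta, 0.001, 0.999)

  trueBeta <- matrix(0, nP, nSamp, dimnames = list(probeIds, sheet$sample_id))
  trueBeta[seq_len(nAuto), affCols] <- betaAf
  trueBeta[seq_len(nAuto), unaffCols] <- betaUn

  ## stage 3: SNP-control probes ------------------------------------------
  set.seed(stageSeed(cfg@seed, 3L))
  snpGeno <- matrix(0L, nSnp, nSamp,
                    dimnames = list(probeIds[nAuto + seq_len(nSnp)],
                                    sheet$sample_id))
  if (nSnp > 0) {
    if (cfg@mzMode) {
      g <- matrix(sample(0:2, nSnp * nPair, replace = TRUE), nSnp, nPair)
      snpGeno[, affCols] <- g
      snpGeno[, unaffCols] <- g
    } else {
      snpGeno[] <- sample(0:2, nSnp * nSamp, replace = TRUE)
    }
    snpBeta <- clipRange(
      snpGenotypeCenters[snpGeno + 1L] +
        stats::rnorm(nSnp * nSamp, sd = cfg@snpNoiseSd), 0.001, 0.999)
    trueBeta[nAuto + seq_len(nSnp), ] <- snpBeta
  }

  ## stage 4: intensities --------------------------------------------------
  set.seed(stageSeed(cfg@seed, 4L))
  total <- matrix(stats::rlnorm(nP * nSamp, cfg@totalIntensityLogMean,
                                cfg@totalIntensityLogSd), nP, nSamp)
  M <- round(trueBeta * total)
  U <- round((1 - trueBeta) * total)
  typeI <- man$design_type[match(probeIds, man$probe_id)] == "I"
  M[typeI, ] <- M[typeI, ] + cfg@typeIOffset
  U[typeI, ] <- U[typeI, ] + cfg@typeIOffset
  dimnames(M) <- dimnames(U) <- dimnames(trueBeta)

  ## stage 5: detection p-values -------------------------------------------
  set.seed(stageSeed(cfg@seed, 5L))
  detP <- matrix(stats::runif(nP * nSamp, 0, 0.001), nP, nSamp,
                 dimnames = dimnames(trueBeta))
  fail <- matrix(stats::runif(nP * nSamp) < cfg@detectionFailRate, nP, nSamp)
  detP[fail] <- stats::runif(sum(fail))

  ## stage 6: bead counts ---------------------------------------------------
  set.seed(stageSeed(cfg@seed, 6L))
  beads <- matrix(1L + stats::rpois(nP * nSamp, cfg@beadcountMean - 1),
                  nP, nSamp, dimnames = dimnames(trueBeta))

  mset <- MethylIntensitySet(M = M, U = U, detectionP = detP,
                             beadCount = beads, manifest = man,
                             sampleSheet = sheet)
  list(manifest = man, sheet = sheet, data = mset,
       truth = list(dmpProbeIds = dmpIds, trueDelta = trueDelta,
                    varInflatedProbeIds = inflIds, snpGenotypes = snpGeno,
                    trueBeta = trueBeta))
}

#' Simulate longitudinal SMFQ phenotype scores
#'
#' Discordant pairs draw the higher-scoring twin's per-wave scores from a
#' normal centered at 12.38 (above the clinical threshold of 8) and the
#' cotwin's from one centered at 6.42; non-discordant pairs draw both twins
#' from the cotwin distribution. Scores are rounded and clipped to the
#' 0-26 SMFQ range.
#'
#' @param cfg a [SimConfig-class]; `phenoSd` sets the score noise and the
#'   phenotype sub-stream is derived from `cfg@seed` independently of the
#'   methylation stages.
#' @param nWaves number of measurement waves (>= 2).
#' @param discordantPairIds pair ids to make discordant.
#' @param affectedTwin optional named character ("a"/"b") saying which twin
#'   scores higher in each discordant pair; default all "a".
#' @return a phenotype `data.frame` (see [readPhenotypeTable()]).
#' @export
simulatePhenotypes <- function(cfg, nWaves = 2L, discordantPairIds = character(),
                               affectedTwin = NULL) {
  stopIfNot(nWaves >= 2, "nWaves must be >= 2")
  set.seed(stageSeed(cfg@seed, 7L))
  pids <- sprintf("pair%03d", seq_len(cfg@nPairs))
  stopIfNot(all(discordantPairIds %in% pids),
            "unknown pair id among discordantPairIds")
  if (is.null(affectedTwin))
    affectedTwin <- stats::setNames(rep("a", length(discordantPairIds)),
                                    discordantPairIds)
  draw <- function(n, mu) clipRange(round(stats::rnorm(n, mu, cfg@phenoSd)),
                                    0, 26)
  out <- do.call(rbind, lapply(pids, function(pid) {
    disc <- pid %in% discordantPairIds
    hi <- draw(nWaves, 12.38); lo <- draw(nWaves, 6.42)
    lo2 <- draw(nWaves, 6.42)
    if (!disc) { a <- lo; b <- lo2 }
    else if (affectedTwin[[pid]] == "a") { a <- hi; b <- lo }
    else { a <- lo; b <- hi }
    data.frame(pair_id = pid, wave = seq_len(nWaves),
               score_twin_a = a, score_twin_b = b)
  }))
  rownames(out) <- NULL
  out
}
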