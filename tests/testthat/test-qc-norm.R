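makeToySet <- function(nProbes, nPairs, detP = NULL, beads = NULL,
                       seed = 1) {
  set.seed(seed)
  sheet <- toySheet(nPairs)
  man <- toyManifest(nProbes)
  dims <- list(man$probe_id, sheet$sample_id)
  M <- matrix(rpois(nProbes * 2 * nPairs, 2000), nProbes, 2 * nPairs,
              dimnames = dims)
  U <- matrix(rpois(nProbes * 2 * nPairs, 2000), nProbes, 2 * nPairs,
              dimnames = dims)
  if (is.null(detP)) detP <- matrix(0.0001, nProbes, 2 * nPairs)
  if (is.null(beads)) beads <- matrix(10, nProbes, 2 * nPairs)
  dimnames(detP) <- dimnames(beads) <- dims
  MethylIntensitySet(M, U, detP, beads, man, sheet)
}

test_that("sample filter removes samples at or above the failure fraction", {
  # 100 probes x 4 samples; sample 2 has 6 probes at detection p = 0.5 (6%)
  detP <- matrix(0.0001, 100, 4)
  detP[1:6, 2] <- 0.5
  mset <- makeToySet(100, 2, detP = detP)
  res <- filterSamples(mset)
  expect_equal(res$report@samplesRemoved$id, colnames(mset)[2])
  expect_equal(ncol(res$data), 3)
  # 4 failed probes (4% < 5%) is retained
  detP2 <- matrix(0.0001, 100, 4); detP2[1:4, 2] <- 0.5
  res2 <- filterSamples(makeToySet(100, 2, detP = detP2))
  expect_equal(nrow(res2$report@samplesRemoved), 0)
  expect_error(filterSamples(makeToySet(3, 2,
                                        detP = matrix(0.9, 3, 4))),
               "all samples")
})

test_that("zero failure rate passes every sample through QC untouched", {
  sim <- simulateDataset(simConfig(seed = 2, nProbes = 500L,
                                   nSnpProbes = 10L, dmpSetSize = 5L,
                                   detectionFailRate = 0))
  res <- filterSamples(sim$data)
  expect_equal(nrow(res$report@samplesRemoved), 0)
  expect_equal(ncol(res$data), ncol(sim$data))
})

test_that("probe filter matches hand enumeration on a planted fixture", {
  # 5 probes x 4 samples:
  #  probe 1: clean                                -> kept
  #  probe 2: detection failed in 1/4 (25% > 5%)   -> removed (detection)
  #  probe 3: bead count 2 in 1/4 (25% >= 5%)      -> removed (beadcount)
  #  probe 4: bead count exactly 3 everywhere      -> kept (3 is not < 3)
  #  probe 5: both failure modes                   -> removed
  detP <- matrix(0.0001, 5, 4); detP[2, 1] <- 0.6; detP[5, 4] <- 0.9
  beads <- matrix(10, 5, 4); beads[3, 2] <- 2; beads[4, ] <- 3; beads[5, 1] <- 1
  mset <- makeToySet(5, 2, detP = detP, beads = beads)
  res <- filterProbes(mset)
  rem <- res$report@probesRemoved
  expect_equal(rem$id, rownames(mset)[c(2, 3, 5)])
  expect_equal(rem$reason, c("detection", "beadcount", "detection+beadcount"))
  expect_equal(rownames(res$data), rownames(mset)[c(1, 4)])
})

test_that("probe filter boundaries: 2/36 samples fails, exactly 5% does not", {
  detP <- matrix(0.0001, 3, 36)
  detP[1, 1:2] <- 0.5          # 2/36 = 5.6% > 5% -> removed
  mset <- makeToySet(3, 18, detP = detP)
  res <- filterProbes(mset)
  expect_equal(res$report@probesRemoved$id, rownames(mset)[1])
  detP2 <- matrix(0.0001, 3, 40)
  detP2[1, 1:2] <- 0.5         # 2/40 = 5% exactly, not > 5% -> kept
  res2 <- filterProbes(makeToySet(3, 20, detP = detP2))
  expect_equal(nrow(res2$report@probesRemoved), 0)
})

test_that("QC filters are idempotent", {
  set.seed(11)
  detP <- matrix(sample(c(0.0001, 0.5), 200 * 8, TRUE, prob = c(.93, .07)),
                 200, 8)
  beads <- matrix(sample(c(2, 10), 200 * 8, TRUE, prob = c(.04, .96)), 200, 8)
  mset <- makeToySet(200, 4, detP = detP, beads = beads, seed = 11)
  s1 <- filterSamples(mset)
  s2 <- filterSamples(s1$data)
  expect_equal(nrow(s2$report@samplesRemoved), 0)
  p1 <- filterProbes(s1$data)
  p2 <- filterProbes(p1$data)
  expect_equal(nrow(p2$report@probesRemoved), 0)
})

test_that("literal failure-direction reading is selectable", {
  cfg <- normConfig(failDirection = "below")
  detP <- matrix(0.5, 10, 4)     # all calls 'good' under the literal reading
  detP[1:6, 2] <- 0.0001         # 6/10 small p = 'failed' under it
  mset <- makeToySet(10, 2, detP = detP)
  res <- filterSamples(mset, cfg)
  expect_equal(res$report@samplesRemoved$id, colnames(mset)[2])
})

test_that("quantile normalization has its fixed point and sorted-profile property", {
  mset <- makeToySet(40, 3, seed = 3)
  # make every sample identical within each stratum: fixed point up to the
  # stage-1 type I shift, which is 0 when backgrounds already agree
  M <- methylated(mset)
  M[] <- rep(seq_len(nrow(M)) * 100, ncol(M))
  U <- M + 5
  mset2 <- MethylIntensitySet(M, U, detectionP(mset), beadCount(mset),
                              manifest(mset), sampleSheet(mset))
  # backgrounds: type I and II quantiles differ, so allow the shift; the
  # within-stratum sorted profiles must still be identical across samples
  nrm <- normalizeDasen(mset2)
  man <- manifest(mset2)
  for (chan in list(methylated, unmethylated)) {
    x <- chan(nrm)
    for (tt in c("I", "II")) {
      sub <- x[man$design_type[match(rownames(x), man$probe_id)] == tt, ]
      sorted <- apply(sub, 2, sort)
      expect_equal(sorted, sorted[, c(2:ncol(sorted), 1)],
                   ignore_attr = TRUE)
    }
  }
})

test_that("within-stratum quantile normalization matches a brute-force oracle", {
  for (seed in 1:20) {
    set.seed(seed)
    x <- matrix(rlnorm(20 * 4, 7, 0.5), 20, 4)
    # force some ties
    x[sample(80, 6)] <- x[1, 1]
    expect_equal(limma::normalizeQuantiles(x, ties = TRUE),
                 bruteQuantileNormalize(x), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  # and through the exported surface: single-type manifest, one channel
  mset <- makeToySet(30, 2, seed = 5)
  man <- manifest(mset); man$design_type <- "II"
  mset2 <- MethylIntensitySet(methylated(mset), unmethylated(mset),
                              detectionP(mset), beadCount(mset), man,
                              sampleSheet(mset))
  nrm <- normalizeDasen(mset2)
  expect_equal(methylated(nrm),
               bruteQuantileNormalize(methylated(mset2)),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("normalization equalizes type I / II backgrounds and keeps ranks", {
  sim <- simulateDataset(simConfig(seed = 6, nProbes = 3000L,
                                   nSnpProbes = 0L, dmpSetSize = 0L))
  nrm <- normalizeDasen(sim$data)
  man <- manifest(sim$data)
  tI <- man$design_type == "I"
  rawGap <- quantile(methylated(sim$data)[tI, 1], .05) -
    quantile(methylated(sim$data)[!tI, 1], .05)
  nrmGap <- quantile(methylated(nrm)[tI, 1], .05) -
    quantile(methylated(nrm)[!tI, 1], .05)
  expect_lt(abs(nrmGap), abs(rawGap))   # background offset mostly removed
  # rank order within a (sample, stratum) is preserved
  o1 <- order(methylated(sim$data)[tI, 3])
  expect_equal(order(methylated(nrm)[tI, 3]), o1)
  expect_error(normalizeDasen(sim$data[, 1]), "2 samples")
})

test_that("beta computation follows M / (M + U + alpha)", {
  d <- toyDesign(2)
  dims <- list(c("cg1", "cg2", "cg3"),
               c(affectedSamples(d), unaffectedSamples(d)))
  M <- matrix(c(0, 600, 250), 3, 4, dimnames = dims)
  U <- matrix(c(900, 300, 250), 3, 4, dimnames = dims)
  man <- toyManifest(3); man$probe_id <- dims[[1]]
  mset <- MethylIntensitySet(M, U, matrix(0.001, 3, 4, dimnames = dims),
                             matrix(5, 3, 4, dimnames = dims), man,
                             toySheet(2))
  b <- computeBetas(mset, normConfig(betaOffsetAlpha = 100))
  expect_equal(unname(b[1, 1]), 0)
  expect_equal(unname(b[2, 1]), 0.6)
  b0 <- M / (M + U)        # alpha = 0 symmetry at M = U
  expect_equal(unname(b0[3, ]), rep(0.5, 4))
  # monotone in M for fixed U
  expect_true(all(diff(sapply(c(100, 200, 400), function(m)
    m / (m + 300 + 100))) > 0))
})

test_that("monozygosity concordance separates MZ from unrelated pairs", {
  # identity: affected columns copied to unaffected
  d <- toyDesign(3)
  man <- toyManifest(10, snp = rep(TRUE, 10))
  b <- toyBetas(10, d, seed = 2)
  rownames(b) <- man$probe_id
  b[, unaffectedSamples(d)] <- b[, affectedSamples(d)]
  mz <- checkMonozygosity(b, man, d)
  expect_true(all(mz$concordance == 1) && all(mz$pass))
  expect_error(checkMonozygosity(b, toyManifest(10), d), "SNP-control")

  simMz <- simulateDataset(simConfig(seed = 14, nProbes = 500L,
                                     nSnpProbes = 65L, dmpSetSize = 0L,
                                     mzMode = TRUE))
  dd <- buildDesign(simMz$sheet)
  got <- checkMonozygosity(computeBetas(simMz$data), simMz$manifest, dd)
  expect_true(all(got$pass))

  simUn <- simulateDataset(simConfig(seed = 14, nProbes = 500L,
                                     nSnpProbes = 65L, dmpSetSize = 0L,
                                     mzMode = FALSE))
  gotUn <- checkMonozygosity(computeBetas(simUn$data), simUn$manifest, dd)
  # independent uniform genotypes agree with probability 1/3
  se <- sqrt(1 / 3 * 2 / 3 / (65 * 18))
  expect_lt(abs(mean(gotUn$concordance) - 1 / 3), 5 * se)
})
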