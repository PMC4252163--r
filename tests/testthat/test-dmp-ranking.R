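# Printed statistics for the ten top-ranked probes of the motivating
# study's published table (inputs, used as a worked example).
publishedTopTen <- data.frame(
  probe_id = c("cg07080019", "cg12721804", "cg24618467", "cg02495760",
               "cg24644902", "cg10651583", "cg04897932", "cg09090376",
               "cg26180263", "cg25966908"),
  delta_beta = c(.07, .06, .05, -.05, -.06, -.05, -.04, -.05, .05, .05),
  p_value = c(.000144, .001758, .000822, .000950, .003038, .001586,
              .000225, .003880, .003454, .001861))

test_that("paired t handles exact-null and degenerate inputs", {
  d <- toyDesign(3)
  b <- toyBetas(2, d)
  b[1, ] <- 0.4                                    # all differences 0
  b[2, affectedSamples(d)] <- 0.47
  b[2, unaffectedSamples(d)] <- 0.40               # constant nonzero diff
  res <- pairedTTest(b, d)
  expect_equal(res$t_stat[1], 0)
  expect_equal(res$p_value[1], 1)
  expect_false(res$degenerate[2] && res$p_value[2] > 1e-300)
  expect_true(res$degenerate[2])
  expect_equal(res$delta_beta[2], 0.07)
  expect_error(pairedTTest(b, buildDesign(toySheet(1))), ">= 2 pairs")
  expect_error(pairedTTest(b[, 1:4], d), "missing from betas")
})

test_that("paired t equals the textbook recomputation via t.test", {
  d <- toyDesign(10)
  for (seed in 1:20) {
    b <- toyBetas(5, d, seed = seed, sd = 0.08)
    res <- pairedTTest(b, d)
    for (i in 1:5) {
      ref <- t.test(b[i, affectedSamples(d)], b[i, unaffectedSamples(d)],
                    paired = TRUE)
      expect_equal(res$t_stat[i], unname(ref$statistic), tolerance = 1e-12)
      expect_equal(res$p_value[i], ref$p.value, tolerance = 1e-12)
      expect_equal(res$delta_beta[i], unname(ref$estimate), tolerance = 1e-12)
    }
  }
})

test_that("summed ranks reproduce the published worked example", {
  ranked <- rankFromStats(publishedTopTen$probe_id, publishedTopTen$delta_beta, publishedTopTen$p_value)
  expect_equal(ranked$probe_id[1], "cg07080019")
  expect_equal(ranked$rank_sum[ranked$probe_id == "cg07080019"], 2) # 1 + 1
  expect_equal(ranked$final_rank[ranked$probe_id == "cg04897932"], 7)
  # hand-computed rank sums: p-ranks 1..10 by p; |db| ranks 1, 2.5 (x2),
  # 6.5 (x6), 10
  expect_equal(ranked$rank_sum[match(publishedTopTen$probe_id, ranked$probe_id)],
               c(2, 8.5, 9.5, 10.5, 10.5, 11.5, 12, 16.5, 15.5, 13.5))
  # positions 1-7 match the printed table exactly
  expect_equal(ranked$probe_id[1:7], publishedTopTen$probe_id[1:7])
})

test_that("ranking equals a brute-force sort-rank-sum oracle", {
  bruteRank <- function(id, db, p) {
    cnt <- function(v) vapply(v, function(x)
      sum(v < x) + (sum(v == x) + 1) / 2, 0)
    rs <- cnt(p) + cnt(-abs(db))
    id[order(rs, p, id)]
  }
  for (seed in 1:20) {
    set.seed(seed)
    n <- 200
    id <- sprintf("cg%05d", sample.int(1e5, n))
    db <- round(rnorm(n, 0, 0.03), 3)        # rounding forces ties
    p <- round(runif(n), 3)
    ranked <- rankFromStats(id, db, p)
    expect_equal(ranked$probe_id, bruteRank(id, db, p))
    expect_equal(sort(ranked$final_rank), 1:n)
    expect_true(all(ranked$rank_sum >= 2 & ranked$rank_sum <= 2 * n))
  }
})

test_that("ranking is invariant under monotone transforms of p and |delta|", {
  set.seed(33)
  id <- sprintf("cg%04d", 1:150)
  db <- rnorm(150, 0, 0.04); p <- runif(150)
  base <- rankFromStats(id, db, p)
  expect_equal(rankFromStats(id, db, sqrt(p))$probe_id, base$probe_id)
  expect_equal(rankFromStats(id, sign(db) * abs(db)^3, p)$final_rank[
    match(id, rankFromStats(id, sign(db) * abs(db)^3, p)$probe_id)],
    base$final_rank[match(id, base$probe_id)])
})

test_that("swapping twin labels negates effects but preserves the ranking", {
  sheet <- toySheet(8)
  d <- buildDesign(sheet)
  b <- toyBetas(60, d, seed = 44, sd = 0.06)
  fwd <- rankDmps(b, d)
  sheetSwap <- transform(sheet, status = ifelse(status == "affected",
                                                "unaffected", "affected"))
  rev <- rankDmps(b, buildDesign(sheetSwap))
  m <- match(fwd$probe_id, rev$probe_id)
  expect_equal(rev$delta_beta[m], -fwd$delta_beta)
  expect_equal(rev$t_stat[m], -fwd$t_stat)
  expect_equal(rev$p_value[m], fwd$p_value, tolerance = 1e-12)
  expect_equal(rev$final_rank[m], fwd$final_rank)
})

test_that("case-control replication test matches the Welch oracle", {
  set.seed(55)
  cols <- c(paste0("case", 1:14), paste0("ctl", 1:15))
  b <- matrix(runif(10 * 29, 0.2, 0.8), 10, 29,
              dimnames = list(sprintf("cg%03d", 1:10), cols))
  res <- caseControlTest(b, cols[1:14], cols[15:29], rownames(b))
  for (i in 1:10) {
    ref <- t.test(b[i, 1:14], b[i, 15:29])
    expect_equal(res$t_stat[i], unname(ref$statistic), tolerance = 1e-12)
    expect_equal(res$p_value[i], ref$p.value, tolerance = 1e-12)
  }
  # exact two-group null: identical group values
  b2 <- b; b2[, 15:28] <- b2[, 1:14]
  res2 <- caseControlTest(b2, cols[1:14], cols[15:28], rownames(b2)[1])
  expect_equal(res2$mean_diff, 0)
  expect_gt(res2$p_value, 0.99)
  expect_error(caseControlTest(b, cols[1], cols[2:29], "cg001"), ">= 2")
})

test_that("a planted case-control shift is recovered on average", {
  # 14 cases vs 15 controls with +0.02 at one probe, averaged over cohorts
  set.seed(66)
  diffs <- replicate(300, {
    cases <- rnorm(14, 0.52, 0.03); ctls <- rnorm(15, 0.50, 0.03)
    b <- matrix(c(cases, ctls), 1, 29,
                dimnames = list("cg1", c(paste0("c", 1:14), paste0("k", 1:15))))
    caseControlTest(b, paste0("c", 1:14), paste0("k", 1:15), "cg1")$mean_diff
  })
  expect_lt(abs(mean(diffs) - 0.02), 4 * sd(diffs) / sqrt(300))
})

test_that("sex-difference check is calibrated when effects are sex-neutral", {
  sim <- simulateDataset(simConfig(seed = 77, nProbes = 2000L,
                                   nSnpProbes = 0L, dmpSetSize = 0L))
  d <- buildDesign(sim$sheet)
  b <- computeBetas(sim$data)
  res <- sexDifferenceCheck(b, d, sim$sheet, rownames(b))
  expect_equal(res$n_female_pairs[1], 13)
  expect_equal(res$n_male_pairs[1], 5)
  # 99% binomial band around 0.05 for 2000 nearly independent probes
  expect_lt(abs(mean(res$p_value < 0.05) - 0.05),
            2.576 * sqrt(0.05 * 0.95 / 2000) + 0.01)

  # planted sex-by-effect interaction is detected
  sex <- sim$sheet$sex[match(affectedSamples(d), sim$sheet$sample_id)]
  b2 <- b
  b2["cg00000001", affectedSamples(d)[sex == "M"]] <-
    b2["cg00000001", affectedSamples(d)[sex == "M"]] + 0.25
  res2 <- sexDifferenceCheck(b2, d, sim$sheet, "cg00000001")
  expect_lt(res2$p_value, 0.01)

  sheet2 <- sim$sheet; sheet2$sex <- "F"
  expect_error(sexDifferenceCheck(b, d, sheet2, "cg00000001"), ">= 2 male")
})
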