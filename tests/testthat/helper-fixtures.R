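# Small in-code fixtures shared across test files.

toyManifest <- function(n = 5, chrom = "chr1", start = 1000, gap = 100,
                        snp = rep(FALSE, n)) {
  data.frame(probe_id = sprintf("cg%06d", seq_len(n)),
             chrom = chrom, pos = start + gap * (seq_len(n) - 1),
             design_type = rep_len(c("I", "II"), n),
             is_snp_control = snp,
             strand = rep_len(c("+", "-"), n))
}

randomManifest <- function(n, seed) {
  set.seed(seed)
  data.frame(probe_id = sprintf("cg%06d", sample.int(10 * n, n)),
             chrom = sample(c("chr1", "chr2", "chrX"), n, TRUE),
             pos = sample.int(1e6, n, replace = TRUE),
             design_type = sample(c("I", "II"), n, TRUE),
             is_snp_control = FALSE,
             strand = sample(c("+", "-", "."), n, TRUE))
}

toySheet <- function(nPairs = 4, sexes = rep_len(c("F", "M"), nPairs)) {
  pid <- sprintf("p%02d", seq_len(nPairs))
  data.frame(
    sample_id = as.vector(rbind(paste0(pid, "a"), paste0(pid, "u"))),
    pair_id = rep(pid, each = 2),
    status = rep(c("affected", "unaffected"), nPairs),
    sex = rep(sexes, each = 2),
    batch = rep(pid, each = 2))
}

toyDesign <- function(nPairs = 4, ...) buildDesign(toySheet(nPairs, ...))

# Beta matrix keyed to a toy design: probes x (2 * nPairs) columns.
toyBetas <- function(nProbes, design, seed = 1, sd = 0.05, base = 0.5) {
  set.seed(seed)
  cols <- c(affectedSamples(design), unaffectedSamples(design))
  m <- matrix(pmin(pmax(rnorm(nProbes * length(cols), base, sd), 0), 1),
              nProbes, length(cols),
              dimnames = list(sprintf("cg%06d", seq_len(nProbes)), cols))
  m
}

# Independent quantile-normalization oracle: sort each column, average
# across columns, then hand each sample the mean profile at its values'
# average ranks (linear interpolation between adjacent means for
# fractional ranks).
bruteQuantileNormalize <- function(x) {
  means <- rowMeans(apply(x, 2, sort))
  apply(x, 2, function(col) {
    r <- rank(col, ties.method = "average")
    lo <- floor(r); hi <- ceiling(r)
    means[lo] + (r - lo) * (means[hi] - means[lo])
  })
}

# Independent greedy-gap clustering oracle built on pairwise distances
# (O(n^2) single-linkage at cutoff maxGap, per chromosome).
bruteCluster <- function(man, maxGap) {
  out <- list()
  for (ch in unique(man$chrom)) {
    sub <- man[man$chrom == ch, ]
    sub <- sub[order(sub$pos), ]
    n <- nrow(sub)
    grp <- seq_len(n)
    repeat {
      merged <- FALSE
      for (i in seq_len(n)) for (j in seq_len(n)) {
        if (grp[i] != grp[j] && abs(sub$pos[i] - sub$pos[j]) <= maxGap) {
          grp[grp == grp[j]] <- grp[i]; merged <- TRUE
        }
      }
      if (!merged) break
    }
    for (g in unique(grp))
      out[[length(out) + 1]] <- sort(sub$probe_id[grp == g])
  }
  out
}

# Exact signed-rank statistic computed a second way: explicit midranks by
# counting, summed over positive differences.
bruteSignedRankStat <- function(x, y) {
  d <- (x - y)[x != y]
  a <- abs(d)
  r <- vapply(a, function(v) sum(a < v) + (sum(a == v) + 1) / 2, 0)
  sum(r[d > 0])
}

writeTempTsv <- function(df) {
  f <- tempfile(fileext = ".tsv")
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  f
}
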