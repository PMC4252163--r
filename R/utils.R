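# Internal numeric helpers shared across modules.

logit <- function(p) log(p / (1 - p))

invLogit <- function(x) 1 / (1 + exp(-x))

clipRange <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Row-wise (n-1)-denominator sample variance; guards tiny negative
# round-off from the sum-of-squares form.
rowVariances <- function(x) {
  n <- ncol(x)
  m <- rowMeans(x)
  pmax((rowSums(x * x) - n * m * m) / (n - 1), 0)
}

# Average-tie ascending ranks; named so the tie policy is explicit at the
# call sites of the summed-rank procedure.
avgRank <- function(x) rank(x, ties.method = "average")

# Deterministic sub-seed per generator stage, kept below 2^31.
stageSeed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 11L + stage) %% 2147483587)
}

stopIfNot <- function(cond, ...) if (!cond) stop(..., call. = FALSE)
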