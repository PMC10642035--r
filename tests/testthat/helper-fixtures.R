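## Shared fixtures: a desk-scale simulation configuration and independent
## oracles used across test files.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(S4Vectors)
})

tinyConfig <- function(seed = 1L, ...) {
  args <- list(seed = seed, genomeSize = 4e5, nChrom = 2L, nGenes = 20L,
               geneLength = c(2000, 8000), cpgDensity = 0.02,
               chDensity = 0.03, nSpikePerClass = 200L)
  over <- list(...)
  args[names(over)] <- over
  do.call(simConfig, args)
}

## Exhaustive hypergeometric two-sided tail enumeration for a 2x2 table
## (point-probability method), independent of stats::fisher.test.
fisherEnumerate <- function(a, b, c, d) {
  m <- a + c; n2 <- b + d; k <- a + b
  xs <- max(0L, k - n2):min(k, m)
  probs <- dhyper(xs, m, n2, k)
  pObs <- dhyper(a, m, n2, k)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

## Per-window Student t on a level matrix, via stats::t.test (oracle for
## the vectorized implementation).
tTestOracle <- function(x, s1, s2) {
  apply(x, 1L, function(r)
    t.test(r[s1], r[s2], var.equal = TRUE)$p.value)
}

expect_fractions <- function(x) {
  expect_true(all(is.na(x) | (x >= 0 & x <= 1)))
}
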