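test_that("the generator is deterministic under a fixed seed", {
  cfg <- tinyConfig(seed = 42L)
  g1 <- makeGenome(cfg); g2 <- makeGenome(cfg)
  expect_identical(g1$chromSizes, g2$chromSizes)
  expect_identical(g1$genes, g2$genes)
  expect_identical(g1$repeats, g2$repeats)
  t1 <- makeLandscape(cfg, g1); t2 <- makeLandscape(cfg, g2)
  expect_identical(t1$fracs, t2$fracs)
  expect_identical(t1$tiers, t2$tiers)
  a1 <- simulateArm(t1, "neuron", "CG", cfg$rates$BS, seed = 5L)
  a2 <- simulateArm(t2, "neuron", "CG", cfg$rates$BS, seed = 5L)
  expect_identical(a1, a2)
  ## a different seed changes the draws
  expect_false(identical(
    a1, simulateArm(t1, "neuron", "CG", cfg$rates$BS, seed = 6L)))
})

test_that("the genome layout honors its constraints", {
  cfg <- tinyConfig(seed = 3L, nGenes = 50L, geneLength = c(1000, 4000))
  g <- makeGenome(cfg)
  expect_length(g$genes, 50L)
  expect_equal(sum(countOverlaps(g$genes, g$genes,
                                 ignore.strand = TRUE)), 50L)
  expect_true(all(width(g$genes) >= 1000 & width(g$genes) <= 4000))
  ## realized repeat fraction tracks the request
  frac <- sum(width(GenomicRanges::reduce(g$repeats,
                                          ignore.strand = TRUE))) /
    sum(g$chromSizes)
  expect_lt(abs(frac - cfg$repeatFraction), 0.02)
  expect_setequal(unique(mcols(g$repeats)$class),
                  c("LINE", "SINE", "LTR", "Simple_repeat"))
  ## infeasible layouts are refused
  expect_error(makeGenome(tinyConfig(nGenes = 200L,
                                     geneLength = c(4000, 8000))),
               "infeasible")
})

test_that("landscape means realize the configured genome-wide targets", {
  cfg <- tinyConfig(seed = 11L)
  tr <- makeLandscape(cfg, makeGenome(cfg))
  for (ct in names(cfg$targets)) {
    expect_equal(mean(tr$means[[ct]]$CG$mC), cfg$targets[[ct]]$mCG,
                 tolerance = 1e-6)
    expect_equal(mean(tr$means[[ct]]$CG$hmC), cfg$targets[[ct]]$hmCG,
                 tolerance = 1e-6)
    expect_equal(mean(tr$means[[ct]]$CH$mC), cfg$targets[[ct]]$mCH,
                 tolerance = 1e-6)
    ## hmCH target 0 -> exactly zero everywhere
    expect_true(all(tr$means[[ct]]$CH$hmC == 0))
    expect_true(all(tr$fracs[[ct]]$CH[, "f_hmC"] == 0))
    ## realized fractions average to the target within Monte-Carlo error
    expect_equal(mean(tr$fracs[[ct]]$CG[, "f_mC"]),
                 cfg$targets[[ct]]$mCG, tolerance = 0.01)
  }
  ## simplex everywhere
  s <- rowSums(tr$fracs$neuron$CG)
  expect_equal(range(s), c(1, 1), tolerance = 1e-12)
})

test_that("simple-repeat mCH is elevated without moving the genome mean", {
  cfg <- tinyConfig(seed = 2L)
  tr <- makeLandscape(cfg, makeGenome(cfg))
  sr <- overlapsAny(tr$sites$CH,
                    tr$repeats[mcols(tr$repeats)$class == "Simple_repeat"],
                    ignore.strand = TRUE)
  m <- tr$means$neuron$CH$mC
  expect_equal(mean(m[sr]), cfg$simpleRepeatMCH[["neuron"]],
               tolerance = 1e-6)
  expect_equal(mean(m), cfg$targets$neuron$mCH, tolerance = 1e-6)
})

test_that("planted windows carry their configured true difference", {
  planted <- data.frame(mod_type = "hmCG", cell_a = "neuron",
                        cell_b = "astrocyte", n = 5L, diff = 20)
  cfg <- tinyConfig(seed = 6L, planted = planted)
  tr <- makeLandscape(cfg, makeGenome(cfg))
  expect_length(tr$planted, 5L)
  for (i in seq_along(tr$planted)) {
    w <- tr$planted[i]
    sel <- overlapsAny(tr$sites$CG, w, ignore.strand = TRUE)
    d <- mean(tr$means$neuron$CG$hmC[sel]) -
      mean(tr$means$astrocyte$CG$hmC[sel])
    expect_equal(100 * d, 20, tolerance = 1e-6)
  }
})

test_that("the arm forward model behaves like the chemistry it encodes", {
  cfg <- tinyConfig(seed = 8L)
  tr <- makeLandscape(cfg, makeGenome(cfg))
  ## perfect BS chemistry on a fully methylated landscape: every call
  ## reads modified
  cfgFull <- tinyConfig(seed = 8L,
                        targets = list(neuron = list(mCG = 0.999,
                                                     hmCG = 0, mCH = 0,
                                                     hmCH = 0)),
                        simpleRepeatMCH = c(neuron = 0),
                        repeatMcgOffset = 0, repeatHmcgOffset = 0,
                        promoterMult = list(
                          mCG = c(high = 1, mid = 1, low = 1,
                                  unexpressed = 1),
                          hmCG = c(high = 1, mid = 1, low = 1,
                                   unexpressed = 1),
                          mCH = c(high = 1, mid = 1, low = 1,
                                  unexpressed = 1)),
                        bodyMult = list(
                          mCG = c(high = 1, mid = 1, low = 1,
                                  unexpressed = 1),
                          hmCG = c(high = 1, mid = 1, low = 1,
                                   unexpressed = 1),
                          mCH = c(high = 1, mid = 1, low = 1,
                                  unexpressed = 1)))
  trF <- makeLandscape(cfgFull, makeGenome(cfgFull))
  trF$fracs$neuron$CG[, "f_mC"] <- 1
  trF$fracs$neuron$CG[, "f_C"] <- 0
  arm <- simulateArm(trF, "neuron", "CG", ConversionRates("BS", 0, 1, 1),
                     meanCoverage = 3, seed = 2L)
  expect_identical(modifiedCalls(arm), siteCoverage(arm))
  ## BS reads at least as modified as oxBS in expectation when hmC > 0
  diffs <- vapply(1:20, function(i) {
    bs <- simulateArm(tr, "neuron", "CG", cfg$rates$BS,
                      meanCoverage = 2, seed = 100L + i)
    ox <- simulateArm(tr, "neuron", "CG", cfg$rates$oxBS,
                      meanCoverage = 2, seed = 200L + i)
    genomeLevel(bs) - genomeLevel(ox)
  }, numeric(1))
  expect_gt(mean(diffs > 0), 0.95)
  expect_equal(mean(diffs), 0.16 * 0.9, tolerance = 0.02)
})

test_that("the spike-in loop recovers the configured rates", {
  cfg <- tinyConfig(seed = 4L, nSpikePerClass = 2000L)
  tr <- makeLandscape(cfg, makeGenome(cfg))
  for (arm in c("BS", "oxBS")) {
    sp <- simulateSpikeIns(tr, cfg$rates[[arm]], meanCoverage = 20,
                           seed = 3L)
    est <- conversionRates(estimateConversionRates(sp, tr$spikes, arm))
    want <- conversionRates(cfg$rates[[arm]])
    for (i in 1:3) {
      se <- sqrt(max(want[i] * (1 - want[i]), 1e-6) / (2000 * 20))
      expect_lt(abs(est[i] - want[i]), 4 * se)
    }
  }
})

test_that("expression tables respect tiers and are recoverable", {
  cfg <- tinyConfig(seed = 5L, nGenes = 120L, geneLength = c(1000, 2500))
  tr <- makeLandscape(cfg, makeGenome(cfg))
  e <- makeExpression(tr, "neuron", seed = 7L)
  tier <- tr$tiers$neuron
  expect_true(all(e[names(tier)[tier == "unexpressed"], ] == 0))
  ## per-tier mean ordering holds in every replicate
  for (j in seq_len(ncol(e))) {
    mus <- tapply(e[, j], tier[rownames(e)], mean)
    expect_gt(mus[["high"]], mus[["mid"]])
    expect_gt(mus[["mid"]], mus[["low"]])
  }
  ## expressionClasses recovers the planted tiers at >= 95% agreement
  cl <- expressionClasses(e)
  agree <- mean(c(tier[cl$high] == "high", tier[cl$mid] == "mid",
                  tier[cl$low] == "low",
                  tier[cl$unexpressed] == "unexpressed"))
  expect_gte(agree, 0.95)
})

test_that("the full simulate-subtract loop recovers genome-wide truths", {
  ## simulate both arms with realistic chemistry, subtract, and compare
  ## to the configured targets after conversion correction
  cfg <- tinyConfig(seed = 9L, meanCoverage = 4)
  tr <- makeLandscape(cfg, makeGenome(cfg))
  bs <- simulateArm(tr, "neuron", "CG", cfg$rates$BS, seed = 31L)
  ox <- simulateArm(tr, "neuron", "CG", cfg$rates$oxBS, seed = 32L)
  spB <- simulateSpikeIns(tr, cfg$rates$BS, seed = 33L)
  spO <- simulateSpikeIns(tr, cfg$rates$oxBS, seed = 34L)
  rB <- estimateConversionRates(spB, tr$spikes, "BS")
  rO <- estimateConversionRates(spO, tr$spikes, "oxBS")
  corr <- correctLevels(genomeLevel(bs), genomeLevel(ox), rB, rO)
  expect_equal(corr$f_mC, cfg$targets$neuron$mCG, tolerance = 0.02)
  expect_equal(corr$f_hmC, cfg$targets$neuron$hmCG, tolerance = 0.02)
})
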