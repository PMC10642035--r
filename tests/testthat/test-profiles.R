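## Uniform call table: every position pos in [1, n] covered with level p.
constantCalls <- function(n, p, cov = 10L, context = "CG") {
  SiteCalls("chr1", seq(1L, n, by = 7L), "+",
            cov, as.integer(round(cov * p)), context = context)
}

test_that("expression classes split genes as specified", {
  expr <- rbind(g01 = c(0, 0, 0, 0),
                matrix(rep(c(100, 90, 80, 70, 60, 50, 40, 30, 20), 4),
                       ncol = 4,
                       dimnames = list(paste0("g", 10:18), NULL)))
  cl <- expressionClasses(expr)
  expect_equal(cl$unexpressed, "g01")
  expect_equal(lengths(cl[c("high", "mid", "low")]),
               c(high = 3L, mid = 3L, low = 3L))
  expect_equal(cl$high, c("g10", "g11", "g12"))
  expect_equal(cl$low, c("g16", "g17", "g18"))
  ## 10 expressed genes -> sizes 4/3/3 from the highest tertile down
  expr10 <- matrix(100:91, ncol = 1,
                   dimnames = list(paste0("g", sprintf("%02d", 1:10)), NULL))
  cl10 <- expressionClasses(expr10)
  expect_equal(lengths(cl10[c("high", "mid", "low")]),
               c(high = 4L, mid = 3L, low = 3L))
  ## partition property and stable tie-breaking by gene id
  exprT <- matrix(rep(5, 6), ncol = 1,
                  dimnames = list(paste0("g", 1:6), NULL))
  clT <- expressionClasses(exprT)
  expect_equal(sort(unlist(clT[1:3], use.names = FALSE)), rownames(exprT))
  expect_equal(clT$high, c("g1", "g2"))
  expect_error(expressionClasses(matrix(numeric(), 0, 1)), "empty")
})

test_that("metagene profiles are flat on a constant landscape", {
  genes <- geneModels(
    GRanges("chr1", IRanges(c(20000L, 60000L), width = 5000L),
            strand = c("+", "-")),
    c("gA", "gB"))
  calls <- list(s1 = constantCalls(100000L, 0.5))
  mp <- metageneProfile(calls, genes, flank = 4000L, flankBins = 20L,
                        bodyBins = 27L)
  expect_equal(nrow(mp), 67L)
  expect_equal(unique(mp$segment[mp$bin <= 20]), "upstream")
  expect_equal(unique(mp$segment[mp$bin > 20 & mp$bin <= 47]), "body")
  expect_equal(mp$level, rep(0.5, 67))
  expect_equal(unique(mp$n_genes), 2L)
})

test_that("minus-strand profiles mirror the plus-strand layout", {
  ## one plus gene and one minus gene with mirror-image landscapes must
  ## produce the same 5'->3' profile
  gPlus <- geneModels(GRanges("chr1", IRanges(20000L, 24999L),
                              strand = "+"), "gP")
  gMinus <- geneModels(GRanges("chr2", IRanges(20000L, 24999L),
                               strand = "-"), "gM")
  set.seed(14)
  pos <- seq(14000L, 31000L, by = 5L)
  lv <- runif(length(pos))
  callsP <- SiteCalls("chr1", pos, "+", 20L, round(20 * lv), "CG")
  ## mirror the landscape around the gene midpoint (22499.5)
  callsM <- SiteCalls("chr2", as.integer(2L * 22499L + 1L - pos), "+",
                      20L, round(20 * lv), "CG")
  mpP <- metageneProfile(list(s = callsP), gPlus)
  mpM <- metageneProfile(list(s = callsM), gMinus)
  expect_equal(mpM$level, mpP$level, tolerance = 1e-12)
})

test_that("a planted TSS dip is recovered at the right bins", {
  genes <- geneModels(GRanges("chr1", IRanges(20000L, 30000L),
                              strand = "+"), "gA")
  pos <- seq(15000L, 35000L, by = 4L)
  lv <- ifelse(pos >= 19600L & pos <= 20400L, 0.1, 0.8)
  calls <- SiteCalls("chr1", pos, "+", 25L, round(25 * lv), "CG")
  mp <- metageneProfile(list(s = calls), genes)
  dipBins <- mp$bin[mp$level < 0.4]
  expect_true(all(dipBins %in% 19:22))
  expect_gt(min(dipBins), 18)
  ## genes shorter than the body bin count are dropped with a count
  tiny <- geneModels(GRanges("chr1", IRanges(c(100L, 20000L),
                                             width = c(10L, 10001L)),
                             strand = "+"), c("tiny", "gA"))
  mp2 <- metageneProfile(list(s = calls), tiny)
  expect_equal(attr(mp2, "dropped_short_genes"), 1L)
})

test_that("region averages are conserved against the genome level", {
  genes <- geneModels(GRanges("chr1", IRanges(20000L, 29999L),
                              strand = "+"), "gA")
  set.seed(31)
  pos <- seq(16000L, 34000L, by = 3L)
  cov <- rpois(length(pos), 8) + 1L
  calls <- SiteCalls("chr1", pos, "+", cov,
                     rbinom(length(pos), cov, 0.6), "CG")
  ra <- regionAverages(list(s = calls), genes)
  expect_setequal(ra$region, c("upstream", "body", "downstream"))
  ## coverage-weighted recombination of the three regions equals the
  ## genome level over their union
  regs <- list(GRanges("chr1", IRanges(16000L, 19999L)),
               GRanges("chr1", IRanges(20000L, 29999L)),
               GRanges("chr1", IRanges(30000L, 33999L)))
  w <- sapply(regs, function(r) sum(siteCoverage(calls)[
    overlapsAny(calls, r)]))
  keep <- overlapsAny(calls, GRanges("chr1", IRanges(16000L, 33999L)))
  lvAll <- sum(modifiedCalls(calls)[keep]) / sum(siteCoverage(calls)[keep])
  ord <- match(c("upstream", "body", "downstream"), ra$region)
  expect_equal(sum(ra$level[ord] * w) / sum(w), lvAll, tolerance = 1e-12)
  ## constant landscape: all three regions equal
  cc <- constantCalls(40000L, 0.5)
  raC <- regionAverages(list(s = cc), genes)
  expect_equal(raC$level, rep(0.5, 3))
})

test_that("group comparisons of region averages behave as designed", {
  ## identical groups -> p = 1 on zero paired differences
  df <- data.frame(sample = rep(1:4, 2),
                   group = rep(c("input", "pos"), each = 4),
                   region = "body",
                   level = rep(c(.5, .52, .48, .51), 2))
  out <- compareRegionAverages(df, design = "paired")
  expect_equal(out$p, 1)
  expect_error(compareRegionAverages(df[-1, ], design = "paired"),
               "unbalanced")
  ## power: a 5 pp shift with 1 pp SD at n = 4 rejects essentially always
  set.seed(9)
  rej <- mean(replicate(100, {
    d <- data.frame(group = rep(c("a", "b"), each = 4), region = "body",
                    level = c(rnorm(4, 0.55, 0.01), rnorm(4, 0.50, 0.01)))
    compareRegionAverages(d, design = "paired")$p < 0.05
  }))
  expect_gte(rej, 0.99)
  ## Sidak closed form
  expect_equal(sidakAdjust(0.01, m = 5), 1 - 0.99^5)
  ## multi-group ANOVA with pooled-variance contrasts
  set.seed(10)
  dfm <- expand.grid(rep_ = 1:4, group = c("n", "a", "m"),
                     region = c("upstream", "body", "downstream"))
  dfm$level <- 0.5 + 0.2 * (dfm$group == "n" & dfm$region == "body") +
    rnorm(nrow(dfm), 0, 0.01)
  res <- compareRegionAverages(dfm, design = "multi")
  ct <- res$contrasts
  hit <- ct[ct$region == "body" & grepl("n", ct$contrast), ]
  expect_true(all(hit$p_sidak < 0.01))
  miss <- ct[ct$region == "upstream", ]
  expect_true(all(miss$p_sidak > 0.05))
})

test_that("repeat summaries partition sites and mix as expected", {
  calls <- constantCalls(10000L, 0.5, context = "CH")
  ## no repeat intervals: non-repeat equals whole genome, repeat missing
  rs0 <- repeatSummary(list(s = calls), GRanges())
  expect_true(is.na(rs0$level[rs0$category == "repeat"]))
  expect_equal(rs0$level[rs0$category == "non_repeat"],
               rs0$level[rs0$category == "whole_genome"])
  ## repeats covering everything: repeat equals whole genome
  all_ <- GRanges("chr1", IRanges(1L, 10000L))
  mcols(all_)$class <- "LINE"
  rs1 <- repeatSummary(list(s = calls), all_)
  expect_equal(rs1$level[rs1$category == "repeat"],
               rs1$level[rs1$category == "whole_genome"])
  ## mixture arithmetic: 85% in repeats, 70% outside, repeat fraction 1/2
  set.seed(2)
  pos <- seq(1L, 20000L, by = 2L)
  inRep <- pos <= 10000L
  cov <- rep(20L, length(pos))
  mod <- as.integer(round(20 * ifelse(inRep, 0.85, 0.70)))
  mix <- SiteCalls("chr1", pos, "+", cov, mod, "CH")
  repIv <- GRanges("chr1", IRanges(1L, 10000L))
  mcols(repIv)$class <- "Simple_repeat"
  rs2 <- repeatSummary(list(s = mix), repIv)
  expect_equal(rs2$level[rs2$category == "whole_genome"], 0.775,
               tolerance = 1e-3)
  expect_equal(rs2$level[rs2$category == "Simple_repeat"], 0.85,
               tolerance = 1e-3)
  expect_warning(repeatSummary(list(s = mix),
                               {x <- repIv; mcols(x)$class <- "weird"; x}),
                 "Other")
})

test_that("targeted region tests flag planted per-CpG differences", {
  set.seed(23)
  ## identical profiles: nothing significant
  base <- matrix(rep(seq(0.2, 0.8, length.out = 20), 3), 20,
                 dimnames = list(paste0("cpg", 1:20), NULL))
  same <- emseqRegionTests(base, base)
  expect_equal(same$region$p, 1)
  expect_true(all(same$per_cpg$p_sidak > 0.99))
  ## planted 30 pp at 3 of 20 CpGs, SD 5 pp, n = 3: flagged positions are
  ## the planted ones at >= 90% sensitivity over 100 reps
  hits <- replicate(100, {
    l1 <- base[, c(1, 1, 1)] + matrix(rnorm(60, 0, 0.05), 20)
    l2 <- base[, c(1, 1, 1)] + matrix(rnorm(60, 0, 0.05), 20)
    l1[1:3, ] <- l1[1:3, ] + 0.30
    res <- emseqRegionTests(l1, l2)$per_cpg
    sig <- res$pos[res$p_sidak < 0.05]
    c(sens = mean(paste0("cpg", 1:3) %in% sig),
      false = sum(!sig %in% paste0("cpg", 1:3)))
  })
  expect_gte(mean(hits["sens", ]), 0.9)
  expect_lt(mean(hits["false", ] / 17), 0.05)
  ## Sidak over m = 20 positions matches the closed form
  l1 <- base + matrix(rnorm(60, 0, 0.02), 20)
  res <- emseqRegionTests(l1, base + matrix(rnorm(60, 0, 0.02), 20))
  expect_equal(res$per_cpg$p_sidak, sidakAdjust(res$per_cpg$p, 20))
})
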