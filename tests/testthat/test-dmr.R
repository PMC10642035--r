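test_that("genome tiling is exhaustive with a retained partial tile", {
  tiles <- tileWindows(c(chrA = 2500L), 1000L)
  expect_equal(start(tiles), c(1L, 1001L, 2001L))
  expect_equal(end(tiles), c(1000L, 2000L, 2500L))
  expect_length(tileWindows(c(chrA = 1000L), 1000L), 1L)
  sizes <- c(chr1 = 2500L, chr2 = 999L, chr3 = 3000L)
  expect_equal(sum(width(tileWindows(sizes, 1000L))), sum(sizes))
})

test_that("window retention rules follow the per-analysis coverage rules", {
  tiles <- tileWindows(c(chr1 = 3000L), 1000L)
  mk <- function(pos, cov, mod)
    SiteCalls("chr1", pos, "+", cov, mod, "CG")
  calls <- list(s1 = mk(c(100L, 1100L, 2100L), c(10L, 10L, 10L),
                        c(4L, 5L, 6L)),
                s2 = mk(c(150L, 1150L, 2150L), c(8L, 8L, 8L),
                        c(4L, 4L, 4L)),
                s3 = mk(c(160L, 1160L), c(6L, 6L), c(3L, 3L)),
                s4 = mk(c(170L, 1170L), c(6L, 6L), c(3L, 3L)))
  wtAll <- windowLevels(calls, tiles, rep(c("a", "b"), each = 2),
                        rule = "all")
  expect_equal(nrow(wtAll), 2L)       # window 3 covered in only 2 samples
  expect_equal(metadata(wtAll)$dropped_windows, 1L)
  wt2 <- windowLevels(calls, tiles, rep(c("a", "b"), each = 2),
                      rule = "at_least_k", k = 2L)
  expect_equal(nrow(wt2), 3L)         # retained under at-least-two
  expect_equal(unname(assay(wtAll, "level")[1, "s1"]), 0.4)
})

test_that("step-up q-values equal the independently coded BH adjustment", {
  expect_equal(manualQ(0.5), 0.5)
  expect_equal(manualQ(c(0.04, 0.01)), c(0.04, 0.02))
  expect_error(manualQ(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(10)
  for (i in 1:50) {
    p <- runif(sample(1:200, 1))
    if (i %% 5 == 0) p <- round(p, 1)  # exercise heavy ties
    expect_equal(manualQ(p), p.adjust(p, "BH"))
  }
})

test_that("the closed-form window LRT equals the binomial GLM test", {
  set.seed(8)
  for (i in 1:20) {
    cov <- rpois(8, 30) + 2L
    p <- runif(1, 0.05, 0.95)
    mod <- rbinom(8, cov, p + c(rep(0, 4), runif(1, -0.05, 0.05)))
    g <- factor(rep(c("a", "b"), each = 4))
    fit1 <- glm(cbind(mod, cov - mod) ~ g, family = binomial)
    fit0 <- glm(cbind(mod, cov - mod) ~ 1, family = binomial)
    pGlm <- anova(fit0, fit1, test = "LRT")$`Pr(>Chi)`[2]
    pOurs <- oxbsdm:::binomialLrt(sum(mod[1:4]), sum(cov[1:4]),
                                  sum(mod[5:8]), sum(cov[5:8]))
    expect_equal(pOurs, pGlm, tolerance = 1e-8)
  }
})

test_that("window DMR calls apply the difference and q filters", {
  tiles <- tileWindows(c(chr1 = 3000L), 1000L)
  ## identical counts in every window -> no records
  covM <- matrix(50, 3, 8)
  modM <- matrix(rep(c(10, 25, 40), 8), 3)
  wt <- makeWindowTable(tiles, covM, modM,
                        groups = rep(c("a", "b"), each = 4))
  expect_length(callDMR(wt, c("a", "b")), 0L)
  ## a 30 pp difference at deep coverage is recovered; a 4.9 pp
  ## difference with tiny p is still excluded by the >= 5 pp filter
  modM2 <- modM
  modM2[1, 1:4] <- 40                      # group a: 80% vs group b: 20%
  covB <- matrix(5000, 3, 8)
  modB <- cbind(matrix(5000 * 0.549, 3, 4), matrix(5000 * 0.5, 3, 4))
  wt2 <- makeWindowTable(tiles, covM, modM2,
                         groups = rep(c("a", "b"), each = 4))
  rec <- callDMR(wt2, c("a", "b"))
  expect_length(rec, 1L)
  expect_equal(start(rec), 1L)
  expect_equal(mcols(rec)$direction, "hyper")
  expect_equal(mcols(rec)$diff, 60)
  wt3 <- makeWindowTable(tiles, covB, modB,
                         groups = rep(c("a", "b"), each = 4))
  expect_length(callDMR(wt3, c("a", "b")), 0L)   # diff 4.9 pp, p ~ 0
  expect_length(callDMR(wt3, c("a", "b"), minDiffPct = 4), 3L)
})

test_that("the vectorized window t test matches stats::t.test", {
  set.seed(13)
  x <- matrix(rnorm(50 * 8, 0.5, 0.05), 50)
  tt <- oxbsdm:::rowTTest(x, 1:4, 5:8, varPooling = "per_window")
  expect_equal(tt$p, tTestOracle(x, 1:4, 5:8), tolerance = 1e-12)
  ## across-window pooling: one variance, df summed over windows
  tg <- oxbsdm:::rowTTest(x, 1:4, 5:8, varPooling = "across_windows")
  sp2 <- mean(apply(x[, 1:4], 1, var) + apply(x[, 5:8], 1, var)) / 2
  tstat <- (rowMeans(x[, 1:4]) - rowMeans(x[, 5:8])) / sqrt(sp2 / 2)
  expect_equal(tg$p, 2 * pt(-abs(tstat), 50 * 6), tolerance = 1e-12)
})

test_that("DhMR calling subtracts arms, tests, and filters as specified", {
  tiles <- tileWindows(c(chr1 = 5000L), 1000L)
  g <- rep(c("a", "b"), each = 4)
  base <- matrix(0.5, 5, 8)
  ox <- makeWindowTable(tiles, level = matrix(0.2, 5, 8), groups = g)
  ## identical per-sample h everywhere -> no records
  bs0 <- makeWindowTable(tiles, level = base, groups = g)
  expect_length(callDhMR(bs0, ox, c("a", "b")), 0L)
  ## planted 20 pp h difference in window 2, tight replicate noise
  set.seed(2)
  lv <- base + matrix(rnorm(40, 0, 0.005), 5)
  lv[2, 1:4] <- lv[2, 1:4] + 0.20
  bs <- makeWindowTable(tiles, level = lv, groups = g)
  rec <- callDhMR(bs, ox, c("a", "b"))
  expect_equal(start(rec), 1001L)
  expect_equal(mcols(rec)$direction, "hyper")
  expect_equal(mcols(rec)$diff, 20, tolerance = 1)
  ## a 6 pp difference too noisy for the t test is excluded
  set.seed(4)
  lv2 <- base + matrix(rnorm(40, 0, 0.08), 5)
  lv2[3, 1:4] <- lv2[3, 1:4] + 0.06
  bs2 <- makeWindowTable(tiles, level = lv2, groups = g)
  rec2 <- callDhMR(bs2, ox, c("a", "b"))
  expect_false("chr1:2001-3000" %in%
               paste0(seqnames(rec2), ":", start(rec2), "-", end(rec2)))
  expect_error(callDhMR(bs, ox, c("a", "missing")), "replicates")
})

test_that("DhMR results are invariant to sample order and window order", {
  tiles <- tileWindows(c(chr1 = 20000L), 1000L)
  g <- rep(c("a", "b"), each = 4)
  set.seed(6)
  lv <- matrix(rnorm(20 * 8, 0.4, 0.03), 20)
  lv[5, 1:4] <- lv[5, 1:4] + 0.25
  bs <- makeWindowTable(tiles, level = lv, groups = g)
  ox <- makeWindowTable(tiles, level = matrix(0.1, 20, 8), groups = g)
  rec <- callDhMR(bs, ox, c("a", "b"))
  ## permute samples within groups
  perm <- c(sample(1:4), sample(5:8))
  bsP <- makeWindowTable(tiles, level = lv[, perm], groups = g[perm],
                         samples = paste0("sample", perm))
  oxP <- makeWindowTable(tiles, level = matrix(0.1, 20, 8),
                         groups = g[perm],
                         samples = paste0("sample", perm))
  recP <- callDhMR(bsP, oxP, c("a", "b"))
  expect_equal(start(rec), start(recP))
  expect_equal(mcols(rec)$p, mcols(recP)$p)
  ## permute windows
  wperm <- sample(20)
  bsW <- makeWindowTable(tiles[wperm], level = lv[wperm, ], groups = g)
  oxW <- makeWindowTable(tiles[wperm], level = matrix(0.1, 20, 8),
                         groups = g)
  recW <- callDhMR(bsW, oxW, c("a", "b"))
  expect_setequal(start(recW), start(rec))
  expect_equal(sort(mcols(recW)$q), sort(mcols(rec)$q))
})

test_that("three-way overlaps match brute-force set algebra", {
  tiles <- tileWindows(c(chr1 = 100000L), 1000L)
  mkRec <- function(idx, dir) {
    g <- granges(tiles[idx])
    mcols(g)$direction <- dir
    g
  }
  ## disjoint sets
  ov <- dmrOverlap(mkRec(1:3, "hyper"), mkRec(4:6, "hyper"),
                   mkRec(7:9, "hyper"))
  expect_equal(ov$count[ov$direction == "hyper" &
                        ov$region %in% c("AB", "AC", "BC", "ABC")],
               rep(0L, 4))
  ## identical sets: all mass in the triple intersection
  ov2 <- dmrOverlap(mkRec(1:5, "hypo"), mkRec(1:5, "hypo"),
                    mkRec(1:5, "hypo"))
  expect_equal(ov2$count[ov2$direction == "hypo" & ov2$region == "ABC"], 5L)
  expect_equal(sum(ov2$count[ov2$direction == "hypo"]), 5L)
  ## random sets vs an independent enumeration over window membership
  set.seed(77)
  ia <- sample(100, 30); ib <- sample(100, 30); ic <- sample(100, 30)
  ov3 <- dmrOverlap(mkRec(ia, "hyper"), mkRec(ib, "hyper"),
                    mkRec(ic, "hyper"))
  memb <- cbind(1:100 %in% ia, 1:100 %in% ib, 1:100 %in% ic)
  code <- memb %*% c(4, 2, 1)
  want <- c(A = sum(code == 4), B = sum(code == 2), C = sum(code == 1),
            AB = sum(code == 6), AC = sum(code == 5), BC = sum(code == 3),
            ABC = sum(code == 7))
  got <- setNames(ov3$count[ov3$direction == "hyper"],
                  ov3$region[ov3$direction == "hyper"])
  expect_equal(got[names(want)], want)
})

test_that("anti-correlated planted mCG/hmCG differences are recovered by
           the correlation diagnostic", {
  tiles <- tileWindows(c(chr1 = 50000L), 1000L)
  set.seed(19)
  d <- rnorm(30, 0, 15)
  mkRec <- function(diffs) {
    g <- granges(tiles[seq_along(diffs)])
    mcols(g)$diff <- diffs
    mcols(g)$direction <- ifelse(diffs > 0, "hyper", "hypo")
    g
  }
  out <- diffCorrelation(mkRec(d), mkRec(-d + rnorm(30, 0, 3)))
  expect_equal(out$n, 30L)
  expect_lt(out$r, -0.9)
})
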