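## Genome tiling, per-sample window levels, and differential-region calling:
## DMCGR/DMCHR by a binomial likelihood-ratio test on pooled window counts,
## DhMCGR by per-window subtraction plus a two-sample t test, both with a
## step-up q-value.

#' Tile a genome into fixed-width windows
#'
#' Consecutive non-overlapping half-open tiles per chromosome; the final
#' partial tile is retained, so tile lengths sum to the genome length.
#'
#' @param chromSizes named integer vector of chromosome lengths.
#' @param width tile width in bp (default 1000).
#' @return An unstranded [GenomicRanges::GRanges] of tiles.
#' @export
tileWindows <- function(chromSizes, width = 1000L) {
  stopifnot(width >= 1L)
  tiles <- GenomicRanges::tileGenome(chromSizes, tilewidth = as.integer(width),
                                     cut.last.tile.in.chrom = TRUE)
  tiles
}

windowKey <- function(gr)
  paste0(as.character(seqnames(gr)), ":", start(gr), "-", end(gr))

#' Per-sample modification levels over genome tiles
#'
#' Pools each sample's site counts within each window and applies the
#' window-retention rule: `"all"` keeps windows covered (coverage > 0) in
#' every sample (the DMCGR/DMCHR rule); `"at_least_k"` keeps windows
#' covered in at least `k` samples (the DhMCGR rule, `k = 2`).
#'
#' @param callsList named list of [SiteCalls], one per sample (same
#'   context).
#' @param windows tile [GenomicRanges::GRanges] from [tileWindows()].
#' @param groups character vector of group labels parallel to `callsList`.
#' @param rule `"all"` or `"at_least_k"`.
#' @param k minimum number of covered samples under `"at_least_k"`.
#' @return A [WindowTable]; the number of dropped windows is recorded in
#'   `metadata()`.
#' @export
windowLevels <- function(callsList, windows, groups,
                         rule = c("all", "at_least_k"), k = 2L) {
  rule <- match.arg(rule)
  stopifnot(length(callsList) >= 1L, length(groups) == length(callsList))
  ctx <- unique(vapply(callsList, modContext, character(1)))
  if (length(ctx) != 1L)
    stop("all samples must share one context; got: ",
         paste(ctx, collapse = ", "))
  n <- length(windows)
  covM <- matrix(0, n, length(callsList))
  modM <- matrix(0, n, length(callsList))
  for (j in seq_along(callsList)) {
    calls <- callsList[[j]]
    hits <- findOverlaps(calls, windows, ignore.strand = TRUE)
    if (length(hits)) {
      cs <- rowsum(as.numeric(siteCoverage(calls)[queryHits(hits)]),
                   subjectHits(hits))
      ms <- rowsum(as.numeric(modifiedCalls(calls)[queryHits(hits)]),
                   subjectHits(hits))
      i <- as.integer(rownames(cs))
      covM[i, j] <- cs[, 1L]; modM[i, j] <- ms[, 1L]
    }
  }
  covered <- covM > 0
  keep <- if (rule == "all") rowSums(covered) == length(callsList)
          else rowSums(covered) >= k
  nDropped <- sum(!keep)
  covM <- covM[keep, , drop = FALSE]
  modM <- modM[keep, , drop = FALSE]
  lev <- ifelse(covM > 0, modM / covM, NA_real_)
  nm <- names(callsList)
  if (is.null(nm)) nm <- paste0("sample", seq_along(callsList))
  colnames(covM) <- colnames(modM) <- colnames(lev) <- nm
  se <- SummarizedExperiment(
    assays = list(coverage = covM, modified = modM, level = lev),
    rowRanges = windows[keep],
    colData = S4Vectors::DataFrame(sample = nm, group = groups,
                                   row.names = nm))
  wt <- new("WindowTable", se)
  metadata(wt)$context <- ctx
  metadata(wt)$dropped_windows <- nDropped
  metadata(wt)$rule <- rule
  wt
}

## Closed-form binomial likelihood-ratio test of modified/coverage counts on
## two-group membership, per window. With group as the sole covariate the
## binomial GLM's fitted probabilities are the group-pooled proportions, so
## the glm LRT has this closed form (no overdispersion correction).
binomialLrt <- function(mod1, cov1, mod2, cov2) {
  xlogy <- function(x, y) ifelse(x > 0, x * log(y), 0)
  ll <- function(m, c, p) xlogy(m, p) + xlogy(c - m, 1 - p)
  p1 <- mod1 / cov1; p2 <- mod2 / cov2
  p0 <- (mod1 + mod2) / (cov1 + cov2)
  stat <- 2 * (ll(mod1, cov1, p1) + ll(mod2, cov2, p2) -
               ll(mod1, cov1, p0) - ll(mod2, cov2, p0))
  pchisq(pmax(stat, 0), df = 1L, lower.tail = FALSE)
}

#' Step-up q-values (manual Benjamini-Hochberg)
#'
#' The step-up adjustment computed explicitly: sort p ascending with ranks
#' `1..N`; at the largest rank `q_N = p_N`; stepping down,
#' `q_i = min(p_i * N / i, q_{i+1})`; return in the original order. This is
#' algebraically the Benjamini-Hochberg adjustment; equivalence to an
#' independently coded BH is asserted in the test suite. Tied p-values
#' share the step-up minimum naturally under the stable sort.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return q-values in `[0, 1]`, parallel to `p`.
#' @examples
#' manualQ(c(0.04, 0.01))  # 0.04, 0.02
#' @export
manualQ <- function(p) {
  if (!length(p)) return(numeric())
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- ps * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

#' Call differentially methylated regions (DMCGR/DMCHR)
#'
#' Per retained window, a logistic-regression likelihood-ratio test of the
#' pooled modified/coverage counts on two-group membership (computed in
#' closed form; identical to the binomial GLM deviance test). P-values are
#' converted to q with [manualQ()] over all tested windows; reported
#' records satisfy `|diff| >= minDiffPct` (percentage points) and
#' `q < qMax`. Direction is `hyper`/`hypo` with respect to the first group
#' of `comparison`.
#'
#' @param wt a [WindowTable] with count assays.
#' @param comparison character(2): the two group labels, first vs second.
#' @param minDiffPct minimum absolute group difference in percentage points
#'   (default 5).
#' @param qMax q-value cutoff (default 0.05).
#' @param modType modification label stored on the records (e.g. `"mCG"`).
#' @return A [GenomicRanges::GRanges] of differential records with columns
#'   `mod_type`, `comparison`, `mean1`, `mean2`, `diff` (pp), `p`, `q`,
#'   `direction`; `metadata()` records tested/skipped window counts.
#' @export
callDMR <- function(wt, comparison, minDiffPct = 5, qMax = 0.05,
                    modType = "mCG") {
  stopifnot(is(wt, "WindowTable"), length(comparison) == 2L)
  g <- sampleGroups(wt)
  s1 <- which(g == comparison[1L]); s2 <- which(g == comparison[2L])
  if (length(s1) < 2L || length(s2) < 2L)
    stop("need >= 2 samples per group with count data")
  covM <- assay(wt, "coverage"); modM <- assay(wt, "modified")
  cov1 <- rowSums(covM[, s1, drop = FALSE])
  cov2 <- rowSums(covM[, s2, drop = FALSE])
  mod1 <- rowSums(modM[, s1, drop = FALSE])
  mod2 <- rowSums(modM[, s2, drop = FALSE])
  ok <- cov1 > 0 & cov2 > 0
  nSkipped <- sum(!ok)
  if (nSkipped)
    message(nSkipped, " window(s) skipped: zero group coverage")
  p <- rep(NA_real_, length(ok))
  p[ok] <- binomialLrt(mod1[ok], cov1[ok], mod2[ok], cov2[ok])
  q <- rep(NA_real_, length(ok))
  q[ok] <- manualQ(p[ok])
  mean1 <- mod1 / cov1; mean2 <- mod2 / cov2
  diff <- 100 * (mean1 - mean2)
  sel <- ok & abs(diff) >= minDiffPct & q < qMax
  out <- granges(windowRanges(wt))[sel]
  mcols(out) <- S4Vectors::DataFrame(
    mod_type = rep(modType, sum(sel)),
    comparison = rep(paste(comparison, collapse = "-"), sum(sel)),
    mean1 = mean1[sel], mean2 = mean2[sel], diff = diff[sel],
    p = p[sel], q = q[sel],
    direction = ifelse(diff[sel] > 0, "hyper", "hypo"))
  metadata(out) <- list(tested = sum(ok), skipped = nSkipped,
                        comparison = comparison)
  out
}

## Row-wise two-sample t on a matrix of per-sample values, NA-tolerant.
## varPooling "across_windows" pools the residual variance over all rows
## (one variance for the whole table, df summed over rows);
## "per_window" is the classical per-row pooled-variance Student t.
## Welch (varEqual = FALSE) is only meaningful per window.
rowTTest <- function(x, s1, s2, varEqual = TRUE,
                     varPooling = c("across_windows", "per_window")) {
  varPooling <- match.arg(varPooling)
  x1 <- x[, s1, drop = FALSE]; x2 <- x[, s2, drop = FALSE]
  n1 <- rowSums(!is.na(x1)); n2 <- rowSums(!is.na(x2))
  m1 <- rowMeans(x1, na.rm = TRUE); m2 <- rowMeans(x2, na.rm = TRUE)
  v1 <- apply(x1, 1L, stats::var, na.rm = TRUE)
  v2 <- apply(x2, 1L, stats::var, na.rm = TRUE)
  d <- m1 - m2
  if (!varEqual) {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- se^4 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else if (varPooling == "per_window") {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    ss <- ifelse(n1 > 1, (n1 - 1) * v1, 0) + ifelse(n2 > 1, (n2 - 1) * v2, 0)
    dfw <- pmax(n1 - 1, 0) + pmax(n2 - 1, 0)
    ok <- is.finite(ss) & dfw > 0
    df <- sum(dfw[ok])
    sp2 <- if (df > 0) sum(ss[ok]) / df else NA_real_
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  }
  t <- d / se
  p <- 2 * pt(-abs(t), df)
  ## degenerate rows: zero variance
  zero <- is.finite(d) & !is.na(se) & se == 0
  p[zero & d == 0] <- 1
  p[zero & d != 0] <- 0
  list(diff = d, p = p, n1 = n1, n2 = n2, m1 = m1, m2 = m2)
}

#' Call differentially hydroxymethylated regions (DhMCGR)
#'
#' BS and oxBS window tables are intersected to the windows covered in
#' both; per sample per window the hmC level is the BS level minus the
#' oxBS level. For a two-group comparison a two-sample pooled-variance
#' t test is applied across replicates in every common window. By default
#' the residual variance is a single estimate pooled across all windows
#' (replicate noise on window-level subtraction values is dominated by a
#' shared technical component, and with few replicates per group the
#' per-window variance estimate is too unstable to rank thousands of
#' windows); `varPooling = "per_window"` gives the classical per-window
#' Student t instead. [manualQ()] is computed within the comparison over
#' all tested windows (so the multiplicity burden reflects every window
#' examined, which is what keeps the false discovery rate controlled).
#' Reported records then satisfy `|diff| >= minDiffPct` percentage
#' points, `p <= pMax` and `q <= qMax`.
#'
#' @param bsWt,oxWt [WindowTable]s for the BS and oxBS arms over the same
#'   tile grid and samples.
#' @param comparison character(2): the two group labels, first vs second.
#' @param minDiffPct minimum absolute group difference in percentage points.
#' @param pMax,qMax t-test p and step-up q cutoffs (defaults 0.05).
#' @param varEqual pooled-variance Student t (default); `FALSE` for Welch
#'   (which forces per-window variances).
#' @param varPooling `"across_windows"` (one variance pooled over all
#'   windows; default) or `"per_window"`.
#' @return As [callDMR()], with `mod_type = "hmCG"`.
#' @export
callDhMR <- function(bsWt, oxWt, comparison, minDiffPct = 5, pMax = 0.05,
                     qMax = 0.05, varEqual = TRUE,
                     varPooling = c("across_windows", "per_window")) {
  stopifnot(is(bsWt, "WindowTable"), is(oxWt, "WindowTable"),
            length(comparison) == 2L)
  if (!identical(colnames(bsWt), colnames(oxWt)))
    stop("BS and oxBS window tables must share samples")
  kb <- windowKey(windowRanges(bsWt)); ko <- windowKey(windowRanges(oxWt))
  common <- intersect(kb, ko)
  bs <- windowLevelMatrix(bsWt)[match(common, kb), , drop = FALSE]
  ox <- windowLevelMatrix(oxWt)[match(common, ko), , drop = FALSE]
  h <- bs - ox
  g <- sampleGroups(bsWt)
  s1 <- which(g == comparison[1L]); s2 <- which(g == comparison[2L])
  if (length(s1) < 2L || length(s2) < 2L)
    stop("t-test undefined: need >= 2 replicates per group")
  tt <- rowTTest(h, s1, s2, varEqual = varEqual,
                 varPooling = match.arg(varPooling))
  diff <- 100 * tt$diff
  tested <- is.finite(diff) & tt$n1 >= 2L & tt$n2 >= 2L &
    is.finite(tt$p)
  q <- rep(NA_real_, length(diff))
  if (any(tested)) q[tested] <- manualQ(tt$p[tested])
  sel <- tested & abs(diff) >= minDiffPct & tt$p <= pMax & q <= qMax
  out <- granges(windowRanges(bsWt))[match(common, kb)][sel]
  mcols(out) <- S4Vectors::DataFrame(
    mod_type = rep("hmCG", sum(sel)),
    comparison = rep(paste(comparison, collapse = "-"), sum(sel)),
    mean1 = tt$m1[sel], mean2 = tt$m2[sel], diff = diff[sel],
    p = tt$p[sel], q = q[sel],
    direction = ifelse(diff[sel] > 0, "hyper", "hypo"))
  metadata(out) <- list(common_windows = length(common),
                        tested = sum(tested),
                        comparison = comparison)
  out
}

#' Correlation of differential levels between two modification types
#'
#' Pearson correlation of the group differences of two differential-region
#' sets over their shared windows (e.g. mCG vs hmCG differences, which are
#' expected to be negatively correlated where the two modifications
#' exchange).
#'
#' @param dmrsA,dmrsB records from [callDMR()] / [callDhMR()] sharing a
#'   tile grid.
#' @return A list with `r` (Pearson correlation of the `diff` columns)
#'   and `n` (shared windows); `r` is `NA` with fewer than 3 shared
#'   windows.
#' @export
diffCorrelation <- function(dmrsA, dmrsB) {
  ka <- windowKey(dmrsA); kb <- windowKey(dmrsB)
  common <- intersect(ka, kb)
  if (length(common) < 3L) return(list(r = NA_real_, n = length(common)))
  list(r = stats::cor(mcols(dmrsA)$diff[match(common, ka)],
                      mcols(dmrsB)$diff[match(common, kb)]),
       n = length(common))
}

#' Assemble a WindowTable from matrices
#'
#' Low-level constructor used when window-level counts or levels are
#' already in matrix form (rows parallel to `windows`, columns samples).
#' Provide `coverage` and `modified` (the `level` assay is derived), or
#' `level` directly for level-only workflows such as [callDhMR()].
#'
#' @param windows tile [GenomicRanges::GRanges].
#' @param coverage,modified numeric matrices of pooled per-window counts.
#' @param level numeric matrix of per-window levels (fractions).
#' @param groups character vector of group labels, one per column.
#' @param samples sample names (defaults to the matrix column names).
#' @return A [WindowTable].
#' @export
makeWindowTable <- function(windows, coverage = NULL, modified = NULL,
                            level = NULL, groups, samples = NULL) {
  src <- if (!is.null(coverage)) coverage else level
  if (is.null(src)) stop("provide coverage+modified or level")
  if (is.null(level)) level <- ifelse(coverage > 0, modified / coverage,
                                      NA_real_)
  if (is.null(coverage)) {
    coverage <- matrix(NA_real_, nrow(level), ncol(level))
    modified <- coverage
  }
  if (is.null(samples)) samples <- colnames(src)
  if (is.null(samples)) samples <- paste0("sample", seq_len(ncol(src)))
  dimnames(coverage) <- dimnames(modified) <- dimnames(level) <-
    list(NULL, samples)
  se <- SummarizedExperiment(
    assays = list(coverage = coverage, modified = modified, level = level),
    rowRanges = windows,
    colData = S4Vectors::DataFrame(sample = samples, group = groups,
                                   row.names = samples))
  new("WindowTable", se)
}

#' Three-way overlap of differential-region sets
#'
#' Window-identity-based Venn counts per direction (`hyper`, `hypo`) for
#' three differential-region sets sharing one tile grid.
#'
#' @param dmrsA,dmrsB,dmrsC differential records from [callDMR()] /
#'   [callDhMR()] on the same tile grid.
#' @return A `data.frame` with columns `direction`, `region` (one of
#'   `A`, `B`, `C`, `AB`, `AC`, `BC`, `ABC` for the exclusive Venn areas),
#'   and `count`.
#' @export
dmrOverlap <- function(dmrsA, dmrsB, dmrsC) {
  sets <- list(A = dmrsA, B = dmrsB, C = dmrsC)
  widths <- unique(unlist(lapply(sets, function(g)
    if (length(g)) unique(width(g)) else integer())))
  if (length(widths) > 1L)
    stop("records do not share one tile grid (mixed window widths)")
  out <- list()
  for (dir in c("hyper", "hypo")) {
    keys <- lapply(sets, function(g)
      windowKey(g[mcols(g)$direction == dir]))
    a <- keys$A; b <- keys$B; c <- keys$C
    venn <- c(
      A = length(setdiff(a, union(b, c))),
      B = length(setdiff(b, union(a, c))),
      C = length(setdiff(c, union(a, b))),
      AB = length(setdiff(intersect(a, b), c)),
      AC = length(setdiff(intersect(a, c), b)),
      BC = length(setdiff(intersect(b, c), a)),
      ABC = length(intersect(intersect(a, b), c)))
    out[[dir]] <- data.frame(direction = dir, region = names(venn),
                             count = unname(venn))
  }
  do.call(rbind, out)
}

#' Export differential records as BED6+
#'
#' Writes `chrom start end name score strand diff p q direction` with
#' 0-based half-open coordinates, `name = mod_type:comparison` and
#' `score = -log10(q)` (capped at 1000).
#'
#' @param x records from [callDMR()] / [callDhMR()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeDMRecords <- function(x, path) {
  df <- data.frame(
    chrom = as.character(seqnames(x)),
    start = start(x) - 1L,
    end = end(x),
    name = paste(mcols(x)$mod_type, mcols(x)$comparison, sep = ":"),
    score = pmin(round(-log10(pmax(mcols(x)$q, 1e-300)), 3), 1000),
    strand = rep(".", length(x)),
    diff = mcols(x)$diff,
    p = mcols(x)$p,
    q = mcols(x)$q,
    direction = mcols(x)$direction)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
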