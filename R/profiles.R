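## Metagene modification profiles, expression-tertile stratification,
## region-average statistics, repeat-element summaries, and the targeted
## EM-seq region/per-CpG comparisons.

#' Split genes into expression classes
#'
#' Genes with zero reads in every sample are classified as not expressed;
#' the remaining genes are split into three equally sized tertiles (high,
#' mid, low) by their mean count across samples. When the number of
#' expressed genes is not divisible by three, the extra genes go to the
#' highest tertile first (`n = 10` gives sizes 4/3/3 from high down). Ties
#' at tertile boundaries are broken by stable gene-id order.
#'
#' @param expr numeric matrix of raw counts, genes in rows (rownames are
#'   gene ids), samples in columns.
#' @return A list of character vectors `high`, `mid`, `low`, `unexpressed`.
#' @export
expressionClasses <- function(expr) {
  if (is.null(dim(expr)) || nrow(expr) == 0L)
    stop("empty expression table")
  if (is.null(rownames(expr))) stop("expression table needs gene-id rownames")
  if (any(expr < 0)) stop("counts must be non-negative")
  unexpr <- rownames(expr)[rowSums(expr) == 0]
  keep <- setdiff(rownames(expr), unexpr)
  m <- rowMeans(expr[keep, , drop = FALSE])
  ord <- keep[order(-m, keep, method = "radix")]
  n <- length(ord)
  base <- n %/% 3L; extra <- n %% 3L
  sizes <- base + (seq_len(3L) <= extra)
  cuts <- cumsum(sizes)
  list(high = ord[seq_len(cuts[1L])],
       mid = if (sizes[2L]) ord[(cuts[1L] + 1L):cuts[2L]] else character(),
       low = if (sizes[3L]) ord[(cuts[2L] + 1L):cuts[3L]] else character(),
       unexpressed = unexpr)
}

## 67 bins per gene: 20 x 200 nt upstream, 27 equal body bins, 20 x 200 nt
## downstream; bin 1 is the far upstream end in the gene's 5'->3' frame.
geneBins <- function(gene, flank, flankBins, bodyBins) {
  chr <- as.character(seqnames(gene))
  plus <- as.character(strand(gene)) == "+"
  binW <- flank %/% flankBins
  ## body bin edges are placed symmetrically from the gene's 5' end so a
  ## minus-strand gene partitions as the exact mirror of a plus-strand one
  w <- width(gene)
  offs <- round(w * (0:bodyBins) / bodyBins)
  if (plus) {
    body <- IRanges(start(gene) + offs[-(bodyBins + 1L)],
                    start(gene) + offs[-1L] - 1L)
    up <- IRanges(start(gene) - flank + (seq_len(flankBins) - 1L) * binW,
                  width = binW)
    down <- IRanges(end(gene) + 1L + (seq_len(flankBins) - 1L) * binW,
                    width = binW)
    ir <- c(up, body, down)
  } else {
    body <- IRanges(end(gene) - offs[-1L] + 1L,
                    end(gene) - offs[-(bodyBins + 1L)])
    up <- IRanges(end(gene) + flank - seq_len(flankBins) * binW + 1L,
                  width = binW)
    down <- IRanges(start(gene) - seq_len(flankBins) * binW,
                    width = binW)
    ir <- c(up, body, down)
  }
  GRanges(chr, ir)
}

#' Metagene modification profile
#'
#' Bins a 4 kb upstream flank into `flankBins` bins of equal width, the
#' gene body into `bodyBins` equal-width bins scaled to each gene's own
#' length, and a 4 kb downstream flank likewise; bin order follows the
#' gene's 5'->3' orientation (minus-strand genes are reversed). Per gene
#' and bin the coverage-weighted level of the sites in the bin is taken;
#' per bin the unweighted mean over genes with data is reported, so every
#' gene carries equal weight. Genes with body length below `bodyBins` nt
#' are dropped (their count is recorded as an attribute).
#'
#' @param callsList named list of [SiteCalls], one per sample.
#' @param genes gene models ([geneModels()]) restricted to the gene set of
#'   interest.
#' @param flank flank size in nt (default 4000).
#' @param flankBins number of flank bins (default 20, i.e. 200 nt each).
#' @param bodyBins number of gene-body bins (default 27).
#' @return A `data.frame` in long format: `sample`, `bin` (1..67 by
#'   default), `segment` (`upstream`/`body`/`downstream`), `level`,
#'   `n_genes` (genes contributing to the bin mean).
#' @export
metageneProfile <- function(callsList, genes, flank = 4000L,
                            flankBins = 20L, bodyBins = 27L) {
  if (!length(genes)) stop("empty gene list")
  short <- width(genes) < bodyBins
  nShort <- sum(short)
  genes <- genes[!short]
  if (!length(genes)) stop("no gene body is long enough to bin")
  binsPerGene <- 2L * flankBins + bodyBins
  allBins <- unlist(GRangesList(lapply(seq_along(genes), function(i)
    geneBins(genes[i], flank, flankBins, bodyBins))))
  binIdx <- rep(seq_len(binsPerGene), length(genes))
  segment <- rep(c(rep("upstream", flankBins), rep("body", bodyBins),
                   rep("downstream", flankBins)), length(genes))
  out <- list()
  for (s in names(callsList)) {
    calls <- callsList[[s]]
    hits <- findOverlaps(calls, allBins, ignore.strand = TRUE)
    cov <- rep(0, length(allBins)); mod <- rep(0, length(allBins))
    if (length(hits)) {
      cs <- rowsum(as.numeric(siteCoverage(calls)[queryHits(hits)]),
                   subjectHits(hits))
      ms <- rowsum(as.numeric(modifiedCalls(calls)[queryHits(hits)]),
                   subjectHits(hits))
      i <- as.integer(rownames(cs))
      cov[i] <- cs[, 1L]; mod[i] <- ms[, 1L]
    }
    lev <- ifelse(cov > 0, mod / cov, NA_real_)
    binMean <- tapply(lev, binIdx, mean, na.rm = TRUE)
    nGenes <- tapply(!is.na(lev), binIdx, sum)
    out[[s]] <- data.frame(sample = s,
                           bin = as.integer(names(binMean)),
                           segment = segment[seq_len(binsPerGene)],
                           level = as.numeric(binMean),
                           n_genes = as.integer(nGenes))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "dropped_short_genes") <- nShort
  res
}

#' Per-replicate region averages around genes
#'
#' Coverage-weighted modification level per replicate over the pooled
#' upstream (-`flank`..TSS), gene-body (TSS..TES), and downstream
#' (TES..+`flank`) intervals of a gene list (intervals are merged before
#' pooling so no call is counted twice within a region class).
#'
#' @param callsList named list of [SiteCalls] (replicates).
#' @param genes gene models restricted to the list of interest.
#' @param flank flank size in nt (default 4000).
#' @return A `data.frame`: `sample`, `region`
#'   (`upstream`/`body`/`downstream`), `level`.
#' @export
regionAverages <- function(callsList, genes, flank = 4000L) {
  regs <- list(
    upstream = reduce(upstreamWindow(genes, 1L, flank), ignore.strand = TRUE),
    body = reduce(granges(genes), ignore.strand = TRUE),
    downstream = reduce(upstreamWindow(invertStrand(genes), 1L, flank),
                        ignore.strand = TRUE))
  out <- list()
  for (s in names(callsList)) {
    for (r in names(regs)) {
      lv <- regionLevel(callsList[[s]], regs[[r]])
      cov <- regionCoverage(callsList[[s]], regs[[r]])
      w <- sum(cov, na.rm = TRUE)
      pooled <- if (w > 0) sum(lv * cov, na.rm = TRUE) / w else NA_real_
      out[[length(out) + 1L]] <- data.frame(sample = s, region = r,
                                            level = pooled)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## total call coverage per interval (companion to regionLevel)
regionCoverage <- function(calls, intervals) {
  hits <- findOverlaps(calls, intervals, ignore.strand = TRUE)
  cov <- rep(0, length(intervals))
  if (length(hits)) {
    cs <- rowsum(as.numeric(siteCoverage(calls)[queryHits(hits)]),
                 subjectHits(hits))
    cov[as.integer(rownames(cs))] <- cs[, 1L]
  }
  cov
}

#' Sidak multiple-comparison correction
#'
#' `p_adj = 1 - (1 - p)^m` for `m` contrasts.
#'
#' @param p p-values.
#' @param m number of contrasts (default `length(p)`).
#' @return Adjusted p-values.
#' @export
sidakAdjust <- function(p, m = length(p)) {
  pmin(1 - (1 - p)^m, 1)
}

#' Compare region averages between groups
#'
#' Two designs. `"paired"`: a paired two-tailed t test between two groups
#' (e.g. input vs positive fraction), pairing replicates by order within
#' group, run separately per region. `"multi"`: a two-factor fixed-effects
#' ANOVA (group x region) on the replicate means, with all pairwise group
#' contrasts within each region computed from the pooled residual variance
#' and Sidak-corrected over the number of contrasts.
#'
#' @param df a `data.frame` with columns `sample`, `group`, `region`,
#'   `level` (one row per replicate x region).
#' @param design `"paired"` or `"multi"`.
#' @return For `"paired"`: a `data.frame` `region`, `mean_diff`, `p`.
#'   For `"multi"`: a list with the ANOVA table (`anova`) and a
#'   `data.frame` of Sidak-corrected pairwise contrasts (`contrasts`).
#' @export
compareRegionAverages <- function(df, design = c("paired", "multi")) {
  design <- match.arg(design)
  stopifnot(all(c("group", "region", "level") %in% names(df)))
  df$group <- factor(df$group); df$region <- factor(df$region)
  if (design == "paired") {
    gl <- levels(df$group)
    if (length(gl) != 2L) stop("paired design needs exactly two groups")
    out <- list()
    for (r in levels(df$region)) {
      x <- df$level[df$group == gl[1L] & df$region == r]
      y <- df$level[df$group == gl[2L] & df$region == r]
      if (length(x) != length(y))
        stop("unbalanced pairing in region ", r)
      d <- x - y
      p <- if (all(d == 0)) 1 else t.test(x, y, paired = TRUE)$p.value
      out[[r]] <- data.frame(region = r, mean_diff = mean(d), p = p)
    }
    res <- do.call(rbind, out); rownames(res) <- NULL
    return(res)
  }
  fit <- lm(level ~ group * region, data = df)
  av <- anova(fit)
  mse <- av["Residuals", "Mean Sq"]
  dfr <- av["Residuals", "Df"]
  gl <- levels(df$group); rl <- levels(df$region)
  rows <- list()
  for (r in rl) {
    for (i in seq_len(length(gl) - 1L)) for (j in (i + 1L):length(gl)) {
      xi <- df$level[df$group == gl[i] & df$region == r]
      xj <- df$level[df$group == gl[j] & df$region == r]
      d <- mean(xi) - mean(xj)
      se <- sqrt(mse * (1 / length(xi) + 1 / length(xj)))
      p <- 2 * pt(-abs(d / se), dfr)
      rows[[length(rows) + 1L]] <- data.frame(
        region = r, contrast = paste(gl[i], gl[j], sep = " vs "),
        diff = d, p = p)
    }
  }
  ct <- do.call(rbind, rows)
  ct$p_sidak <- sidakAdjust(ct$p, m = nrow(ct))
  list(anova = av, contrasts = ct)
}

#' Repeat-element modification summary
#'
#' Coverage-weighted levels per sample for the whole genome, repeat-masked
#' vs non-repeat partitions (a site is a repeat site if it overlaps any
#' repeat interval), and each repeat class. Unknown class labels are
#' grouped as `"Other"` with a warning. The repeat/non-repeat site sets
#' partition all sites by construction.
#'
#' @param callsList named list of [SiteCalls], one per sample.
#' @param repeats [GenomicRanges::GRanges] of repeat intervals with a
#'   metadata column `class` (or `name`) holding the repeat class
#'   (`LINE`, `SINE`, `LTR`, `Simple_repeat`).
#' @param classes repeat classes to summarize.
#' @return A `data.frame`: `sample`, `category` (whole_genome, repeat,
#'   non_repeat, then classes), `level`.
#' @export
repeatSummary <- function(callsList, repeats,
                          classes = c("LINE", "SINE", "LTR",
                                      "Simple_repeat")) {
  cls <- mcols(repeats)$class
  if (is.null(cls)) cls <- mcols(repeats)$name
  if (is.null(cls)) cls <- rep(NA_character_, length(repeats))
  cls <- as.character(cls)
  unknown <- !is.na(cls) & !cls %in% classes
  if (any(unknown)) {
    warning("unknown repeat classes grouped as 'Other': ",
            paste(unique(cls[unknown]), collapse = ", "))
    cls[unknown] <- "Other"
  }
  catLevels <- c("whole_genome", "repeat", "non_repeat", classes,
                 if (any(cls == "Other", na.rm = TRUE)) "Other")
  out <- list()
  for (s in names(callsList)) {
    calls <- callsList[[s]]
    inRep <- overlapsAny(calls, repeats, ignore.strand = TRUE)
    lv <- function(sel) {
      tot <- sum(as.numeric(siteCoverage(calls)[sel]))
      if (tot == 0) NA_real_
      else sum(as.numeric(modifiedCalls(calls)[sel])) / tot
    }
    vals <- c(whole_genome = lv(rep(TRUE, length(calls))),
              "repeat" = if (length(repeats)) lv(inRep) else NA_real_,
              non_repeat = lv(!inRep))
    for (cl in setdiff(catLevels, names(vals))) {
      sel <- overlapsAny(calls, repeats[!is.na(cls) & cls == cl],
                         ignore.strand = TRUE)
      vals[cl] <- lv(sel)
    }
    out[[s]] <- data.frame(sample = s, category = names(vals),
                           level = unname(vals))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$category <- factor(res$category, levels = catLevels)
  res
}

#' Targeted EM-seq region and per-CpG comparisons
#'
#' For one targeted region assayed in two cell types: the region mean per
#' replicate is compared with a two-tailed unpaired t test, and individual
#' CpG positions are contrasted from a position x cell-type fixed-effects
#' ANOVA using the single pooled residual variance, Sidak-corrected over
#' positions. Positions must be common to all replicates; with fewer than
#' two common positions the per-CpG test is skipped with a note.
#'
#' @param levels1,levels2 numeric matrices (positions x replicates) of
#'   per-CpG levels for the two cell types, with common position rownames.
#' @param varEqual pooled-variance region t test (default `TRUE`).
#' @return A list: `region` (`data.frame` with means and `p`) and
#'   `per_cpg` (`data.frame` with per-position `diff`, `p`, `p_sidak`, or
#'   `NULL` with a message when skipped).
#' @export
emseqRegionTests <- function(levels1, levels2, varEqual = TRUE) {
  stopifnot(is.matrix(levels1), is.matrix(levels2))
  common <- intersect(rownames(levels1), rownames(levels2))
  n1 <- ncol(levels1); n2 <- ncol(levels2)
  if (n1 < 2L || n2 < 2L) stop("need >= 2 replicates per cell type")
  r1 <- colMeans(levels1); r2 <- colMeans(levels2)
  pReg <- if (isTRUE(all.equal(unname(r1), unname(r2))) &&
              stats::var(r1) == 0) 1
          else t.test(r1, r2, var.equal = varEqual)$p.value
  region <- data.frame(mean1 = mean(r1), mean2 = mean(r2),
                       diff = mean(r1) - mean(r2), p = pReg)
  if (length(common) < 2L) {
    message("fewer than two common CpG positions: per-CpG test skipped")
    return(list(region = region, per_cpg = NULL))
  }
  x1 <- levels1[common, , drop = FALSE]
  x2 <- levels2[common, , drop = FALSE]
  long <- data.frame(
    level = c(as.vector(x1), as.vector(x2)),
    pos = factor(c(rep(common, n1), rep(common, n2)), levels = common),
    cell = factor(c(rep("g1", length(x1)), rep("g2", length(x2)))))
  fit <- lm(level ~ pos * cell, data = long)
  av <- suppressWarnings(anova(fit))  # zero-residual fits are handled below
  mse <- av["Residuals", "Mean Sq"]; dfr <- av["Residuals", "Df"]
  d <- rowMeans(x1) - rowMeans(x2)
  se <- sqrt(mse * (1 / n1 + 1 / n2))
  p <- if (se == 0) ifelse(d == 0, 1, 0) else 2 * pt(-abs(d / se), dfr)
  perCpg <- data.frame(pos = common, diff = unname(d), p = unname(p),
                       p_sidak = sidakAdjust(unname(p), m = length(common)))
  list(region = region, per_cpg = perCpg)
}
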