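## Genic-feature assignment of regions (midpoint, fixed priority) and
## log-odds over/under-representation with Woolf confidence intervals and
## Fisher's exact test.

#' Fixed genic feature vocabulary
#'
#' The eleven feature labels used for region annotation and enrichment,
#' in reporting order.
#' @export
genicFeatureLabels <- c("Promoter (2-3kb)", "Promoter (1-2kb)",
                        "Promoter (<=1kb)", "5' UTR", "1st Exon",
                        "1st Intron", "Other Exon", "Other Intron",
                        "3' UTR", "Downstream (<=300bp)",
                        "Distal Intergenic")

#' Construct gene models
#'
#' A gene-model set is a [GenomicRanges::GRanges] of gene spans (strand
#' required) with metadata columns `gene_id`, optionally `exons`
#' (a [GenomicRanges::GRangesList] of absolute exon coordinates, one
#' element per gene) and `cds` (an [IRanges::IRanges] of the coding span,
#' zero-width for non-coding genes). Genes without exon structure are
#' treated as single-exon.
#'
#' @param genes gene spans (GRanges with strand).
#' @param gene_id character vector of ids.
#' @param exons optional GRangesList of exons per gene.
#' @param cds optional IRanges of coding spans per gene.
#' @return The annotated GRanges.
#' @export
geneModels <- function(genes, gene_id, exons = NULL, cds = NULL) {
  stopifnot(is(genes, "GRanges"), length(gene_id) == length(genes))
  if (any(as.character(strand(genes)) == "*"))
    stop("gene models require an explicit strand")
  mcols(genes)$gene_id <- as.character(gene_id)
  if (!is.null(exons)) mcols(genes)$exons <- exons
  if (!is.null(cds)) mcols(genes)$cds <- cds
  genes
}

#' Read gene models from BED12
#'
#' Exon blocks come from the BED12 block fields and the coding span from
#' thickStart/thickEnd.
#'
#' @param path a BED12 file.
#' @return Gene models as from [geneModels()].
#' @export
readGeneModels <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  exons <- if ("blocks" %in% colnames(mcols(gr))) {
    bl <- rtracklayer::blocks(gr)
    names(bl) <- NULL
    bl
  } else NULL
  cds <- if ("thick" %in% colnames(mcols(gr))) mcols(gr)$thick else NULL
  ids <- if ("name" %in% colnames(mcols(gr))) mcols(gr)$name
         else paste0("gene", seq_along(gr))
  out <- granges(gr)
  geneModels(out, ids, exons = exons, cds = cds)
}

geneExons <- function(genes) {
  if ("exons" %in% colnames(mcols(genes)) &&
      !is.null(mcols(genes)$exons))
    mcols(genes)$exons
  else methods::as(granges(genes), "GRangesList")
}

## Strand-aware upstream window [d1, d2] bp upstream of the TSS.
upstreamWindow <- function(genes, d1, d2) {
  plus <- as.character(strand(genes)) == "+"
  tss <- ifelse(plus, start(genes), end(genes))
  st <- ifelse(plus, tss - d2, tss + d1)
  en <- ifelse(plus, tss - d1, tss + d2)
  gr <- GRanges(seqnames(genes), IRanges(pmax(st, 1L), pmax(en, 1L)))
  mcols(gr)$tss <- tss
  gr
}

## Per-gene ordered exon/intron decomposition, strand-aware ordering.
genicPieces <- function(genes) {
  exl <- geneExons(genes)
  n <- length(genes)
  firstExon <- otherExon <- firstIntron <- otherIntron <- GRangesList()
  fe <- vector("list", n); oe <- vector("list", n)
  fi <- vector("list", n); oi <- vector("list", n)
  empty <- GRanges()
  for (i in seq_len(n)) {
    ex <- reduce(exl[[i]])
    plus <- as.character(strand(genes))[i] == "+"
    ord <- order(start(ex), decreasing = !plus)
    ex <- ex[ord]
    fe[[i]] <- granges(ex[1L])
    oe[[i]] <- if (length(ex) > 1L) granges(ex[-1L]) else empty
    intr <- setdiff(granges(genes[i]), ex, ignore.strand = TRUE)
    if (length(intr)) {
      ordI <- order(start(intr), decreasing = !plus)
      intr <- intr[ordI]
      fi[[i]] <- granges(intr[1L])
      oi[[i]] <- if (length(intr) > 1L) granges(intr[-1L]) else empty
    } else {
      fi[[i]] <- empty; oi[[i]] <- empty
    }
  }
  cat1 <- function(l) if (length(l)) unlist(methods::as(l, "GRangesList"))
                      else GRanges()
  list(firstExon = cat1(fe), otherExon = cat1(oe),
       firstIntron = cat1(fi), otherIntron = cat1(oi))
}

## UTRs: exonic sequence outside the coding span, strand-aware 5'/3'.
utrPieces <- function(genes) {
  empty <- GRanges()
  if (!"cds" %in% colnames(mcols(genes)) || is.null(mcols(genes)$cds))
    return(list(utr5 = empty, utr3 = empty))
  cds <- mcols(genes)$cds
  exl <- geneExons(genes)
  u5 <- vector("list", length(genes)); u3 <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    u5[[i]] <- empty; u3[[i]] <- empty
    if (width(cds)[i] <= 0) next
    ex <- reduce(granges(exl[[i]]))
    chr <- as.character(seqnames(genes))[i]
    plus <- as.character(strand(genes))[i] == "+"
    before <- GRanges(chr, IRanges(start(genes)[i],
                                   max(start(genes)[i], start(cds)[i] - 1L)))
    after <- GRanges(chr, IRanges(min(end(genes)[i], end(cds)[i] + 1L),
                                  end(genes)[i]))
    if (start(cds)[i] > start(genes)[i]) {
      seg <- intersect(ex, before, ignore.strand = TRUE)
      if (plus) u5[[i]] <- seg else u3[[i]] <- seg
    }
    if (end(cds)[i] < end(genes)[i]) {
      seg <- intersect(ex, after, ignore.strand = TRUE)
      if (plus) u3[[i]] <- seg else u5[[i]] <- seg
    }
  }
  cat1 <- function(l) if (length(l)) unlist(methods::as(l, "GRangesList"))
                      else GRanges()
  list(utr5 = cat1(u5), utr3 = cat1(u3))
}

#' Assign regions to genic features
#'
#' Each region is assigned one label from [genicFeatureLabels] using its
#' midpoint (or any-overlap with `mode = "any"`, where the highest-priority
#' overlapping feature wins). Priority: promoter tiers (tier chosen by the
#' nearest TSS among genes whose upstream 3 kb window contains the point) >
#' 5' UTR > 3' UTR > 1st exon > other exon > 1st intron > other intron >
#' downstream (<= 300 bp past the TES) > distal intergenic. Promoter tiers
#' are measured upstream of the TSS in strand orientation.
#'
#' @param regions [GenomicRanges::GRanges] to annotate.
#' @param genes gene models from [geneModels()].
#' @param mode `"midpoint"` (default) or `"any"`.
#' @return A factor parallel to `regions` with levels
#'   [genicFeatureLabels].
#' @export
annotateRegion <- function(regions, genes, mode = c("midpoint", "any")) {
  mode <- match.arg(mode)
  stopifnot(is(regions, "GRanges"))
  query <- if (mode == "midpoint") {
    midp <- floor((start(regions) + end(regions)) / 2)
    GRanges(seqnames(regions), IRanges(midp, width = 1L))
  } else granges(regions)
  n <- length(query)
  lab <- rep(NA_character_, n)
  ## promoter tiers via nearest TSS among genes whose 3 kb upstream window
  ## contains the query point
  prom <- upstreamWindow(genes, 1L, 3000L)
  hits <- findOverlaps(query, prom, ignore.strand = TRUE)
  if (length(hits)) {
    plus <- as.character(strand(genes))[subjectHits(hits)] == "+"
    qpos <- if (mode == "midpoint") start(query)[queryHits(hits)] else NA
    ## for any-overlap, measure from the region edge nearest the TSS
    if (mode == "any") {
      tssP <- mcols(prom)$tss[subjectHits(hits)]
      qpos <- pmin(pmax(tssP, start(query)[queryHits(hits)]),
                   end(query)[queryHits(hits)])
    }
    tss <- mcols(prom)$tss[subjectHits(hits)]
    d <- ifelse(plus, tss - qpos, qpos - tss)
    d <- pmax(d, 1L)
    dmin <- tapply(d, queryHits(hits), min)
    qi <- as.integer(names(dmin))
    tier <- pmin(ceiling(dmin / 1000), 3)
    lab[qi] <- c("Promoter (<=1kb)", "Promoter (1-2kb)",
                 "Promoter (2-3kb)")[tier]
  }
  pieces <- genicPieces(genes)
  utrs <- utrPieces(genes)
  featOrder <- list(`5' UTR` = utrs$utr5,
                    `3' UTR` = utrs$utr3,
                    `1st Exon` = pieces$firstExon,
                    `Other Exon` = pieces$otherExon,
                    `1st Intron` = pieces$firstIntron,
                    `Other Intron` = pieces$otherIntron,
                    `Downstream (<=300bp)` = upstreamWindow(
                      invertStrand(genes), 1L, 300L))
  for (nmf in names(featOrder)) {
    todo <- which(is.na(lab))
    if (!length(todo)) break
    ov <- overlapsAny(query[todo], featOrder[[nmf]], ignore.strand = TRUE)
    lab[todo[ov]] <- nmf
  }
  lab[is.na(lab)] <- "Distal Intergenic"
  factor(lab, levels = genicFeatureLabels)
}

#' Log-odds feature enrichment with Woolf CIs and Fisher's exact test
#'
#' For each genic feature, counts `a` (comparison regions in the feature),
#' `b` (comparison regions outside), `c` (background in), `d` (background
#' out) are tabulated and the log odds ratio
#' `ln((a * d) / (c * b))` computed. When any cell is zero a
#' Haldane-Anscombe 0.5 is added to every cell before the estimate and CI
#' -- except when `a = 0`, which is reported as status `"n.d."` with no
#' estimate. The 95% CI is the Woolf logit interval,
#' `log_odds +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d)` on the (possibly
#' corrected) cells; the two-sided p is Fisher's exact test on the
#' uncorrected table.
#'
#' @param regions comparison region set ([GenomicRanges::GRanges]).
#' @param background background region set (all detected windows).
#' @param genes gene models from [geneModels()].
#' @param mode annotation mode, see [annotateRegion()].
#' @return A `data.frame` with one row per feature: `feature`, `a`, `b`,
#'   `c`, `d`, `log_odds`, `ci_low`, `ci_high`, `p`, `status`. The
#'   fraction of comparison regions present in the background is attached
#'   as attribute `"in_background"`.
#' @export
logOddsEnrichment <- function(regions, background, genes,
                              mode = c("midpoint", "any")) {
  mode <- match.arg(mode)
  if (!length(background)) stop("empty background region set")
  annR <- annotateRegion(regions, genes, mode = mode)
  annB <- annotateRegion(background, genes, mode = mode)
  tabR <- table(annR); tabB <- table(annB)
  nR <- length(regions); nB <- length(background)
  out <- data.frame(feature = genicFeatureLabels,
                    a = as.integer(tabR[genicFeatureLabels]),
                    c = as.integer(tabB[genicFeatureLabels]))
  out$b <- nR - out$a
  out$d <- nB - out$c
  out$log_odds <- out$ci_low <- out$ci_high <- out$p <- NA_real_
  out$status <- ifelse(out$a == 0L, "n.d.", "ok")
  for (i in seq_len(nrow(out))) {
    if (out$status[i] == "n.d.") next
    a <- out$a[i]; b <- out$b[i]; cc <- out$c[i]; d <- out$d[i]
    if (min(b, cc, d) == 0L) { a <- a + 0.5; b <- b + 0.5
                               cc <- cc + 0.5; d <- d + 0.5 }
    lo <- log((a * d) / (cc * b))
    hw <- 1.96 * sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
    out$log_odds[i] <- lo
    out$ci_low[i] <- lo - hw
    out$ci_high[i] <- lo + hw
    out$p[i] <- fisher.test(matrix(c(out$a[i], out$b[i], out$c[i],
                                     out$d[i]), 2L))$p.value
  }
  out <- out[, c("feature", "a", "b", "c", "d", "log_odds", "ci_low",
                 "ci_high", "p", "status")]
  key <- function(g) paste0(seqnames(g), ":", start(g), "-", end(g))
  attr(out, "in_background") <-
    if (nR) mean(key(regions) %in% key(background)) else NA_real_
  out
}
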