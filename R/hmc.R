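## Resolving mC and hmC from paired assay arms (BS/oxBS subtraction and
## EM-seq TET+/TET- arithmetic), region-level aggregation, and binomial
## subsampling of call tables.

## Shared kernel for two-arm arithmetic. 'total' is the arm reading
## mC + hmC (BS or TET+); 'partial' reads one state only: mC for oxBS,
## hmC for TET-. The derived state is total - partial.
pairedArmLevels <- function(total, partial, minCov, clamp,
                            partialState = c("mC", "hmC")) {
  stopifnot(is(total, "SiteCalls"), is(partial, "SiteCalls"))
  partialState <- match.arg(partialState)
  if (modContext(total) != modContext(partial))
    stop("context mismatch between arms: ", modContext(total), " vs ",
         modContext(partial))
  keyT <- paste0(seqnames(total), ":", start(total), strand(total))
  keyP <- paste0(seqnames(partial), ":", start(partial), strand(partial))
  idx <- match(keyT, keyP)
  shared <- !is.na(idx)
  nDroppedUnpaired <- (length(total) - sum(shared)) +
    (length(partial) - sum(shared))
  tot <- total[shared]
  par <- partial[idx[shared]]
  covOK <- siteCoverage(tot) >= minCov & siteCoverage(par) >= minCov
  nDroppedLowCov <- sum(!covOK)
  tot <- tot[covOK]; par <- par[covOK]
  lvT <- modLevels(tot); lvP <- modLevels(par)
  rawDerived <- lvT - lvP
  derived <- if (clamp) pmax(rawDerived, 0) else rawDerived
  out <- granges(tot)
  if (partialState == "mC") {
    mcols(out)$f_mC <- lvP
    mcols(out)$f_hmC <- derived
  } else {
    mcols(out)$f_hmC <- lvP
    mcols(out)$f_mC <- derived
  }
  mcols(out)$raw_derived <- rawDerived
  mcols(out)$coverage_total <- siteCoverage(tot)
  mcols(out)$coverage_partial <- siteCoverage(par)
  metadata(out) <- list(context = modContext(total),
                        dropped_unpaired = nDroppedUnpaired,
                        dropped_low_coverage = nDroppedLowCov,
                        level_total = if (length(tot))
                          genomeLevel(tot) else NA_real_,
                        level_partial = if (length(par))
                          genomeLevel(par) else NA_real_)
  out
}

#' Per-site mC/hmC by BS minus oxBS subtraction
#'
#' For every site covered at `minCov` or more in both arms, `f_mC` is the
#' oxBS level (oxidation converts hmC, so only mC reads modified) and
#' `f_hmC` is the BS level minus the oxBS level. Sites covered in only one
#' arm are dropped and counted in the result's metadata. With
#' `clamp = TRUE` (default), negative subtraction values are set to 0 for
#' reporting while the raw value is retained in the `raw_derived` column;
#' genome-wide hmC should be taken from [genomeHmcLevel()], which
#' subtracts aggregate arm levels and so lets negative site noise cancel.
#'
#' @param bs,oxbs [SiteCalls] for the BS and oxBS arms (same context).
#' @param minCov minimum per-arm coverage for a site to be retained.
#' @param clamp clamp negative `f_hmC` to zero (raw value kept alongside).
#' @return A [GenomicRanges::GRanges] with columns `f_mC`, `f_hmC`,
#'   `raw_derived`, `coverage_total`, `coverage_partial`; drop counts and
#'   aggregate arm levels in `metadata()`.
#' @export
subtractOxBS <- function(bs, oxbs, minCov = 1L, clamp = TRUE) {
  pairedArmLevels(bs, oxbs, minCov = minCov, clamp = clamp,
                  partialState = "mC")
}

#' Per-site mC/hmC from EM-seq TET+/TET- arms
#'
#' In enzymatic methyl sequencing the TET2-converted (TET+) arm reads total
#' modification (mC + hmC) while the mock (TET-) arm reads hmC only, so
#' `f_hmC` is the TET- level and `f_mC` the TET+ minus TET- level. Sites
#' below `minCov` (default 10, strand-specific) in either arm are dropped.
#'
#' @param tetPlus,tetMinus [SiteCalls] for the TET+ and TET- arms.
#' @param minCov minimum strand-specific coverage (default 10).
#' @param clamp clamp negative `f_mC` to zero.
#' @return As [subtractOxBS()].
#' @export
emseqLevels <- function(tetPlus, tetMinus, minCov = 10L, clamp = TRUE) {
  pairedArmLevels(tetPlus, tetMinus, minCov = minCov, clamp = clamp,
                  partialState = "hmC")
}

#' Genome-wide hmC by aggregate subtraction
#'
#' Genome-wide hmC level computed as the difference of the two arms'
#' coverage-weighted genome-wide levels (total arm minus partial arm),
#' i.e. without per-site clamping, so negative site-level noise cancels in
#' the aggregate rather than biasing the estimate upward.
#'
#' @param total,partial [SiteCalls] for the total-modification arm (BS or
#'   TET+) and the partial arm (oxBS or TET-).
#' @return A (possibly negative) fraction.
#' @export
genomeHmcLevel <- function(total, partial) {
  genomeLevel(total) - genomeLevel(partial)
}

#' Coverage-weighted level per interval
#'
#' Pools counts of the sites falling in each half-open interval and returns
#' the coverage-weighted level per interval; intervals containing no
#' covered site get `NA`.
#'
#' @param calls a [SiteCalls] object.
#' @param intervals a [GenomicRanges::GRanges] of non-overlapping query
#'   intervals.
#' @return Numeric vector parallel to `intervals` (fractions or `NA`).
#' @export
regionLevel <- function(calls, intervals) {
  stopifnot(is(calls, "SiteCalls"), is(intervals, "GRanges"))
  hits <- findOverlaps(calls, intervals, ignore.strand = TRUE)
  cov <- rep(0, length(intervals)); mod <- rep(0, length(intervals))
  if (length(hits)) {
    cs <- rowsum(as.numeric(siteCoverage(calls)[queryHits(hits)]),
                 subjectHits(hits))
    ms <- rowsum(as.numeric(modifiedCalls(calls)[queryHits(hits)]),
                 subjectHits(hits))
    i <- as.integer(rownames(cs))
    cov[i] <- cs[, 1L]; mod[i] <- ms[, 1L]
  }
  ifelse(cov > 0, mod / cov, NA_real_)
}

#' Binomial thinning of a call table
#'
#' Retains each read-call independently with probability `fraction`:
#' per site, modified and unmodified calls are thinned with independent
#' binomial draws and the site's coverage recomputed. Sites whose retained
#' coverage is zero are dropped (as in real low-coverage call tables).
#' Deterministic under `seed`. Thinning preserves the expected genome-wide
#' level, which is what makes very low genome-coverage estimates unbiased.
#'
#' @param calls a [SiteCalls] object.
#' @param fraction retention probability in `(0, 1]`.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return A thinned [SiteCalls] object.
#' @export
subsampleCalls <- function(calls, fraction, seed = NULL) {
  stopifnot(is(calls, "SiteCalls"))
  if (!is.finite(fraction) || fraction <= 0 || fraction > 1)
    stop("fraction must lie in (0, 1]")
  if (fraction == 1) return(calls)
  if (!is.null(seed)) set.seed(seed)
  mod <- modifiedCalls(calls)
  unmod <- siteCoverage(calls) - mod
  mod2 <- rbinom(length(mod), mod, fraction)
  unmod2 <- rbinom(length(unmod), unmod, fraction)
  cov2 <- mod2 + unmod2
  keep <- cov2 > 0L
  gr <- granges(calls)[keep]
  SiteCalls(as.character(seqnames(gr)), start(gr),
            as.character(strand(gr)), cov2[keep], mod2[keep],
            context = modContext(calls), seqlengths = seqlengths(calls))
}
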