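## Reading/writing per-site call tables, genome-wide levels, and spike-in
## based conversion-efficiency estimation and correction.

#' Read a per-site modification call table
#'
#' Reads a methylKit-dialect tab-separated call table into a [SiteCalls]
#' object. Two layouts are accepted, detected from the header line:
#' the frequency layout (`chrBase chr base strand coverage freqC freqT`,
#' with `freqC` the percent-modified in `[0, 100]`) and a counts layout
#' (`chr base strand coverage modified`). With the frequency layout the
#' modified count is reconstructed as `round(coverage * freqC / 100)`
#' (ties round half up). Strand may be encoded `+`/`-` or methylKit-style
#' `F`/`R`. Rows are sorted and exact duplicates collapsed; a duplicated
#' key with conflicting values is an error.
#'
#' @param path path to the text file.
#' @param context `"CG"` or `"CH"`; recorded on the returned object.
#' @param destrand if `TRUE` (CG context only), the two strands of each CpG
#'   dyad are merged into one plus-strand record (minus-strand positions are
#'   mapped to `pos - 1` and counts summed).
#' @return A [SiteCalls] object (possibly empty).
#' @seealso [writeSiteCalls()]
#' @export
readSiteCalls <- function(path, context = c("CG", "CH"), destrand = FALSE) {
  context <- match.arg(context)
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = 1:2), fill = TRUE,
                          showProgress = FALSE)
  freqLayout <- all(c("coverage", "freqC") %in% names(dt))
  countLayout <- all(c("coverage", "modified") %in% names(dt))
  if (!freqLayout && !countLayout)
    stop("unrecognized call-table header in ", path,
         ": need columns coverage+freqC or coverage+modified")
  if (nrow(dt) == 0L)
    return(SiteCalls(character(), integer(), character(), integer(),
                     integer(), context = context))
  need <- if (freqLayout) c("chr", "base", "strand", "coverage", "freqC")
          else c("chr", "base", "strand", "coverage", "modified")
  for (col in setdiff(need, c("chr", "strand"))) {
    v <- suppressWarnings(as.numeric(dt[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop("parse error in ", path, " line ", bad[1L] + 1L,
           ": non-numeric value in column '", col, "'")
    dt[[col]] <- v
  }
  strand <- as.character(dt$strand)
  strand[strand == "F"] <- "+"
  strand[strand == "R"] <- "-"
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad))
    stop("parse error in ", path, " line ", bad[1L] + 1L,
         ": invalid strand '", dt$strand[bad[1L]], "'")
  if (freqLayout) {
    bad <- which(dt$freqC < 0 | dt$freqC > 100)
    if (length(bad))
      stop("validation error in ", path, " line ", bad[1L] + 1L,
           ": freqC outside [0, 100]")
    ## round half up, per the count-reconstruction convention
    modified <- floor(dt$coverage * dt$freqC / 100 + 0.5)
  } else {
    modified <- dt$modified
  }
  sc <- SiteCalls(dt$chr, dt$base, strand, dt$coverage, modified,
                  context = context)
  if (destrand) destrandCpG(sc) else sc
}

#' Write a per-site call table
#'
#' Writes a [SiteCalls] object in the methylKit-dialect frequency layout
#' (`chrBase chr base strand coverage freqC freqT`). `freqC` is the percent
#' modified; `freqT` its complement.
#'
#' @param x a [SiteCalls] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSiteCalls <- function(x, path) {
  stopifnot(is(x, "SiteCalls"))
  cov <- siteCoverage(x)
  freqC <- ifelse(cov > 0L, 100 * modifiedCalls(x) / cov, 0)
  dt <- data.table::data.table(
    chrBase = paste(as.character(seqnames(x)), start(x), sep = "."),
    chr = as.character(seqnames(x)),
    base = start(x),
    strand = as.character(strand(x)),
    coverage = cov,
    freqC = freqC,
    freqT = 100 - freqC)
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Merge CpG dyad strands
#'
#' Collapses plus- and minus-strand records of the same CpG dyad into one
#' plus-strand record at the C of the plus strand (minus-strand positions
#' are mapped to `pos - 1`); coverage and modified counts are summed.
#'
#' @param x a CG-context [SiteCalls] object.
#' @return A destranded [SiteCalls] object, all records on `+`.
#' @export
destrandCpG <- function(x) {
  stopifnot(is(x, "SiteCalls"))
  if (modContext(x) != "CG")
    stop("destranding is defined for CG context only")
  if (!length(x)) return(x)
  pos <- ifelse(as.character(strand(x)) == "-", start(x) - 1L, start(x))
  key <- paste0(as.character(seqnames(x)), ":", pos)
  cov <- rowsum(siteCoverage(x), key, reorder = FALSE)
  mod <- rowsum(modifiedCalls(x), key, reorder = FALSE)
  first <- !duplicated(key)
  SiteCalls(as.character(seqnames(x))[first], pos[first], "+",
            cov[match(key[first], rownames(cov)), 1L],
            mod[match(key[first], rownames(mod)), 1L],
            context = "CG",
            seqlengths = seqlengths(x))
}

#' Genome-wide modification level
#'
#' The coverage-weighted genome-wide level `sum(modified) / sum(coverage)`
#' (the default, matching per-site call percentages pooled over all calls),
#' or optionally the unweighted mean of per-site fractions.
#'
#' @param x a [SiteCalls] object.
#' @param method `"coverage"` (weighted; default) or `"mean"` (per-site
#'   mean).
#' @return A fraction in `[0, 1]`.
#' @examples
#' sc <- SiteCalls("chr1", c(1L, 5L), "+", c(10L, 10L), c(5L, 10L), "CG")
#' genomeLevel(sc)  # 0.75
#' @export
genomeLevel <- function(x, method = c("coverage", "mean")) {
  stopifnot(is(x, "SiteCalls"))
  method <- match.arg(method)
  if (!length(x)) stop("empty SiteCalls table: level undefined")
  if (method == "mean") {
    lv <- modLevels(x)
    return(mean(lv[!is.na(lv)]))
  }
  tot <- sum(as.numeric(siteCoverage(x)))
  if (tot == 0) stop("zero total coverage: level undefined")
  sum(as.numeric(modifiedCalls(x))) / tot
}

#' Estimate conversion chemistry from spike-in controls
#'
#' Given spike-in calls and the known true state (`C`, `mC`, `hmC`) of every
#' spike-in position, estimates per-state apparent-modification
#' probabilities as pooled `sum(modified) / sum(coverage)` over the
#' positions of each state.
#'
#' @param spikeCalls [SiteCalls] restricted to spike-in contigs.
#' @param truth a [GenomicRanges::GRanges] of spike-in positions with a
#'   metadata column `true_state` in `{"C", "mC", "hmC"}`.
#' @param arm arm label stored on the result (e.g. `"BS"`, `"oxBS"`).
#' @return A [ConversionRates] object.
#' @export
estimateConversionRates <- function(spikeCalls, truth, arm) {
  stopifnot(is(spikeCalls, "SiteCalls"), is(truth, "GRanges"))
  st <- as.character(mcols(truth)$true_state)
  if (is.null(st) || !all(st %in% c("C", "mC", "hmC")))
    stop("truth must carry a true_state column in {C, mC, hmC}")
  keyC <- paste0(seqnames(spikeCalls), ":", start(spikeCalls),
                 strand(spikeCalls))
  keyT <- paste0(seqnames(truth), ":", start(truth), strand(truth))
  idx <- match(keyC, keyT)
  if (all(is.na(idx))) stop("no spike-in calls overlap the truth positions")
  est <- function(state) {
    sel <- !is.na(idx) & st[idx] == state
    tot <- sum(as.numeric(siteCoverage(spikeCalls)[sel]))
    if (tot == 0)
      stop("spike-in class '", state, "' absent or uncovered; cannot ",
           "estimate its conversion rate")
    sum(as.numeric(modifiedCalls(spikeCalls)[sel])) / tot
  }
  ConversionRates(arm, aC = est("C"), amC = est("mC"), ahmC = est("hmC"))
}

#' Conversion-efficiency correction of paired BS/oxBS levels
#'
#' Inverts the two-arm linear forward model of the three-state chemistry.
#' Writing `m = f_mC`, `h = f_hmC` and `a_X^arm` for the apparent
#' modification probability of state `X` under each arm, the observed
#' levels are
#' \deqn{bs = (1-m-h) a_C^{BS} + m\,a_{mC}^{BS} + h\,a_{hmC}^{BS}}
#' \deqn{ox = (1-m-h) a_C^{ox} + m\,a_{mC}^{ox} + h\,a_{hmC}^{ox}}
#' and the 2x2 linear system is solved for `(m, h)`. With identity
#' chemistry (`a_C = 0`, `a_mC = 1`, `a_hmC^{BS} = 1`, `a_hmC^{ox} = 0`)
#' this reduces to the naive subtraction `m = ox`, `h = bs - ox`. Solutions
#' are clamped to the probability simplex and a `clamped` flag reports
#' whether clamping occurred; raw (unclamped) solutions are retained.
#'
#' @param bsLevel,oxbsLevel observed fractions in `[0, 1]` (vectorized).
#' @param ratesBS,ratesOxBS [ConversionRates] for the two arms.
#' @return A `data.frame` with columns `f_C`, `f_mC`, `f_hmC`, `clamped`,
#'   `raw_f_mC`, `raw_f_hmC`.
#' @examples
#' correctLevels(0.8, 0.6,
#'               ConversionRates("BS", 0, 1, 1),
#'               ConversionRates("oxBS", 0, 1, 0))  # f_mC 0.6, f_hmC 0.2
#' @export
correctLevels <- function(bsLevel, oxbsLevel, ratesBS, ratesOxBS) {
  stopifnot(is(ratesBS, "ConversionRates"), is(ratesOxBS, "ConversionRates"))
  if (any(!is.finite(c(bsLevel, oxbsLevel))) ||
      any(c(bsLevel, oxbsLevel) < 0) || any(c(bsLevel, oxbsLevel) > 1))
    stop("bsLevel and oxbsLevel must lie in [0, 1]")
  b <- conversionRates(ratesBS); o <- conversionRates(ratesOxBS)
  ## [bs - aC_b; ox - aC_o] = A %*% [m; h]
  A <- rbind(c(b["amC"] - b["aC"], b["ahmC"] - b["aC"]),
             c(o["amC"] - o["aC"], o["ahmC"] - o["aC"]))
  det <- A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1]
  if (abs(det) < 1e-12)
    stop("singular unmixing system: the two arms do not separate mC from hmC")
  y1 <- unname(bsLevel - b[["aC"]]); y2 <- unname(oxbsLevel - o[["aC"]])
  m <- unname((A[2, 2] * y1 - A[1, 2] * y2) / det)
  h <- unname((A[1, 1] * y2 - A[2, 1] * y1) / det)
  mC <- pmin(pmax(m, 0), 1)
  hC <- pmin(pmax(h, 0), 1)
  over <- mC + hC > 1
  if (any(over)) {
    s <- mC[over] + hC[over]
    mC[over] <- mC[over] / s
    hC[over] <- hC[over] / s
  }
  data.frame(f_C = 1 - mC - hC, f_mC = unname(mC), f_hmC = unname(hC),
             clamped = unname(mC != m | hC != h),
             raw_f_mC = unname(m), raw_f_hmC = unname(h))
}

#' Read a two-column chromosome-sizes file
#'
#' @param path TSV with columns chromosome name and length (no header).
#' @return A named integer vector of sequence lengths.
#' @export
readChromSizes <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          showProgress = FALSE)
  setNames(as.integer(dt[[2L]]), as.character(dt[[1L]]))
}

#' Read BED intervals
#'
#' Thin wrapper over [rtracklayer::import] for BED3/BED6/BED12; file
#' coordinates are 0-based half-open, the returned
#' [GenomicRanges::GRanges] is 1-based closed.
#'
#' @param path a BED file.
#' @return A [GenomicRanges::GRanges].
#' @export
readBedIntervals <- function(path) {
  rtracklayer::import(path, format = "BED")
}
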