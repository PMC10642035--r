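#' @import methods
#' @import S4Vectors
#' @import IRanges
#' @import GenomicRanges
#' @import SummarizedExperiment
#' @importFrom GenomeInfoDb seqnames seqlevels seqlengths "seqlengths<-"
#'   seqinfo Seqinfo
#' @importFrom stats rbinom rpois rgamma rnbinom pchisq pt fisher.test
#'   t.test setNames anova lm runif
#' @importFrom utils write.table
#' @importFrom data.table fread fwrite as.data.table data.table setDF
#' @importFrom jsonlite write_json read_json
NULL

## ---------------------------------------------------------------------------
## SiteCalls: per-cytosine coverage / modified-call counts for one sample/arm
## ---------------------------------------------------------------------------

#' Per-cytosine modification calls
#'
#' `SiteCalls` extends [GenomicRanges::GRanges] with one range per cytosine
#' (width 1, 1-based), metadata columns `coverage` and `modified` (apparent
#' modified-call count), and a sequence context (`"CG"` or `"CH"`) uniform
#' within a table. Records are kept sorted by (chrom, pos, strand) with no
#' duplicated keys, and `0 <= modified <= coverage` holds everywhere.
#'
#' @slot context character(1), `"CG"` or `"CH"`.
#' @export
setClass("SiteCalls",
         contains = "GRanges",
         representation(context = "character"))

setValidity("SiteCalls", function(object) {
  msg <- character()
  if (length(object@context) != 1L || !object@context %in% c("CG", "CH"))
    msg <- c(msg, "context must be one of 'CG', 'CH'")
  mc <- mcols(object)
  if (!all(c("coverage", "modified") %in% colnames(mc)))
    msg <- c(msg, "metadata columns 'coverage' and 'modified' are required")
  else {
    cov <- mc$coverage; mod <- mc$modified
    if (any(cov < 0) || any(mod < 0) || any(mod > cov))
      msg <- c(msg, "counts must satisfy 0 <= modified <= coverage")
  }
  if (length(object) && any(width(object) != 1L))
    msg <- c(msg, "all ranges must have width 1")
  if (length(object) > 1L) {
    if (is.unsorted(order(as.integer(seqnames(object)), start(object),
                          as.integer(strand(object)))))
      msg <- c(msg, "records must be sorted by (chrom, pos, strand)")
    if (anyDuplicated(paste0(seqnames(object), ":", start(object),
                             strand(object))))
      msg <- c(msg, "duplicated (chrom, pos, strand) keys are not allowed")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SiteCalls table
#'
#' Builds a validated [SiteCalls] object from parallel vectors. Rows are
#' sorted by (chrom, pos, strand); exactly duplicated rows are collapsed to
#' one record, while duplicated keys carrying different counts raise an error
#' (a site's counts split across rows is treated as a corrupt table, never
#' silently merged).
#'
#' @param chrom character or factor of chromosome names.
#' @param pos integer 1-based positions.
#' @param strand `"+"` or `"-"` per site (recycled).
#' @param coverage,modified non-negative integer counts per site.
#' @param context `"CG"` or `"CH"`.
#' @param seqlengths optional named integer vector of chromosome lengths.
#' @return A [SiteCalls] object.
#' @examples
#' sc <- SiteCalls("chr1", c(100L, 120L), "+", coverage = c(10L, 10L),
#'                 modified = c(5L, 10L), context = "CG")
#' genomeLevel(sc)
#' @export
SiteCalls <- function(chrom, pos, strand = "+", coverage, modified,
                      context = c("CG", "CH"), seqlengths = NULL) {
  context <- match.arg(context)
  coverage <- as.integer(round(coverage))
  modified <- as.integer(round(modified))
  gr <- GRanges(chrom, IRanges(as.integer(pos), width = 1L),
                strand = strand)
  mcols(gr)$coverage <- coverage
  mcols(gr)$modified <- modified
  if (!is.null(seqlengths))
    seqlengths(gr) <- seqlengths[seqlevels(gr)]
  gr <- gr[order(as.integer(seqnames(gr)), start(gr),
                 as.integer(strand(gr)))]
  key <- paste0(seqnames(gr), ":", start(gr), strand(gr))
  if (anyDuplicated(key)) {
    full <- paste(key, mcols(gr)$coverage, mcols(gr)$modified)
    keep <- !duplicated(full)
    gr <- gr[keep]; key <- key[keep]
    if (anyDuplicated(key))
      stop("duplicated (chrom, pos, strand) keys with conflicting counts; ",
           "refusing to merge")
  }
  new("SiteCalls", gr, context = context)
}

#' @rdname SiteCalls-accessors
#' @export
setGeneric("modContext", function(x) standardGeneric("modContext"))

#' Accessors for SiteCalls
#'
#' `modContext` returns the sequence context; `siteCoverage` and
#' `modifiedCalls` the per-site counts; `modLevels` the per-site apparent
#' modification fraction `modified / coverage`.
#'
#' @param x A [SiteCalls] object.
#' @return `modContext`: character(1). Others: numeric vectors parallel to
#'   `x`.
#' @name SiteCalls-accessors
NULL

#' @rdname SiteCalls-accessors
#' @export
setMethod("modContext", "SiteCalls", function(x) x@context)

#' @rdname SiteCalls-accessors
#' @export
siteCoverage <- function(x) mcols(x)$coverage

#' @rdname SiteCalls-accessors
#' @export
modifiedCalls <- function(x) mcols(x)$modified

#' @rdname SiteCalls-accessors
#' @export
modLevels <- function(x) {
  cov <- siteCoverage(x)
  ifelse(cov > 0L, modifiedCalls(x) / cov, NA_real_)
}

setMethod("show", "SiteCalls", function(object) {
  cat("SiteCalls (", object@context, " context): ", length(object),
      " sites on ", length(unique(as.character(seqnames(object)))),
      " sequence(s)\n", sep = "")
  if (length(object)) {
    lv <- tryCatch(genomeLevel(object), error = function(e) NA_real_)
    cat("  total coverage: ", sum(siteCoverage(object)),
        "; genome-wide level: ", formatC(100 * lv, digits = 3, format = "f"),
        "%\n", sep = "")
  }
  callNextMethod()
})

## ---------------------------------------------------------------------------
## ConversionRates: arm-specific apparent-modification probabilities
## ---------------------------------------------------------------------------

#' Arm-specific conversion chemistry
#'
#' Apparent-modification probabilities for the three cytosine states under
#' one sequencing arm: `aC` is the probability an unmodified C still reads
#' as modified (1 - conversion efficiency), `amC` the probability an mC
#' reads as modified (retention), `ahmC` the same for hmC. For a
#' well-behaved BS arm `aC` is near 0 and `amC`, `ahmC` near 1; for a
#' well-behaved oxBS arm `ahmC` is additionally near 0.
#'
#' @slot arm character(1), e.g. `"BS"`, `"oxBS"`, `"TET+"`, `"TET-"`.
#' @slot aC,amC,ahmC probabilities in `[0, 1]`.
#' @export
setClass("ConversionRates",
         representation(arm = "character", aC = "numeric", amC = "numeric",
                        ahmC = "numeric"))

setValidity("ConversionRates", function(object) {
  p <- c(object@aC, object@amC, object@ahmC)
  if (length(p) != 3L || any(!is.finite(p)) || any(p < 0) || any(p > 1))
    "aC, amC, ahmC must each be a single probability in [0, 1]"
  else TRUE
})

#' @rdname ConversionRates-class
#' @param arm arm label.
#' @param aC,amC,ahmC probabilities in `[0, 1]` (see slots).
#' @return A `ConversionRates` object.
#' @examples
#' ConversionRates("BS", aC = 0.005, amC = 0.98, ahmC = 0.95)
#' @export
ConversionRates <- function(arm, aC, amC, ahmC) {
  new("ConversionRates", arm = as.character(arm), aC = aC, amC = amC,
      ahmC = ahmC)
}

#' @rdname ConversionRates-class
#' @param x a `ConversionRates` object.
#' @export
conversionRates <- function(x) {
  stopifnot(is(x, "ConversionRates"))
  c(aC = x@aC, amC = x@amC, ahmC = x@ahmC)
}

setMethod("show", "ConversionRates", function(object) {
  cat("ConversionRates [", object@arm, "]: a_C=", object@aC,
      ", a_mC=", object@amC, ", a_hmC=", object@ahmC, "\n", sep = "")
})

## ---------------------------------------------------------------------------
## WindowTable: per-sample modification levels over fixed genomic tiles
## ---------------------------------------------------------------------------

#' Per-sample window modification levels
#'
#' `WindowTable` extends [SummarizedExperiment::RangedSummarizedExperiment].
#' Rows are fixed-width, non-overlapping genome tiles; assays are
#' `"coverage"` and `"modified"` (pooled per-window counts per sample) and
#' `"level"` (`modified / coverage`, `NA` where uncovered); `colData` holds
#' `sample` and `group` labels.
#'
#' @export
setClass("WindowTable", contains = "RangedSummarizedExperiment")

setValidity("WindowTable", function(object) {
  msg <- character()
  if (!all(c("coverage", "modified", "level") %in% assayNames(object)))
    msg <- c(msg, "assays 'coverage', 'modified', 'level' are required")
  if (!all(c("sample", "group") %in% colnames(colData(object))))
    msg <- c(msg, "colData must contain 'sample' and 'group'")
  if (length(msg)) msg else TRUE
})

#' @rdname WindowTable-class
#' @param x a `WindowTable`.
#' @return `windowRanges`: the tile [GenomicRanges::GRanges];
#'   `windowLevelMatrix`: numeric matrix of per-sample levels;
#'   `sampleGroups`: character vector of group labels.
#' @export
windowRanges <- function(x) rowRanges(x)

#' @rdname WindowTable-class
#' @export
windowLevelMatrix <- function(x) assay(x, "level")

#' @rdname WindowTable-class
#' @export
sampleGroups <- function(x) as.character(colData(x)$group)

setMethod("show", "WindowTable", function(object) {
  cat("WindowTable: ", nrow(object), " windows x ", ncol(object),
      " samples (groups: ",
      paste(unique(sampleGroups(object)), collapse = ", "), ")\n", sep = "")
  callNextMethod()
})
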