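## Pipeline orchestration: stage execution in dependency order over a
## run configuration, with a fixed output layout and a machine-readable
## run report. A thin command-line wrapper lives in inst/scripts/oxbsdm.R.

#' Default run configuration
#'
#' Thresholds default to the analysis constants used throughout: 1000 bp
#' tiles, a 5 percentage-point minimum difference, p and q cutoffs of
#' 0.05, EM-seq minimum strand-specific coverage 10, and 4 kb flanks split
#' into 20 bins with 27 gene-body bins.
#'
#' @param outDir output directory.
#' @param seed integer master seed.
#' @param stages stages to run, in any order; executed in dependency
#'   order. Subset of `simulate`, `levels`, `dmr`, `dhmr`, `enrich`,
#'   `profile`, or `"all"`.
#' @param sim named list of overrides passed to [simConfig()].
#' @param manifest optional path to an existing sample manifest (TSV with
#'   columns `sample_id`, `cell_type`, `fraction`, `arm`, `replicate`,
#'   `context`, `path`); required when `simulate` is not among the
#'   stages.
#' @param tileWidth,minDiffPct,pMax,qMax,minCov,emseqMinCov,flank,flankBins,bodyBins
#'   analysis thresholds (see details).
#' @return A classed list (`RunConfig`).
#' @export
runConfig <- function(outDir, seed = 1L, stages = "all", sim = list(),
                      manifest = NULL, tileWidth = 1000L, minDiffPct = 5,
                      pMax = 0.05, qMax = 0.05, minCov = 1L,
                      emseqMinCov = 10L, flank = 4000L, flankBins = 20L,
                      bodyBins = 27L) {
  cfg <- as.list(environment())
  thr <- c(tileWidth, minDiffPct, pMax, qMax, minCov, emseqMinCov, flank,
           flankBins, bodyBins)
  if (any(thr <= 0)) stop("thresholds must be positive")
  structure(cfg, class = "RunConfig")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys mirror the [runConfig()] arguments.
#' @return A `RunConfig`.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(runConfig, y)
}

#' Read a sample manifest
#'
#' @param path manifest TSV (`sample_id`, `cell_type`, `fraction`, `arm`,
#'   `replicate`, `context`, `path`).
#' @return A `data.frame`.
#' @export
readManifest <- function(path) {
  mf <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  need <- c("sample_id", "cell_type", "arm", "replicate", "context",
            "path")
  miss <- setdiff(need, names(mf))
  if (length(miss)) stop("manifest missing column(s): ",
                         paste(miss, collapse = ", "))
  mf
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order: `simulate`
#' (synthetic genome, landscape, arm call tables, spike-ins, expression),
#' `levels` (per-sample genome-wide levels, spike-in conversion rates and
#' corrected levels, BS-oxBS subtraction), `dmr` (mCG/mCH differential
#' windows), `dhmr` (hmCG differential windows), `enrich` (genic-feature
#' log-odds), `profile` (expression classes, metagene profiles, repeat
#' summary). Outputs are written under `outDir` and a machine-readable
#' report (per-stage record counts, dropped-window counts, genome-wide
#' levels per sample) is written to `report.json`. Re-running with the
#' same configuration and seed reproduces identical numeric outputs.
#'
#' @param config a [runConfig()] list, or a path to a YAML file for
#'   [readRunConfig()].
#' @return The run report, invisibly.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  stopifnot(inherits(config, "RunConfig"))
  stageOrder <- c("simulate", "levels", "dmr", "dhmr", "enrich", "profile")
  stages <- if (identical(config$stages, "all")) stageOrder
            else intersect(stageOrder, config$stages)
  if (!length(stages)) stop("no recognized stage requested")
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  report <- list(stages_completed = character(),
                 stages_skipped = setdiff(stageOrder, stages))
  env <- new.env()

  if ("simulate" %in% stages) {
    sim <- do.call(simConfig, c(list(seed = config$seed), config$sim))
    genome <- makeGenome(sim)
    truth <- makeLandscape(sim, genome)
    dataDir <- file.path(config$outDir, "data")
    dir.create(dataDir, showWarnings = FALSE)
    mf <- list(); calls <- list()
    armRates <- list(BS = sim$rates$BS, oxBS = sim$rates$oxBS)
    sOff <- 0L
    for (ct in names(sim$targets)) {
      for (rep_ in seq_len(sim$nReplicates)) {
        for (arm in names(armRates)) {
          for (ctx in c("CG", "CH")) {
            sOff <- sOff + 1L
            id <- paste(ct, paste0("rep", rep_), arm, ctx, sep = "_")
            sc <- simulateArm(truth, ct, ctx, armRates[[arm]],
                              seed = config$seed * 1000L + sOff)
            path <- file.path(dataDir, paste0(id, ".txt"))
            writeSiteCalls(sc, path)
            calls[[id]] <- sc
            mf[[length(mf) + 1L]] <- data.frame(
              sample_id = id, cell_type = ct, fraction = "Pos",
              arm = arm, replicate = rep_, context = ctx, path = path)
          }
        }
      }
    }
    manifest <- do.call(rbind, mf)
    write.table(manifest, file.path(config$outDir, "manifest.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    spikes <- list(
      BS = simulateSpikeIns(truth, sim$rates$BS,
                            seed = config$seed * 1000L + 901L),
      oxBS = simulateSpikeIns(truth, sim$rates$oxBS,
                              seed = config$seed * 1000L + 902L))
    expr <- lapply(setNames(nm = names(sim$targets)), function(ct)
      makeExpression(truth, ct,
                     seed = config$seed * 1000L +
                       match(ct, names(sim$targets))))
    for (ct in names(expr))
      write.table(data.frame(gene_id = rownames(expr[[ct]]),
                             expr[[ct]], check.names = FALSE),
                  file.path(dataDir, paste0("expression_", ct, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    env$truth <- truth; env$calls <- calls; env$manifest <- manifest
    env$spikes <- spikes; env$expr <- expr; env$sim <- sim
    report$simulate <- list(
      samples = nrow(manifest),
      cpg_sites = length(truth$sites$CG),
      ch_sites = length(truth$sites$CH),
      planted_windows = length(truth$planted))
    report$stages_completed <- c(report$stages_completed, "simulate")
  } else {
    if (is.null(config$manifest))
      stop("stages beyond 'simulate' need a manifest when simulation ",
           "is not run")
    env$manifest <- readManifest(config$manifest)
    env$calls <- list()
    for (i in seq_len(nrow(env$manifest))) {
      row <- env$manifest[i, ]
      env$calls[[row$sample_id]] <-
        readSiteCalls(row$path, context = row$context)
    }
  }
  mfst <- env$manifest

  getCalls <- function(ct, rep_, arm, ctx) {
    sel <- mfst$cell_type == ct & mfst$replicate == rep_ &
      mfst$arm == arm & mfst$context == ctx
    if (!any(sel))
      stop("missing arm for required pairing: cell_type=", ct,
           " replicate=", rep_, " arm=", arm, " context=", ctx)
    env$calls[[mfst$sample_id[which(sel)[1L]]]]
  }
  cellTypes <- unique(mfst$cell_type)
  repsOf <- function(ct) sort(unique(mfst$replicate[mfst$cell_type == ct]))

  if ("levels" %in% stages) {
    rows <- list()
    for (ct in cellTypes) for (rep_ in repsOf(ct)) for (ctx in c("CG", "CH")) {
      bs <- getCalls(ct, rep_, "BS", ctx)
      ox <- getCalls(ct, rep_, "oxBS", ctx)
      lvBS <- genomeLevel(bs); lvOx <- genomeLevel(ox)
      row <- data.frame(cell_type = ct, replicate = rep_, context = ctx,
                        bs_level = lvBS, oxbs_level = lvOx,
                        mC = lvOx, hmC = lvBS - lvOx,
                        mC_corrected = NA_real_, hmC_corrected = NA_real_)
      if (!is.null(env$spikes)) {
        rBS <- estimateConversionRates(env$spikes$BS, env$truth$spikes,
                                       "BS")
        rOx <- estimateConversionRates(env$spikes$oxBS, env$truth$spikes,
                                       "oxBS")
        cl <- correctLevels(lvBS, lvOx, rBS, rOx)
        row$mC_corrected <- cl$f_mC; row$hmC_corrected <- cl$f_hmC
      }
      rows[[length(rows) + 1L]] <- row
    }
    lev <- do.call(rbind, rows)
    write.table(lev, file.path(config$outDir, "levels.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    env$levels <- lev
    report$levels <- list(rows = nrow(lev))
    report$stages_completed <- c(report$stages_completed, "levels")
  }

  chromSizesOf <- function() {
    if (!is.null(env$truth)) return(env$truth$chromSizes)
    ## infer from the data when no simulation context exists
    all <- unlist(GRangesList(lapply(env$calls, granges)))
    vapply(split(end(all), as.character(seqnames(all))), max, numeric(1))
  }

  pairsOf <- function(cts) {
    if (length(cts) < 2L) return(list())
    cmb <- utils::combn(cts, 2L, simplify = FALSE)
    cmb
  }

  if (any(c("dmr", "dhmr", "enrich") %in% stages)) {
    tiles <- tileWindows(chromSizesOf(), config$tileWidth)
    env$tiles <- tiles
  }

  if ("dmr" %in% stages || "enrich" %in% stages) {
    dmrs <- list(); dropped <- list(); backgrounds <- list()
    for (ctx in c("CG", "CH")) {
      modType <- if (ctx == "CG") "mCG" else "mCH"
      callsList <- list(); groups <- character()
      for (ct in cellTypes) for (rep_ in repsOf(ct)) {
        callsList[[paste(ct, rep_, sep = "_")]] <-
          getCalls(ct, rep_, "oxBS", ctx)
        groups <- c(groups, ct)
      }
      wt <- windowLevels(callsList, env$tiles, groups, rule = "all")
      backgrounds[[modType]] <- granges(windowRanges(wt))
      dropped[[modType]] <- metadata(wt)$dropped_windows
      for (pr in pairsOf(cellTypes)) {
        key <- paste(modType, paste(pr, collapse = "-"), sep = ":")
        rec <- callDMR(wt, pr, minDiffPct = config$minDiffPct,
                       qMax = config$qMax, modType = modType)
        dmrs[[key]] <- rec
        writeDMRecords(rec, file.path(config$outDir,
          paste0("dmr_", modType, "_", paste(pr, collapse = "_"),
                 ".bed")))
      }
    }
    env$dmrs <- dmrs; env$backgrounds <- backgrounds
    if ("dmr" %in% stages) {
      report$dmr <- list(records = vapply(dmrs, length, integer(1)),
                         dropped_windows = dropped)
      report$stages_completed <- c(report$stages_completed, "dmr")
    }
  }

  if ("dhmr" %in% stages || "enrich" %in% stages) {
    callsBS <- list(); callsOx <- list(); groups <- character()
    for (ct in cellTypes) for (rep_ in repsOf(ct)) {
      nm <- paste(ct, rep_, sep = "_")
      callsBS[[nm]] <- getCalls(ct, rep_, "BS", "CG")
      callsOx[[nm]] <- getCalls(ct, rep_, "oxBS", "CG")
      groups <- c(groups, ct)
    }
    bsWt <- windowLevels(callsBS, env$tiles, groups, rule = "at_least_k",
                         k = 2L)
    oxWt <- windowLevels(callsOx, env$tiles, groups, rule = "at_least_k",
                         k = 2L)
    dhmrs <- list()
    for (pr in pairsOf(cellTypes)) {
      key <- paste("hmCG", paste(pr, collapse = "-"), sep = ":")
      rec <- callDhMR(bsWt, oxWt, pr, minDiffPct = config$minDiffPct,
                      pMax = config$pMax, qMax = config$qMax)
      dhmrs[[key]] <- rec
      writeDMRecords(rec, file.path(config$outDir,
        paste0("dhmr_hmCG_", paste(pr, collapse = "_"), ".bed")))
    }
    env$dhmrs <- dhmrs
    env$backgrounds$hmCG <- granges(windowRanges(bsWt))[
      windowKey(windowRanges(bsWt)) %in% windowKey(windowRanges(oxWt))]
    if ("dhmr" %in% stages) {
      report$dhmr <- list(records = vapply(dhmrs, length, integer(1)))
      report$stages_completed <- c(report$stages_completed, "dhmr")
    }
  }

  if ("enrich" %in% stages) {
    if (is.null(env$truth))
      stop("the enrich stage needs gene models (run with simulate)")
    allRecs <- c(env$dmrs, env$dhmrs)
    rows <- list()
    for (key in names(allRecs)) {
      rec <- allRecs[[key]]
      modType <- sub(":.*", "", key)
      for (dir in c("hyper", "hypo")) {
        sub_ <- rec[mcols(rec)$direction == dir]
        if (!length(sub_)) next
        lo <- logOddsEnrichment(sub_, env$backgrounds[[modType]],
                                env$truth$genes)
        lo$set <- paste(key, dir, sep = ":")
        rows[[length(rows) + 1L]] <- lo
      }
    }
    enr <- if (length(rows)) do.call(rbind, rows) else
      data.frame(feature = character())
    write.table(enr, file.path(config$outDir, "enrichment.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    report$enrich <- list(tables = length(rows))
    report$stages_completed <- c(report$stages_completed, "enrich")
  }

  if ("profile" %in% stages) {
    if (is.null(env$truth))
      stop("the profile stage needs gene models and expression (run with ",
           "simulate)")
    profRows <- list(); raRows <- list()
    for (ct in cellTypes) {
      classes <- expressionClasses(env$expr[[ct]])
      callsList <- setNames(lapply(repsOf(ct), function(r)
        getCalls(ct, r, "oxBS", "CG")),
        paste0(ct, "_rep", repsOf(ct)))
      for (tier in c("high", "mid", "low", "unexpressed")) {
        gl <- env$truth$genes[mcols(env$truth$genes)$gene_id %in%
                              classes[[tier]]]
        if (!length(gl)) next
        mp <- metageneProfile(callsList, gl, flank = config$flank,
                              flankBins = config$flankBins,
                              bodyBins = config$bodyBins)
        mp$cell_type <- ct; mp$gene_set <- tier
        profRows[[length(profRows) + 1L]] <- mp
        ra <- regionAverages(callsList, gl, flank = config$flank)
        ra$cell_type <- ct; ra$gene_set <- tier
        raRows[[length(raRows) + 1L]] <- ra
      }
    }
    prof <- do.call(rbind, profRows)
    write.table(prof, file.path(config$outDir, "metagene_profiles.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    ra <- do.call(rbind, raRows)
    write.table(ra, file.path(config$outDir, "region_averages.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    repCalls <- list()
    for (ct in cellTypes) for (rep_ in repsOf(ct))
      repCalls[[paste0(ct, "_rep", rep_)]] <-
        getCalls(ct, rep_, "oxBS", "CH")
    rs <- repeatSummary(repCalls, env$truth$repeats)
    write.table(rs, file.path(config$outDir, "repeat_summary.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    report$profile <- list(profile_rows = nrow(prof),
                           repeat_rows = nrow(rs))
    report$stages_completed <- c(report$stages_completed, "profile")
  }

  jsonlite::write_json(report, file.path(config$outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
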