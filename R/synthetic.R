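## Synthetic ground-truth genomes, modification landscapes, sequencing-arm
## call tables, spike-in controls, and expression tables. The generator's
## defaults encode the study conditions the pipeline is meant to operate
## under: three CNS cell types with distinct genome-wide mCG/hmCG/mCH
## levels (neuronal mCH 1.46%, astrocyte 0.85%, microglia 0.67%; elevated
## simple-repeat mCH), arm-specific conversion errors, genic couplings to
## expression, and planted differential windows.

#' Simulation configuration
#'
#' Builds the configuration list consumed by [makeGenome()],
#' [makeLandscape()], [simulateArm()] and [makeExpression()]. Defaults
#' describe a desk-scale genome (5 Mb, ~150k CpGs) with the cell-type
#' genome-wide modification targets, conversion error rates, and coupling
#' structure of the study design; all values are overridable.
#'
#' @param seed integer master seed; all derived draws are deterministic
#'   given it.
#' @param genomeSize total genome length in bp.
#' @param nChrom number of equally sized chromosomes.
#' @param cpgDensity,chDensity cytosine sites per bp in each context.
#' @param nGenes number of non-overlapping genes.
#' @param geneLength length range (bp) genes are drawn from.
#' @param repeatFraction fraction of the genome covered by repeat
#'   intervals.
#' @param repeatClassShares named shares of `repeatFraction` per class.
#' @param tileWidth DMR tile width (bp).
#' @param targets named list per cell type of genome-wide target fractions
#'   `mCG`, `hmCG`, `mCH`, `hmCH`.
#' @param simpleRepeatMCH named per-cell-type mCH level inside
#'   Simple_repeat intervals (the whole-genome `mCH` target is preserved
#'   by adjusting the non-simple-repeat baseline).
#' @param repeatMcgOffset,repeatHmcgOffset additive offsets applied to
#'   repeat-overlapping CpG sites before rescaling to the genome target
#'   (repeats carry more mCG and less hmCG).
#' @param promoterMult,bodyMult named multipliers (high/mid/low/unexpressed
#'   expression tiers) applied to promoter (TSS +/- 1 kb) respectively
#'   gene-body site means, per modification.
#' @param mchCouplingCellTypes cell types in which the mCH-expression
#'   coupling is active (neuron-specific in the defaults).
#' @param rates named list of [ConversionRates] per arm (`BS`, `oxBS`,
#'   `TETplus`, `TETminus`).
#' @param meanCoverage mean per-site call coverage per arm.
#' @param nReplicates replicates per cell type and arm.
#' @param betaPrecision Dirichlet precision of per-site fractions around
#'   their means.
#' @param planted `data.frame` of planted differential windows with
#'   columns `mod_type` (`mCG`/`hmCG`/`mCH`), `cell_a`, `cell_b`, `n`,
#'   `diff` (percentage points added to `cell_a` over `cell_b`); `NULL`
#'   for none.
#' @param nSpikePerClass spike-in positions per true state.
#' @param expressionMeans named mean counts per tier (`unexpressed` is
#'   exactly zero).
#' @param expressionSize negative-binomial size (dispersion) parameter.
#' @return A classed list (`SimConfig`).
#' @export
simConfig <- function(seed = 1L,
                      genomeSize = 5e6,
                      nChrom = 2L,
                      cpgDensity = 0.03,
                      chDensity = 0.06,
                      nGenes = 200L,
                      geneLength = c(5e3, 2e4),
                      repeatFraction = 0.3,
                      repeatClassShares = c(LINE = 0.4, SINE = 0.25,
                                            LTR = 0.2,
                                            Simple_repeat = 0.15),
                      tileWidth = 1000L,
                      targets = list(
                        neuron = list(mCG = 0.75, hmCG = 0.16,
                                      mCH = 0.0146, hmCH = 0),
                        astrocyte = list(mCG = 0.80, hmCG = 0.10,
                                         mCH = 0.0085, hmCH = 0),
                        microglia = list(mCG = 0.82, hmCG = 0.06,
                                         mCH = 0.0067, hmCH = 0)),
                      simpleRepeatMCH = c(neuron = 0.0251,
                                          astrocyte = 0.0154,
                                          microglia = 0.0117),
                      repeatMcgOffset = 0.04,
                      repeatHmcgOffset = -0.03,
                      promoterMult = list(
                        mCG = c(high = 0.3, mid = 0.6, low = 0.9,
                                unexpressed = 1),
                        hmCG = c(high = 0.5, mid = 0.7, low = 0.9,
                                 unexpressed = 1),
                        mCH = c(high = 0.4, mid = 0.7, low = 1.3,
                                unexpressed = 1)),
                      bodyMult = list(
                        mCG = c(high = 0.8, mid = 0.9, low = 1.0,
                                unexpressed = 1),
                        hmCG = c(high = 1.5, mid = 1.2, low = 0.9,
                                 unexpressed = 0.8),
                        mCH = c(high = 0.4, mid = 0.7, low = 1.3,
                                unexpressed = 1)),
                      mchCouplingCellTypes = "neuron",
                      rates = list(
                        BS = ConversionRates("BS", 0.005, 0.98, 0.95),
                        oxBS = ConversionRates("oxBS", 0.005, 0.98, 0.05),
                        TETplus = ConversionRates("TET+", 0.005, 0.98,
                                                  0.95),
                        TETminus = ConversionRates("TET-", 0.005, 0.02,
                                                   0.95)),
                      meanCoverage = 2,
                      nReplicates = 4L,
                      betaPrecision = 20,
                      planted = NULL,
                      nSpikePerClass = 300L,
                      expressionMeans = c(high = 1000, mid = 100,
                                          low = 10),
                      expressionSize = 5) {
  cfg <- as.list(environment())
  probs <- c(cpgDensity, chDensity, repeatFraction,
             unlist(cfg$targets), simpleRepeatMCH)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (meanCoverage < 0) stop("meanCoverage must be non-negative")
  structure(cfg, class = "SimConfig")
}

#' Generate a synthetic genome layout
#'
#' Chromosome sizes, non-overlapping gene models (with exon structure and
#' a coding span), labeled repeat intervals realizing the requested genome
#' fraction, the DMR tile grid, and spike-in truth positions.
#' Deterministic under the configuration seed.
#'
#' @param config a [simConfig()] list.
#' @return A list with `chromSizes`, `genes` ([geneModels()]), `repeats`
#'   (GRanges with `class`), `tiles`, `spikes` (GRanges with
#'   `true_state`).
#' @export
makeGenome <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  chromLen <- as.integer(round(config$genomeSize / config$nChrom))
  chromSizes <- setNames(rep(chromLen, config$nChrom),
                         paste0("chr", seq_len(config$nChrom)))
  ## genes: sequential placement with random gaps, round-robin over chroms
  lens <- as.integer(round(runif(config$nGenes, config$geneLength[1L],
                                 config$geneLength[2L])))
  chrOf <- rep(seq_len(config$nChrom), length.out = config$nGenes)
  geneList <- list()
  for (ci in seq_len(config$nChrom)) {
    idx <- which(chrOf == ci)
    li <- lens[idx]
    pad <- 5000L  # keep flanks on-chromosome
    free <- chromLen - 2L * pad - sum(li)
    if (free < length(li))
      stop("infeasible layout: too many/long genes for the genome size")
    cuts <- diff(c(0, sort(runif(length(li))), 1)) * free
    starts <- pad + as.integer(round(cumsum(cuts[-length(cuts)]) +
                                     cumsum(c(0, li[-length(li)]))))
    geneList[[ci]] <- GRanges(names(chromSizes)[ci],
                              IRanges(starts, width = li),
                              strand = sample(c("+", "-"), length(li),
                                              replace = TRUE))
  }
  genes <- sort(unlist(GRangesList(geneList)), ignore.strand = TRUE)
  ## exon structure: odd segments of a (2k-1)-way split are exons
  nEx <- sample(1:5, length(genes), replace = TRUE)
  exl <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    segs <- tile(granges(genes[i]), n = 2L * nEx[i] - 1L)[[1L]]
    exl[[i]] <- granges(segs[seq(1L, length(segs), by = 2L)])
  }
  cds <- IRanges(start(genes) + as.integer(0.1 * width(genes)),
                 start(genes) + as.integer(0.9 * width(genes)))
  genes <- geneModels(granges(genes), paste0("gene", seq_along(genes)),
                      exons = GRangesList(exl), cds = cds)
  seqlengths(genes) <- chromSizes[seqlevels(genes)]
  ## repeats: pick disjoint 500 bp cells per class, merge adjacent cells
  cellW <- 500L
  tilesAll <- tileWindows(chromSizes, cellW)
  nCells <- length(tilesAll)
  shares <- config$repeatClassShares / sum(config$repeatClassShares)
  nPick <- round(config$repeatFraction * nCells * shares)
  picked <- sample(nCells, sum(nPick))
  cls <- rep(names(nPick), nPick)
  reps <- tilesAll[picked]
  mcols(reps)$class <- cls
  o <- order(as.integer(seqnames(reps)), start(reps))
  reps <- reps[o]
  repeats <- unlist(GRangesList(lapply(split(reps, mcols(reps)$class),
    function(g) { r <- reduce(g); mcols(r)$class <- mcols(g)$class[1L]; r })))
  names(repeats) <- NULL
  repeats <- sort(repeats, ignore.strand = TRUE)
  ## spike-in contig: interleaved C / mC / hmC positions
  nsp <- config$nSpikePerClass
  spikes <- GRanges("spike1", IRanges(seq_len(3L * nsp) * 2L, width = 1L),
                    strand = "+")
  mcols(spikes)$true_state <- rep(c("C", "mC", "hmC"), nsp)
  list(chromSizes = chromSizes, genes = genes, repeats = repeats,
       tiles = tileWindows(chromSizes, config$tileWidth), spikes = spikes)
}

## multiplicative rescale of site means to hit an overall target exactly
rescaleTo <- function(means, target) {
  m <- mean(means)
  if (m == 0) return(means)
  pmin(means * target / m, 0.999)
}

#' Generate the ground-truth modification landscape
#'
#' Draws per-site true `(f_C, f_mC, f_hmC)` for every cell type and
#' context from Dirichlet distributions whose means implement the
#' configured genome-wide targets, repeat-class offsets (including the
#' elevated Simple_repeat mCH with the whole-genome target preserved),
#' promoter/gene-body couplings to per-cell-type expression tiers, and
#' planted differential windows overriding the landscape in specified
#' tiles. Deterministic under the configuration seed.
#'
#' @param config a [simConfig()] list.
#' @param genome output of [makeGenome()].
#' @return A `SyntheticTruth` list: `config`, the genome components,
#'   `sites` (per-context GRanges), `means` and `fracs` (per cell type and
#'   context), `tiers` (per cell type expression tier per gene), and
#'   `planted` (GRanges of planted windows with `mod_type`, `cell_a`,
#'   `cell_b`, `true_diff`).
#' @export
makeLandscape <- function(config, genome) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed + 1L)
  chromSizes <- genome$chromSizes
  drawSites <- function(density) {
    grl <- lapply(names(chromSizes), function(ch) {
      n <- round(density * chromSizes[[ch]])
      pos <- sort(sample.int(chromSizes[[ch]], n))
      GRanges(ch, IRanges(pos, width = 1L), strand = "+")
    })
    gr <- unlist(GRangesList(grl))
    seqlengths(gr) <- chromSizes[seqlevels(gr)]
    gr
  }
  sites <- list(CG = drawSites(config$cpgDensity),
                CH = drawSites(config$chDensity))
  cellTypes <- names(config$targets)
  ## expression tiers per cell type: a quarter unexpressed, rest split
  ## equally (independent assignment per cell type)
  tiers <- list()
  gid <- mcols(genome$genes)$gene_id
  nG <- length(gid)
  for (ct in cellTypes) {
    nU <- round(nG / 4); rest <- nG - nU
    base <- rest %/% 3L; extra <- rest %% 3L
    lab <- c(rep("unexpressed", nU),
             rep(c("high", "mid", "low"), base + (seq_len(3L) <= extra)))
    tiers[[ct]] <- setNames(sample(lab), gid)
  }
  promoters <- upstreamWindow(genome$genes, -1000L, 1000L)  # TSS +/- 1 kb
  inSR <- lapply(sites, function(s)
    overlapsAny(s, genome$repeats[mcols(genome$repeats)$class ==
                                  "Simple_repeat"], ignore.strand = TRUE))
  inRep <- lapply(sites, function(s)
    overlapsAny(s, genome$repeats, ignore.strand = TRUE))
  tierOf <- function(s, ct) {
    hit <- findOverlaps(s, genome$genes, ignore.strand = TRUE,
                        select = "first")
    tier <- rep(NA_character_, length(s))
    ok <- !is.na(hit)
    tier[ok] <- tiers[[ct]][gid[hit[ok]]]
    tier
  }
  promOf <- function(s, ct) {
    hit <- findOverlaps(s, promoters, ignore.strand = TRUE,
                        select = "first")
    tier <- rep(NA_character_, length(s))
    ok <- !is.na(hit)
    tier[ok] <- tiers[[ct]][gid[hit[ok]]]
    tier
  }
  means <- list()
  for (ct in cellTypes) {
    tg <- config$targets[[ct]]
    bodyT <- list(CG = tierOf(sites$CG, ct), CH = tierOf(sites$CH, ct))
    promT <- list(CG = promOf(sites$CG, ct), CH = promOf(sites$CH, ct))
    mkMeans <- function(mod, ctx, target) {
      n <- length(sites[[ctx]])
      if (target == 0) return(rep(0, n))
      mu <- rep(target, n)
      if (ctx == "CG") {
        off <- if (mod == "mCG") config$repeatMcgOffset
               else config$repeatHmcgOffset
        mu[inRep[[ctx]]] <- pmax(mu[inRep[[ctx]]] + off, 0.001)
      }
      applyCoupling <- mod != "mCH" || ct %in% config$mchCouplingCellTypes
      if (applyCoupling) {
        pm <- config$promoterMult[[mod]]; bm <- config$bodyMult[[mod]]
        pt <- promT[[ctx]]; bt <- bodyT[[ctx]]
        sel <- !is.na(pt)
        mu[sel] <- mu[sel] * pm[pt[sel]]
        sel <- is.na(pt) & !is.na(bt)
        mu[sel] <- mu[sel] * bm[bt[sel]]
      }
      mu <- rescaleTo(mu, target)
      if (mod == "mCH" && ct %in% names(config$simpleRepeatMCH)) {
        sr <- inSR[[ctx]]
        if (any(sr) && !all(sr)) {
          v <- config$simpleRepeatMCH[[ct]]
          mu[sr] <- v
          restTarget <- (target * n - v * sum(sr)) / sum(!sr)
          if (restTarget <= 0)
            stop("coupling parameters push means outside (0, 1)")
          mu[!sr] <- rescaleTo(mu[!sr], restTarget)
        }
      }
      if (any(mu < 0 | mu >= 1))
        stop("coupling parameters push means outside (0, 1)")
      mu
    }
    means[[ct]] <- list(
      CG = list(mC = mkMeans("mCG", "CG", tg$mCG),
                hmC = mkMeans("hmCG", "CG", tg$hmCG)),
      CH = list(mC = mkMeans("mCH", "CH", tg$mCH),
                hmC = mkMeans("hmCH", "CH", tg$hmCH)))
  }
  ## planted differential windows override the landscape on the tile grid
  planted <- GRanges()
  if (!is.null(config$planted) && nrow(config$planted)) {
    pw <- list()
    usable <- genome$tiles
    for (r in seq_len(nrow(config$planted))) {
      plant <- config$planted[r, ]
      ctx <- if (plant$mod_type == "mCH") "CH" else "CG"
      mod <- if (plant$mod_type %in% c("mCG", "mCH")) "mC" else "hmC"
      covered <- which(countOverlaps(usable, sites[[ctx]],
                                     ignore.strand = TRUE) >= 5L)
      pick <- sample(covered, plant$n)
      win <- usable[pick]
      usable <- usable[-pick]
      hit <- overlapsAny(sites[[ctx]], win, ignore.strand = TRUE)
      base <- means[[plant$cell_b]][[ctx]][[mod]]
      lift <- pmin(pmax(base[hit] + plant$diff / 100, 0), 0.999)
      means[[plant$cell_a]][[ctx]][[mod]][hit] <- lift
      mcols(win)$mod_type <- plant$mod_type
      mcols(win)$cell_a <- plant$cell_a
      mcols(win)$cell_b <- plant$cell_b
      mcols(win)$true_diff <- plant$diff
      pw[[r]] <- win
    }
    planted <- unlist(GRangesList(pw))
  }
  ## Dirichlet draws around the means (exact means on the simplex)
  fracs <- list()
  k <- config$betaPrecision
  for (ct in cellTypes) {
    fracs[[ct]] <- list()
    for (ctx in c("CG", "CH")) {
      m <- means[[ct]][[ctx]]$mC
      h <- means[[ct]][[ctx]]$hmC
      n <- length(m)
      g1 <- rgamma(n, shape = k * pmax(1 - m - h, 0))
      g2 <- rgamma(n, shape = k * m)
      g3 <- rgamma(n, shape = k * h)
      tot <- g1 + g2 + g3
      tot[tot == 0] <- 1
      fracs[[ct]][[ctx]] <- cbind(f_C = g1 / tot, f_mC = g2 / tot,
                                  f_hmC = g3 / tot)
    }
  }
  structure(list(config = config, chromSizes = chromSizes,
                 genes = genome$genes, repeats = genome$repeats,
                 tiles = genome$tiles, spikes = genome$spikes,
                 sites = sites, means = means, fracs = fracs,
                 tiers = tiers, planted = planted),
            class = "SyntheticTruth")
}

#' Simulate one sequencing arm
#'
#' Forward model inverted by [correctLevels()]: per site, coverage is
#' Poisson with the configured mean and the apparent-modified count is
#' binomial with probability
#' `f_C * a_C + f_mC * a_mC + f_hmC * a_hmC` under the arm's chemistry.
#' Zero-coverage sites are dropped (as in real call tables).
#'
#' @param truth a `SyntheticTruth` from [makeLandscape()].
#' @param cellType cell type name.
#' @param context `"CG"` or `"CH"`.
#' @param rates a [ConversionRates] (e.g. `truth$config$rates$BS`).
#' @param meanCoverage mean site coverage; default from the config.
#' @param seed integer seed (give each replicate/arm its own).
#' @return A [SiteCalls] object.
#' @export
simulateArm <- function(truth, cellType, context = c("CG", "CH"), rates,
                        meanCoverage = NULL, seed = 1L) {
  stopifnot(inherits(truth, "SyntheticTruth"),
            is(rates, "ConversionRates"))
  context <- match.arg(context)
  if (is.null(meanCoverage)) meanCoverage <- truth$config$meanCoverage
  set.seed(seed)
  f <- truth$fracs[[cellType]][[context]]
  if (is.null(f)) stop("unknown cell type: ", cellType)
  r <- conversionRates(rates)
  p <- f[, "f_C"] * r["aC"] + f[, "f_mC"] * r["amC"] +
    f[, "f_hmC"] * r["ahmC"]
  cov <- rpois(nrow(f), meanCoverage)
  mod <- rbinom(nrow(f), cov, p)
  keep <- cov > 0L
  s <- truth$sites[[context]][keep]
  SiteCalls(as.character(seqnames(s)), start(s), as.character(strand(s)),
            cov[keep], mod[keep], context = context,
            seqlengths = truth$chromSizes)
}

#' Simulate spike-in control calls
#'
#' Spike-in positions have pure true states (`C`, `mC`, `hmC`), so the
#' apparent-modification probability is the arm's rate for that state.
#'
#' @param truth a `SyntheticTruth`.
#' @param rates a [ConversionRates].
#' @param meanCoverage mean coverage of the spike contigs (spike-ins are
#'   typically deeply covered).
#' @param seed integer seed.
#' @return A [SiteCalls] on the spike contig (context `"CG"` by
#'   convention).
#' @export
simulateSpikeIns <- function(truth, rates, meanCoverage = 50, seed = 1L) {
  stopifnot(inherits(truth, "SyntheticTruth"),
            is(rates, "ConversionRates"))
  set.seed(seed)
  sp <- truth$spikes
  r <- conversionRates(rates)
  p <- c(C = r[["aC"]], mC = r[["amC"]],
         hmC = r[["ahmC"]])[as.character(mcols(sp)$true_state)]
  cov <- rpois(length(sp), meanCoverage)
  mod <- rbinom(length(sp), cov, p)
  keep <- cov > 0L
  SiteCalls(as.character(seqnames(sp))[keep], start(sp)[keep],
            as.character(strand(sp))[keep], cov[keep], mod[keep],
            context = "CG")
}

#' Simulate expression count tables
#'
#' Counts are negative-binomial with tier-dependent means; genes in the
#' `unexpressed` tier emit exactly zero in every replicate.
#'
#' @param truth a `SyntheticTruth`.
#' @param cellType cell type name.
#' @param nReps replicates; default from the config.
#' @param seed integer seed.
#' @return An integer matrix genes x replicates with gene-id rownames.
#' @export
makeExpression <- function(truth, cellType, nReps = NULL, seed = 1L) {
  stopifnot(inherits(truth, "SyntheticTruth"))
  cfg <- truth$config
  if (is.null(nReps)) nReps <- cfg$nReplicates
  set.seed(seed)
  tier <- truth$tiers[[cellType]]
  if (is.null(tier)) stop("unknown cell type: ", cellType)
  mu <- ifelse(tier == "unexpressed", 0,
               cfg$expressionMeans[tier])
  counts <- matrix(0L, length(tier), nReps,
                   dimnames = list(names(tier),
                                   paste0(cellType, "_rep", seq_len(nReps))))
  pos <- mu > 0
  for (j in seq_len(nReps))
    counts[pos, j] <- rnbinom(sum(pos), mu = mu[pos],
                              size = cfg$expressionSize)
  counts
}

#' @export
print.SimConfig <- function(x, ...) {
  cat("SimConfig: ", x$genomeSize / 1e6, " Mb, ", x$nChrom,
      " chromosome(s), ", x$nGenes, " genes, seed ", x$seed, "\n",
      "  cell types: ", paste(names(x$targets), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' @export
print.SyntheticTruth <- function(x, ...) {
  cat("SyntheticTruth: ", length(x$sites$CG), " CpG and ",
      length(x$sites$CH), " CH sites; ", length(x$genes), " genes; ",
      length(x$planted), " planted window(s)\n", sep = "")
  invisible(x)
}
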