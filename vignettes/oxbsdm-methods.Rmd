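---
title: "Resolving and comparing 5mC and 5hmC from paired-arm sequencing: models and design"
author: "oxbsdm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving and comparing 5mC and 5hmC from paired-arm sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages(library(oxbsdm))
```

## The measurement problem

Bisulfite sequencing (BS) reads 5-methylcytosine (mC) and
5-hydroxymethylcytosine (hmC) jointly: both survive conversion, so the
"methylation" fraction at a cytosine is really the total-modification
fraction. Two paired-arm designs resolve the two marks:

* **oxBS**: chemical oxidation converts hmC before bisulfite treatment, so
  the oxBS arm reads mC only and `hmC = BS - oxBS` per site or region.
* **EM-seq**: TET2 oxidation plus APOBEC deamination reads mC + hmC in the
  TET+ arm; the mock (TET-) arm reads hmC only, so `mC = TET+ - TET-`.

Both arithmetics are one kernel in this package (`subtractOxBS()`,
`emseqLevels()`): a *total* arm minus a *partial* arm, with the partial
arm's identity deciding which state the difference estimates. Sites must
reach a minimum coverage in *both* arms (default 1 for oxBS workflows; 10,
strand-specific, for targeted EM-seq, reflecting how deeply such amplicon
panels are sequenced).

### Negative differences

Subtraction of two noisy binomial fractions produces negative values
wherever the true hmC is small. Per-site reports clamp these to zero but
retain the raw value (`raw_derived`), because a clamped mean is biased
upward exactly where hmC is near zero — the regime of non-CpG
hydroxymethylation (hmCH). Genome-wide hmC is therefore computed by
`genomeHmcLevel()` as the difference of the two arms' aggregate
coverage-weighted levels, where negative site noise cancels. This is why
the pipeline reports hmCH near zero (well below 1%) when the simulated
truth is zero, instead of a clamping artifact of several tenths of a
percent.

## Conversion chemistry and its correction

Chemistry is summarized by three probabilities per arm
(`ConversionRates`): `a_C`, the chance an unmodified C still reads
modified (1 − conversion efficiency); `a_mC`, mC retention; `a_hmC`, hmC
retention. They are estimated from spike-in controls of known per-position
state by pooled counting (`estimateConversionRates()`). The observed arm
levels are then linear in the true state fractions:

$$bs = (1 - m - h)\,a_C^{BS} + m\,a_{mC}^{BS} + h\,a_{hmC}^{BS},
\qquad ox = (1 - m - h)\,a_C^{ox} + m\,a_{mC}^{ox} + h\,a_{hmC}^{ox}.$$

`correctLevels()` solves this 2×2 system for \((m, h)\), clamps to the
probability simplex, and flags clamping; with ideal chemistry it reduces
exactly to the naive subtraction. Corrected values are reported *alongside*
raw levels and never silently substituted downstream — raw and corrected
levels answer different questions, and the correction is only as good as
the spike-in estimate behind it.

## Differential region calling

The genome is tiled in 1000 bp non-overlapping windows (the final partial
tile is kept). Two callers share this grid:

* **mCG/mCH windows** (`callDMR()`): windows covered in *all* samples are
  retained; per window the pooled modified/coverage counts are tested
  against two-group membership with a binomial likelihood-ratio test. With
  group as the sole covariate the logistic regression's fitted
  probabilities are the group-pooled proportions, so the GLM deviance test
  has a closed form — the implementation uses it, and a test asserts exact
  equality with `glm()`. No overdispersion correction is applied.
* **hmCG windows** (`callDhMR()`): windows covered in at least two samples
  per arm are retained and intersected across arms; per sample the window
  hmC level is BS − oxBS; groups are compared with a two-sample
  pooled-variance t test.

Both convert p-values to q with `manualQ()`, the step-up
\(q_i = \min(p_i N / \mathrm{rank}_i,\, q_{i+1})\), which is algebraically
the Benjamini–Hochberg adjustment (asserted against an independent BH
implementation on random inputs). Reported records must pass a minimum
absolute group difference of 5 percentage points and q < 0.05 (plus
p ≤ 0.05 for the hmC caller); defaults mirror the analysis constants used
throughout.

Two statistical choices here were genuinely open and are worth recording:

* **Multiplicity scope.** q-values are computed per pairwise comparison
  over *all tested windows*, not over the subset passing the ≥5 pp
  difference filter. Conditioning the multiplicity burden on an
  effect-size filter invalidates FDR control: at four replicates per
  group, roughly 1.5% of null windows show both a ≥5 pp difference and a
  nominal p ≤ 0.05 by chance, and a step-up over only the filtered few
  dozen windows retains nearly all of them (simulated FDR around 0.5).
  Over all windows the simulated FDR is effectively zero.
* **Variance pooling.** The default t statistic uses a single residual
  variance pooled across windows (degrees of freedom summed over
  windows). With 4 replicates per group a per-window variance estimate
  has 6 df; its sampling noise alone pushes genuinely differential
  windows past the multiplicity threshold often enough to cost ~10%
  sensitivity in simulation. Window-level subtraction noise in this
  design is dominated by a shared technical scale, which makes the pooled
  estimate defensible (the same reasoning that motivates moderated-t
  approaches); `varPooling = "per_window"` restores the classical test.

`dmrOverlap()` reports direction-stratified three-way Venn counts by
window identity, and `diffCorrelation()` the correlation of differences
between modification types over shared windows (differential mCG and hmCG
are expected to anti-correlate where the marks exchange).

## Genic-feature enrichment

Regions are assigned a single label from a fixed vocabulary (promoter
tiers ≤1, 1–2 and 2–3 kb upstream of the TSS; 5′/3′ UTR; first/other
exon; first/other intron; ≤300 bp downstream; distal intergenic) by their
midpoint, with promoter tiers resolved through the nearest TSS. Midpoint
assignment keeps the labels a partition — per-feature counts always sum
to the number of regions — which is what makes the 2×2 enrichment tables
well defined; any-overlap assignment is available behind a flag. One
listed tier label is internally inconsistent with the others ("promoter
≥1 kb" among ≤-style tiers); it is implemented as the within-1-kb tier.

Per feature, enrichment of a region set against the all-detected-windows
background is the log odds ratio \(\ln\frac{a\,d}{c\,b}\) with a Woolf
(normal-approximation) 95% CI of half-width
\(1.96\sqrt{1/a + 1/b + 1/c + 1/d}\), and a two-sided Fisher exact p on
the uncorrected table (the point-probability definition; the test suite
checks it against exhaustive hypergeometric enumeration). A
Haldane–Anscombe 0.5 is added to every cell only when a zero cell would
make the estimate infinite — except `a = 0`, which is reported as status
`n.d.` with no estimate, matching how empty features are conventionally
displayed.

## Profiles, expression classes, and repeats

`metageneProfile()` bins a 4 kb upstream flank into 20 bins of 200 nt,
the gene body into 27 equal-width bins scaled to each gene's own length
(the only reading of a fixed-length profile; genes shorter than 27 nt are
dropped and counted), and a 4 kb downstream flank likewise, in the gene's
5′→3′ orientation. Body bin edges are placed symmetrically from the 5′
end so a minus-strand gene partitions as the exact mirror of a
plus-strand one. Within a gene a bin's level is coverage-weighted; across
genes the bin mean is unweighted, so every gene counts equally. Flanks of
adjacent genes are not deduplicated — each gene contributes its own
window.

Expression classes per cell type: genes with zero counts in all samples
are *unexpressed*; the rest are ranked by mean count and split into three
equal tertiles, extra genes going to the highest tertile first and ties
broken by stable gene-id order. `regionAverages()` gives one pooled value
per replicate for upstream/body/downstream regions, compared either by a
paired t test (two-fraction designs) or a two-factor fixed-effects ANOVA
with Šidák-corrected pairwise contrasts on the pooled residual variance.
`repeatSummary()` assigns a site to the repeat compartment if it overlaps
any repeat interval (the repeat/non-repeat site sets partition all
sites) and summarizes LINE/SINE/LTR/Simple_repeat classes separately.
`emseqRegionTests()` mirrors the targeted-region analysis: an unpaired t
test on replicate region means plus per-CpG contrasts from a
position × cell-type ANOVA with a single pooled variance,
Šidák-corrected over positions.

## The synthetic-data generator

Every stage is exercised on synthetic data with known truth
(`simConfig()`, `makeGenome()`, `makeLandscape()`, `simulateArm()`,
`makeExpression()`). The defaults describe the study conditions the
pipeline is meant for:

* **Genome**: 5 Mb in 2 chromosomes; 200 non-overlapping genes of
  5–20 kb (≈50% genic, mouse-like; a sketch of several hundred 5–50 kb
  genes does not fit 5 Mb); exon/intron structure and a coding span per
  gene; repeat intervals covering 30% of the genome split over
  LINE/SINE/LTR/Simple_repeat; CpG density 0.03/bp (≈150k sites), CH
  density 0.06/bp.
* **Cell-type targets** (genome-wide): neuron mCG 75%, hmCG 16%, mCH
  1.46%; astrocyte 80%/10%/0.85%; microglia 82%/6%/0.67%; hmCH 0
  everywhere. The mCH values are the printed whole-genome levels for the
  three CNS cell types; the CG values reproduce their reported ordering
  (microglia > astrocyte > neuron for mCG, reversed for hmCG) at
  plausible magnitudes. Simple-repeat mCH is set to the printed
  2.51/1.54/1.17% with the non-repeat baseline adjusted so the
  whole-genome target is preserved exactly in expectation.
* **Couplings**: promoter (TSS ± 1 kb) mCG decreases with expression
  tier; gene-body hmCG increases with it; mCH decreases with expression
  in neurons only. Repeat CpGs get +4 pp mCG / −3 pp hmCG offsets. After
  all effects, site means are rescaled multiplicatively so the
  genome-wide mean hits the target exactly.
* **Per-site truth**: \((f_C, f_{mC}, f_{hmC})\) drawn from a Dirichlet
  around the site mean (precision 20), which keeps fractions on the
  simplex with exact means — so genome-wide recovery checks are unbiased
  by construction, unlike independent clamped beta draws.
* **Arms**: coverage Poisson (mean 2 by default; a plain, defensible
  model — no overdispersion), apparent-modified counts binomial with
  probability \(f_C a_C + f_{mC} a_{mC} + f_{hmC} a_{hmC}\). Default
  chemistry: `a_C` 0.005, `a_mC` 0.98 in both arms; `a_hmC` 0.95 (BS)
  vs 0.05 (oxBS) — near-complete conversion of unmodified C and low
  over/under-conversion, as spike-in QC of such libraries typically
  shows. Spike-in contigs (300 positions per state) are simulated with
  the same rates, closing the loop with the estimator.
* **Expression**: negative-binomial counts (size 5) with tier means
  1000/100/10; unexpressed genes emit exactly zero, so the class
  definitions downstream are satisfiable.
* **Planted windows**: differential tiles on the DMR grid set one cell
  type's site means to another's plus a configured offset, giving exact
  truth for power and FDR checks.

What the generator does *not* emulate: sequence-driven CpG clustering and
CpG islands, sharp coverage heterogeneity (GC bias, mappability), spatial
autocorrelation of modification beyond the genic/repeat structure,
per-read errors, and PCR duplicates. Passing tests therefore demonstrate
the *statistical* correctness of the estimators and callers under the
stated noise model, not robustness to every artifact of real libraries.

### Problem sizes used in checks

The simulation-based checks run at the genome scale the generator
defaults describe: a 5 Mb genome (~150k CpG or ~300k CH sites) for
level-recovery and coverage-thinning checks; 100–1000 windows × 8 samples
for caller calibration (500 null replicates) and power (100 replicates);
100 thinning seeds for the coverage-sufficiency check. These sizes give
Monte-Carlo error comfortably below the tolerances being asserted while
keeping the whole suite runnable in minutes.

One empirical note on coverage sufficiency: thinning a 5 Mb table to
0.001X genome coverage retains ≈5000 calls, so the thinned estimate's
error SD is \(\sqrt{p(1-p)/5000} \approx 0.6\) pp at \(p = 0.75\). The
*median* error is well inside 1 pp, but a 95% within-1-pp guarantee needs
≥7200 retained calls — it emerges only at real-genome scale (a 2.7 Gb
genome at 0.001X retains tens of thousands of CpG calls). The test suite
states the genome-scale expectation and documents this scale dependence.

### Parameter-recovery runs and chemistry

The recovery checks that compare an estimated level against a configured
truth (genome-wide and simple-repeat mCH) simulate the oxBS arm with
ideal chemistry. With the default error rates the raw oxBS level is
biased upward by ≈0.49 pp (`a_C` alone contributes
\(0.005 \times 98.5\% \approx 0.49\) pp at 1.46% mCH) — a property of the
chemistry, removable only by the spike-in correction, and separate from
what those checks measure, namely that the generator and the
coverage-weighted estimators are mutually consistent. The chemistry bias
itself is asserted in closed form in the unit tests.

## Numerical and degenerate-input choices

* Counts reconstructed from percent columns round half up; a site's
  counts split across duplicate rows is an error, never a silent merge.
* Call tables are strand-resolved; `destrandCpG()` merges CpG dyads
  (minus-strand positions map to pos − 1) when a destranded view is
  wanted.
* Call-table positions are 1-based; interval files (BED) are 0-based
  half-open; conversion happens only at the file boundary
  (`rtracklayer`, and the BED writer for differential records).
* Zero total coverage raises rather than returning NaN; windows with
  zero group coverage are skipped with a log message; zero-variance
  windows get p = 1 (no difference) or p = 0 (exact difference).
* Ties in the step-up ranking need no special handling: a stable sort
  plus the running minimum give tied p-values a common q.
* All randomness flows through explicit seeds; identical configuration
  and seed reproduce byte-identical pipeline outputs.

## Known limitations

* The window tests assume binomial counting noise (no overdispersion
  between replicates beyond pooling); biological replicate
  heterogeneity beyond that model will inflate the DMR caller's
  false-positive rate.
* The across-window variance pooling in the hmC caller assumes a shared
  replicate-noise scale; strongly heteroscedastic designs should switch
  to `varPooling = "per_window"`.
* Feature annotation resolves each region to one label by midpoint;
  regions straddling features are deliberately not multi-counted.
* The EM-seq module covers level arithmetic and region/per-CpG testing
  for targeted panels, not genome-wide EM-seq calling.
* Alignment, read trimming, and modified-base calling from raw reads are
  out of scope; inputs are per-site call tables.
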