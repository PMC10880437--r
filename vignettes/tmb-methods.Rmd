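---
title: "Estimating tumor mutational burden from targeted-panel VCFs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating tumor mutational burden from targeted-panel VCFs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelTMB)
```

## The problem

Tumor mutational burden (TMB) — the density of qualifying somatic variants
per megabase of sequenced footprint — is used as a pan-cancer predictive
biomarker for immune checkpoint inhibitors, with a widely cited TMB-high
bound of 10 mut/Mb. The number itself, however, is an artifact of the
filter chain that produced it. On a targeted panel without a matched
normal, the raw caller output mixes four populations:

* true clonal somatic variants (the quantity of interest),
* germline polymorphisms that survive calling because no matched normal
  was sequenced,
* formalin-induced C>T deamination artifacts in FFPE tissue, concentrated
  at low allele fractions,
* run-level systematic artifacts shared by many samples of one
  sequencing batch.

panelTMB implements the TMB arithmetic as a cascade of five independent,
per-variant predicates, each directly testable, and ships two complete
parameterizations (`builtinProfile("IC")` and `builtinProfile("FO")`)
that differ in caller-quality policy, germline databases, consequence
classes counted, COSMIC driver handling, and the FFPE VAF bound:

```{r}
builtinProfile("IC")
```

## The score and its filters

For one sample, `applyProfile()` evaluates every variant against:

1. **caller quality** — the caller's PASS flag, and/or removal of
   variants present in more than 15% of the samples of the same
   sequencing run (intra-run recurrence);
2. **germline** — any configured population database (1000 Genomes,
   gnomAD, ExAC) reporting an allele frequency strictly above 0.1%;
3. **consequence class** — an include/exclude table over missense,
   nonsense, frameshift/in-frame indels, synonymous, splice-site
   (within 2 bp of an exon/intron boundary), and pooled non-coding
   classes, plus a COSMIC driver rule;
4. **VAF and depth** — fraction of supporting reads strictly above the
   preservation-specific minimum (10% FFPE / 5% frozen under IC, 5%
   under FO), depth strictly above 100 reads.

TMB is then the retained count divided by the footprint (1.6 Mb by
default): `computeTMB()`. Retention is order-independent — every stage is
a pure predicate given a fixed run context — so the per-stage attrition in
a `FilterReport` is a reporting convention (first failing stage in the
order quality, recurrence, germline, class/driver, VAF/depth), not an
algorithmic one.

All thresholds are compared strictly (`>`), mirroring the "higher than"
definitions of both algorithms; a `strict = FALSE` switch turns them
inclusive for interoperability with pipelines that use `>=`. Two
deliberate asymmetries are kept exactly as the algorithms define them:
the sample-level QC gate fails strictly *below* its bounds (20 million
reads, 15% of the footprint above 1000X — a sample exactly at either
bound is contributive), and the curation rules below use *inclusive*
bounds (MSIsensor score ≥ 10, allelic ratio ≥ 10%).

### Decisions where the definitions are silent

* **Unannotated or unmappable consequence terms** become `"unknown"` and
  are excluded by both built-ins — a conservative default that can only
  lower TMB, never inflate it.
* **Indels at splice boundaries**: the annotator's consequence term wins,
  so a frameshift annotated as splice-site is excluded under IC even
  though indels are included. This follows the principle that the
  annotation, not the allele length, encodes the biological effect.
* **Degenerate runs**: with fewer than 7 samples, 15% of the run is less
  than one sample, so the recurrence predicate removes anything shared by
  two samples (and in a single-sample run, everything). The predicate is
  applied as defined, with a warning.
* **Recurrence counting** happens over raw parsed variants, before any
  other filter, so a germline-heavy sample still contributes to
  recurrence evidence.
* **Multi-allelic records** are split into one record per alternate
  allele before anything else; keys are taken as written (no
  left-alignment), which is sufficient because recurrence matching
  operates within a single pipeline's own output. Mutect2 VAF is
  `altAD / sum(AD)` with depth `sum(AD)` (equal to alt/(ref+alt) for
  biallelic records), falling back to the `AF`/`DP` tags.
* **MNVs** count as one event per record, with the annotator's class.
* **External somatic/germline classifiers** (zygosity-based algorithms
  used by some commercial pipelines) are not reimplemented; the
  `externalGermline` argument of `applyProfile()` accepts their verdicts
  as a per-variant key list, and the FO built-in otherwise approximates
  germline removal by population databases alone.

## VAF sweeps and plateaus

`vafSweep()` recomputes TMB along a grid of minimum-VAF cutoffs (default
0.01–0.30 in steps of 0.01) with every other filter fixed; the curve is
non-increasing by construction. `plateauVaf()` reports the smallest
cutoff from which every successive relative decrease stays within
`relTol` (default 0.05). A candidate plateau must have at least one
successor step; otherwise any strictly decreasing curve would trivially
"plateau" at the end of the grid. With count data the relative-decrease
test is granular — losing one variant out of twenty is a 5% step — so
plateau positions should be read as grid-resolution estimates, not sharp
change points.

The biological reading: frozen tumors carry no deamination artifacts, so
their curves flatten by a 5% cutoff; well-preserved FFPE flattens around
10%; heavily deaminated FFPE keeps falling, and no fixed cutoff fully
rescues it — such samples need manual curation.

## Cohort layer and curation

`summarizeByType()` reports per-tumor-type medians and observed ranges,
usually over the MSS/POLE-wild-type stratum, since hypermutators dominate
pooled medians. `binCounts()` uses the bins [0,10], (10,30], (30,100],
(100,∞): the low bin is right-closed so "between 0 and 10 mut/Mb"
includes a sample at exactly 10, while "greater than 100" starts strictly
above. `topDecileThreshold()` is the 90th percentile with linear
interpolation between order statistics (R's default quantile type 7);
samples strictly above it form the TMB-high set.

`curateHighTmb()` encodes the triage applied to TMB-high cases:
MSIsensor score ≥ 10%, a pathogenic mismatch-repair variant, an MSI or
APOBEC mutational signature, or a POLE proofreading mutation reclassifies
the sample as a biologically explained ("true") hypermutator; otherwise a
pathogenic TP53/PTEN/ARID1A variant at allelic ratio ≥ 10% marks it as
DNA-damage-repair-associated; otherwise it stays unexplained. Evidence
flags are consumed precomputed: MSI scoring and signature fitting are
upstream tools, not reimplemented here.

## What the synthetic cohorts emulate — and what they do not

`simConfig()`/`simulateCohort()` generate annotated VCF cohorts with a
per-variant truth label (`somatic`, `germline`, `ffpe_artifact`,
`recurrent_artifact`), so every stage of the cascade can be validated
without external data. The defaults are fixed study conditions, not
tuning knobs:

* somatic countable density 8.8/Mb for MSS samples (a typical
  pan-cancer MSS median on a 1.6 Mb panel), multiplied by 5 for MSI
  hypermutators;
* clonal somatic VAFs from Beta(8, 14) truncated to [0.12, 0.95]: fully
  above the 10% FFPE bound, so threshold experiments never clip true
  variants and clean-cohort recovery is exact;
* germline leakage 10 variants/sample at heterozygous VAF, with database
  allele frequencies drawn as a two-point mixture straddling the 0.1%
  bound (80% above it, the rest at or below — including exactly 0.001,
  so the strict-inequality edge is always exercised);
* FFPE deamination artifacts (C>T) at 30/Mb with VAF Beta(1.5, 40) for
  high-quality DNA (mass below 0.10) or Beta(1.2, 10) for low-quality
  DNA (heavier tail above 0.10); frozen samples receive none;
* two run-recurrent artifact keys per run, injected into 25% of the
  run's samples at VAF 0.15–0.35 (visible only to the recurrence
  filter);
* depth from a negative binomial around 800X with a floor of 150 reads,
  so the depth predicate never confounds VAF-threshold experiments.

Coordinates live on a single pseudo-contig because no filter consults a
reference sequence. Germline keys are private per sample (rare
polymorphisms); real cohorts also share *common* SNPs across samples,
which the recurrence filter would remove redundantly with the database
filter — a regime the generator deliberately omits to keep truth labels
unambiguous. Other simplifications: no read-level error model, no
subclonal somatic structure, no UMI/deduplication effects, and artifact
rates are qualitative (chosen to reproduce the plateau phenomenology,
not fitted to any cohort). Passing tests on these cohorts therefore
demonstrate the correctness of the filter arithmetic and the direction
of preservation effects, not clinical performance on real FFPE archives.

Determinism: the seed fully determines every file byte; the generator
saves and restores the session RNG state.

## Problem sizes and numerical notes

The test suite and the acceptance script run cohorts of 10–80 samples
with roughly 90–500 variants each — large enough for stable medians and
filter attrition, small enough to run in minutes on one CPU. VAF values
are stored as fractions in [0, 1] everywhere (VarScan2 percent strings
are converted on input); TMB is kept unrounded and only display code
rounds. Floating-point equality in round-trip tests is at `all.equal`
tolerance; the VarScan `FREQ` field is emitted with 10 significant
digits so a parse–write–parse cycle is lossless at that tolerance.

## Worked example

```{r example, eval = FALSE}
sim <- simulateCohort(simConfig(seed = 42, nSamples = 20), "cohort")
res <- runTmbWorkflow(sim$manifest, profile = "IC")
head(res$tmb[, c("sample_id", "preservation", "n_retained", "tmb")])
ev <- evaluateAgainstTruth(res$results, sim$truth)
summary(ev$abs_error)
```

A command-line wrapper with subcommands `simulate`, `tmb`, `sweep`,
`cohort-summary` and `curate` is installed at
`system.file("cli", "panelTMB.R", package = "panelTMB")`.
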