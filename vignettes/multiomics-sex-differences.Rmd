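---
title: "Methods: sex-difference analysis of exercise multi-omics"
author: "sexomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sex-difference analysis of exercise multi-omics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexomics)
```

## The problem

Skeletal muscle differs between the sexes at every molecular layer:
DNA methylation, transcript abundance, and protein abundance. In an
endurance-training cohort sampled at baseline, one hour after a first
acute exercise bout, and after eight weeks of training, those layers
can be read together: which transcriptional sex differences trace back
to the methylome, which protein differences trace back over
transcription to methylation, how the acute stress response differs by
sex, and which baseline differences training removes ("equalization").

`sexomics` implements that analysis as a tested pipeline with a
synthetic-cohort generator standing in for the raw study data. The
generator plants known effects; every downstream stage is validated by
recovering them.

## Statistical model

### Per-feature linear models with moderation

Every layer is modeled feature-by-feature on its stated scale — beta
values for methylation, log2 intensities for transcripts, log2
abundances for proteins. The baseline sex contrast fits

y = b0 + b1 * sexF + b2 * age + e

per feature, with `sexF = 1` for female samples so positive effects are
female-minus-male. Age is always included: the cohort's female subjects
are younger on average (about 28 vs 33 years), so age is a mild
confounder the covariate must absorb. The generator plants a small
per-year age slope on transcripts for exactly this reason, and a test
confirms the sex estimates stay unbiased under it.

Residual variances are moderated by empirical Bayes. The sample
variances are modeled as scaled chi-square draws around gene-level
variances with a scaled inverse-chi-square prior (d0, s0^2). The
hyper-parameters are estimated by method of moments on log s^2:
`e = log(s2) - digamma(d/2) + log(d/2)` has excess variance
`trigamma(d0/2)`, inverted numerically by a Newton iteration; the
posterior variance `(d0 s0^2 + d s^2)/(d0 + d)` feeds the moderated t
with `d0 + d` degrees of freedom. Degenerate inputs are handled
explicitly: identical variances (including all-zero) give `d0 = Inf`
and the common variance as prior; `d0 = 0` reproduces the classical t
exactly, which a test asserts. On heterogeneous-variance data the
implementation agrees with the reference Bioconductor implementation to
numerical precision (cross-checked in the test suite, never used as the
implementation).

Timepoint contrasts are paired: per-subject differences are regressed
on an intercept, so the subject-level random intercepts the generator
plants cancel, and fold changes are reported as `2^effect`. Subjects
missing either timepoint are dropped with a logged count; fewer than
three complete pairs is an error. Multiple testing uses
Benjamini-Hochberg throughout.

The Shapiro-Wilk gate (log-transform when a variable fails normality at
alpha = 0.05 and is strictly positive) applies to clinical-style
group-comparison variables only, not per omics feature: switching
transforms per feature would make effects incomparable across features.

### DMR detection

Differentially methylated regions are found by bump hunting. CpGs
within `maxgap = 300` bp on one chromosome form clusters; the per-CpG
sex coefficients are smoothed by a window-3 running mean inside
clusters (clusters under 3 CpGs stay unsmoothed); candidate regions are
maximal same-sign runs of smoothed effect at or above the 0.99 quantile
of all absolute smoothed effects with at least 2 CpGs; each candidate
is scored by its area (sum of absolute smoothed effects). The cutoff is
chosen once from the observed data and held fixed while sex labels are
permuted within timepoint strata B times (default 1000; desk-scale runs
use the 200 the calibration suites prescribe), the full candidate
extraction re-run each time. The null statistic is the maximum
candidate area per permutation, so `p = (1 + #[null >= area])/(B + 1)`
is family-wise and bounded below by `1/(B+1)`. Holding the cutoff fixed
is what makes observed and null areas comparable; re-deriving a
quantile cutoff inside each permutation would compare areas taken at
systematically lower thresholds.

With a tenth of the array differential, a 0.99-quantile cutoff sits
near the top of the single-site effect distribution; coherent blocks
only dominate it because the generator gives isolated differential
CpGs heterogeneous magnitudes (25-90% of `delta_beta`) while block
members carry the full effect — the realistic regime in which bump
hunting is useful at all. On arrays small enough that block CpGs
exceed 1% of all sites (the reduced test configurations), tests lower
the cutoff quantile to 0.95; the parameter is exposed precisely
because its correct value depends on array geometry.

### Direction-aware integration

Promoter methylation associates with silencing; gene-body methylation
with active transcription. A (differential CpG, differential
transcript) pair sharing a gene is *consistent* when the promoter
directions oppose or the gene-body directions agree. A transcript is
linked when it has at least one consistent CpG; a differential protein
is linked when its gene carries any differential CpG; the stricter
chain requires the gene to be a differential transcript with a
consistent CpG link and protein and transcript effects in the same
direction. The looser protein rule is deliberate: the linked-protein
count answers "does the gene's methylation differ", the chain answers
"does the difference propagate through expression".

Reported percentages are truncated (not rounded) to one decimal; that
is the convention under which 80/120 prints as 66.6%, and the package
reproduces such worked ratios exactly.

The headline differential sets use raw p < 0.05, matching the reporting
convention of cohort studies of this size; BH-thresholded variants are
available everywhere. One measurement deliberately differs: when the
*direction fraction* of differential CpGs (the female-hypermethylated
percentage) is estimated on a discovered set, false positives dilute it
toward 50% by about FDR x 34 points, so the estimate uses the BH 1%
set, where the bias is under half a point.

### Fiber type, mitochondria, equalization

Fiber-type calls take the argmax of a reference percentage profile
(slow type 1 vs fast 2a/2x, optionally pooled), with proteins whose top
two percentages lie within 5 points left unclassified. The 2x2
association of protein sex direction with fiber class uses the exact
Fisher test; the odds ratio is the sample OR with a Haldane 0.5
correction when a cell is empty. Mitochondrial annotation is exact and
case-sensitive, with near-misses reported but never counted — silent
fuzzy matching corrupts counts.

Equalization re-evaluates the features that differed between sexes at
baseline: a feature is equalized iff it is no longer differential after
training, with per-sex change directions from the paired contrasts. The
rule is antisymmetric in the timepoints by construction.

### Over-representation analysis

ORA is the hypergeometric upper tail of the overlap between a query set
and each gene set, intersected with a universe that defaults to the
features quantified in the relevant layer (not the genome — standard
practice for targeted panels), BH-corrected across terms. The
graph-aware correction used by online enrichment services is
proprietary; BH is used and reported as the correction method.

## Proteome preprocessing

Label-free proteomes arrive with intensity-dependent missingness. The
chain is: group-completeness filter (keep a protein quantified in at
least 90% of at least one sex-by-timepoint group; the boundary is
inclusive), total-amount normalization (columns scaled to the mean
observed total), log2, then downshift imputation — each missing cell
drawn from `N(mu - 1.5 sd, (0.5 sd)^2)` of its sample column's observed
moments, the convention for left-censored label-free data. Columns with
fewer than three observed values fall back to global moments with a
warning. The imputed-cell count and fraction are always reported; at
the default study conditions about 1.4% of cells are imputed, and
imputed values fall below the column mean in over 97% of draws, as the
distribution implies.

## The synthetic cohort

The generator is the package's study-conditions module, not a test
helper. Defaults were chosen once to mirror the emulated study design:

- **Design**: 16 female / 9 male subjects, ages ~N(27.9, 8.79^2) and
  ~N(33.2, 5.59^2) truncated at 18, three timepoints. Methylation is
  generated for baseline only (assayed once); transcripts and proteins
  for all timepoints. Subject random intercepts (SD 0.3 log2 units)
  give paired contrasts their advantage over unpaired ones.
- **Methylome**: bimodal beta values (promoters low, gene bodies high),
  logit-scale noise SD 0.12 (~0.03 beta units at mid-range). 10% of
  CpGs carry sex effects, each hypermethylated in females with
  probability 0.84. Twelve 8-CpG DMR blocks (88% on chrX) carry the
  full `delta_beta = 0.2` at intermediate baseline methylation, so
  either direction fits without clipping; effects are planted on the
  logit scale and clipped to [0.001, 0.999].
- **Coupling**: coupled differential genes take their expression
  direction *from* their methylation direction via the promoter/
  gene-body rule, so planted links are consistent by construction and
  the cohort-wide hyper-F fraction stays 0.84. DMR-block genes couple
  through their promoters (hyper-F block, repressed-in-F transcript).
- **Transcriptome**: 10% differential genes at |log2 FC| = 1, residual
  SD 0.4; 60 acute stress genes induced (+1.5) in males only at the
  acute timepoint; a 0.02/year age slope on all genes.
- **Proteome**: log2 abundances ~N(20, 2^2), residual SD 0.5; protein
  sex effects are 0.85x their gene's transcript effect; missingness
  follows `plogis((14 - x)/1)`, ~1.4% of cells. 120 mitochondrial
  proteins gain +0.75 log2 units after training in both sexes. 15 slow-
  and 15 fast-fiber proteins carry opposite sex effects (|log2 FC|
  1.2); training removes 80% of the male fast-fiber excess and fills
  the same share of the male slow-fiber deficit, emulating the
  equalization phenomenon.

What the generator does *not* emulate: probe-level array artifacts,
batch effects, correlated CpGs beyond the planted blocks, peptide-level
proteomics structure, menstrual-cycle or hormonal covariates, and
realistic gene-length or GC structure. Passing tests therefore
demonstrate the pipeline's statistical behavior under its stated model,
not robustness to those real-data complications.

Problem sizes in the shipped analyses — 2,000 genes, ~10,600 CpGs,
600 proteins, B = 200 resamplings, 20-40 calibration seeds — were
chosen as the scale at which every property of interest (calibration,
recovery, FWER control) is measurable in seconds on a laptop.

## Numerical choices and edge cases

- Deterministic everywhere: one master seed derives per-stage streams;
  identical seed and config give bit-identical output, asserted by
  tests.
- BH ties are resolved by the stable ordering of `p.adjust`; feature
  order is deterministic.
- Zero residual variance (exact fits, identical paired differences) is
  flagged (`degenerate`), the p-value set to NA rather than 0.
- Beta-range, duplicate-id, and context/gene-coupling violations raise
  errors naming the offending row and column; readers never coerce.
- The trigamma inversion uses the standard Newton scheme with closed-
  form guards for extreme arguments.
- `cutoff_quantile = 1` yields no candidate DMRs (the maximum is a
  single site, below `min_cpgs`), an asserted degenerate case.

## Known limitations

- The permutation null permutes sex labels, not residuals; with 25
  baseline samples the permutation space is ample, but for very small
  strata the p resolution degrades (B < 20 is refused).
- One CpG maps to at most one gene and context; multi-gene CpGs must be
  duplicated as input rows.
- Whether the completeness filter groups by sex x timepoint or
  timepoint alone is a config choice (`groups`), surfaced in the
  decision table, as the convention varies between studies.
- No mixed-effects models: within-subject correlation is handled by
  pairing, not by random-effect estimation.
- No ranked (GSEA-style) enrichment; ORA only.
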