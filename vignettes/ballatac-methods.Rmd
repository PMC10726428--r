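---
title: "Models and methods behind ballatac"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ballatac}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ballatac)
```

This vignette is the package's own account of its statistical machinery:
the models, their assumptions, the tunable parameters and their defaults,
what the synthetic generators do and do not emulate, and the design
choices made where several reasonable options existed. Nothing stated
here goes beyond what the test suite and `scripts/acceptance.R` actually
compute.

## Coordinates, regions and matrices

Every genomic coordinate inside the package is 0-based, half-open (BED
convention); 1-based inputs — VCF positions, GRanges — are converted at
the boundary, once. A region catalog is an ordered, non-overlapping set
of intervals with stable `chrom:start-end` ids, and all matrices are
anchored on it: rows are regions, columns are samples, and readers never
reorder samples relative to the sample sheet.

ROI selection follows the summit-anchored recipe: a subtype-merged summit
survives when it lies inside peaks of at least `min_support = 2` distinct
samples of that subtype ("reproducible in multiple samples" read as at
least two, scoped to the subtype because summits are subtype-merged, and
implemented as point containment of the summit rather than overlap of the
extended interval — both interpretations are defensible; point
containment is the stricter and simpler one and is what `select_roi`
does). Surviving summits are extended symmetrically by
`half_width = 150` — the only symmetric reading that produces the odd
301-bp interval — merged, and removed if they touch the blacklist by even
one base. Windowing into 250-bp tiles keeps a final partial window when
it is at least half a window wide and otherwise absorbs it into the
preceding window; this conserves covered bases exactly and never emits
fragments shorter than 125 bp, and re-merging the windows reconstructs
the parent regions (a tested invariant).

Annotation assigns each region by its midpoint with the precedence
promoter > 5'UTR > 3'UTR > exon > intron > distal intergenic. The
promoter window defaults to (−2000, +500) around the TSS; the upstream
tool this mimics does not publish its settings, so ours are explicit and
configurable. Chromatin states are boolean combinations of ≥ 1 bp
overlaps with H3K27ac, H3K4me1 and H3K27me3 interval sets: active (either
activating mark without K27me3), bivalent/poised (K27me3 plus an
activating mark), repressed (K27me3 alone), unmarked otherwise; the four
states partition any input by construction.

## The negative-binomial differential model

Counts are modeled per region as NB with median-of-ratios size factors
and a fixed per-region dispersion. The dispersion pipeline is
deliberately simple and fully specified:

1. moment estimate on normalized counts,
   `alpha_mom = max((s² − m)/m², 1e-8)`;
2. a robust (`MASS::rlm`) linear trend of `log alpha` on `log m`, fit on
   rows not stuck at the floor;
3. geometric-mean shrinkage halfway toward the trend.

The GLM is fit by IRLS with a log link and log size-factor offsets, the
Wald statistic uses the normal approximation, and BH adjustment runs
within each contrast over converged regions only. Known deltas against
the reference tool this emulates, all intentional: no LFC shrinkage, no
independent filtering, no outlier replacement, and a design-free
dispersion estimate. The last point matters: because the moment estimator
sees group differences as variance, dispersions at truly differential
regions are inflated and the test is mildly conservative. The test suite
quantifies this by cross-checking against DESeq2 on a small matrix
(log2FC correlation > 0.97; our adjusted p-values run slightly higher),
and the null simulations (10,000 regions, n = 20, no effects) show
near-uniform p-values (KS D around 0.03) with zero BH discoveries —
conservatism, never anticonservatism.

The stabilized signal is `log2(count/s + 1)` with optional per-region
Z-scoring. It is monotone, parameter-free and adequate for heatmaps,
classifiers and the QTL regression; it is not the reference VST, and low
counts retain somewhat more variance under it.

Selection gates follow the field's conventions: DASs at padj < 0.05 and
|log2FC| ≥ 1; subtype-enriched DASs additionally significant in exactly
one one-vs-rest contrast; progenitor identity loci at padj < 0.005
without the exclusivity requirement. Subtype contrasts accept sample
covariates (entered as fixed-effect columns, categorical ones one-hot
against a reference level); the progenitor and B-ALL-vs-Pro-B contrasts
default to no covariates, each with a flag.

## Classifiers

The k-NN cell-of-origin model votes among `k = 5` Euclidean neighbours on
locus-Z-scored stabilized signal; neither k nor the metric is dictated by
the problem, so both are parameters. Vote ties break to the single
nearest neighbour's label, which keeps leave-one-out cross-validation
exactly reproducible by a naive refit loop (a tested equivalence).

The stepwise PCA-LDA classifier centres and scales features, takes the
SVD, and applies LDA on the leading `n_pc` components with the pooled
within-class covariance regularized as `(1−γ)S + γ·diag(S)`, `γ = 0.1`
by default — with far more features than samples some shrinkage is
needed for a stable inversion even after PCA. `n_pc` is selected by
internal LOOCV over `2..min(50, n−2)`, ties to the smallest value, and
the final model is refit on all samples. Two caveats are worth stating
plainly. First, LOOCV refits the PCA and LDA in every fold but keeps the
DAS feature set fixed, because the catalog is derived once from the full
cohort; the reported accuracy therefore carries the optimism of
full-cohort feature selection, exactly as in the workflow it reproduces.
Second, prediction is by nearest class mean in discriminant space under
the regularized metric, with exact ties resolved to the lexicographically
first label; with `γ = 0` and equal class sizes this coincides with
classical LDA (tested against `MASS::lda`). Validation cohorts are
normalized independently (their own size factors) before projection; a
joint-normalization flag was considered and rejected as the default
because a deployed classifier cannot renormalize its training cohort for
every query.

## Footprint scores

An insertion profile covers `[−w_out, motif, +w_out]` with
`w_out = 50`; the score normalizes the profile to mean 1 and subtracts
the mean over the motif core from the mean over `w_f = 30` flanking bases
on each side, with no gap. Scores are undefined below
`min_cov = 20` insertions per window. The windows are conventional
rather than derived — the cited footprinting literature uses comparable
spans — and all three are arguments. There is no Tn5 hexamer bias
correction: that requires genome sequence context the pipeline does not
consume; a bias-table hook is the natural extension point. Group
profiles are pooled across samples before scoring, matching the
merged-signal design of the subtype comparisons.

Bound/unbound calling fits a two-component Gaussian mixture by EM
(mclust, whose model-based hierarchical initialization is deterministic);
an occurrence is bound when its posterior for the upper-mean component
exceeds 0.5. Degenerate fits — components within 0.1 pooled standard
deviations, or constant scores — fall back to a mean + 1 sd threshold.
Differential footprinting pairs per-occurrence scores across groups, so
the permutation null is a sign-flip of the paired differences: exact
antisymmetry under group swap and seeded reproducibility come for free.
The per-subtype signature statistic is the **median** over all other
subtypes of the pairwise mean score difference, computed on signed (not
absolute) differences — the selection deliberately seeks enrichment, not
mere difference — and top-`n` selection breaks ties lexicographically by
motif id.

## The two-part QTL test

The joint-likelihood machinery of specialized QTL callers is replaced by
an explicit, testable composition: an OLS regression of stabilized signal
on alt dosage (covariates projected out exactly by residualization), an
exact binomial test of pooled allelic imbalance at heterozygotes
(optionally beta-binomial with moment-estimated overdispersion when at
least five heterozygotes are available; its two-sided p-value uses tail
doubling, which stays monotone even when the moment fit lands in the
U-shaped regime), Fisher's combination when both arms exist, and BH
across all pairs for the genome-wide 10% FDR. Gates — `min_het = 2`,
`min_reads = 10`, `min_maf = 0.05` — exist to block degenerate tests and
are all configurable; a missing imputation R² is treated as a directly
genotyped variant and passes the R² ≥ 0.80 filter. FDR is per variant;
a per-region lead-variant flag (smallest combined p, position breaking
ties) is emitted alongside for region-level summaries.

In the genotype generator the causal effect scales a region's NB mean by
`2^(β·dosage/2)`, so β is the log2 difference between the two homozygote
classes and the per-allele regression slope is β/2. Recovery tests
assert the slope on that scale; detection of the planted β = 0.5,
π = 0.7 effects at n = 60 is driven jointly by the two arms, with the
allelic arm contributing most of the power at typical read depths.

## Activity-by-contact and networks

Element activity is the geometric mean of ATAC and H3K27ac signal;
contact is the strongest loop score linking the element to the gene's
promoter window (zero without a loop), candidates are confined to 2 Mb
around the TSS (the loop-span rule), and scores are normalized per gene
so they sum to one. An element overlapping the promoter window plays the
promoter-candidate role and inherits the gene's maximum observed contact
(standard ABC practice; configurable off). The candidate universe
defaults to the enriched DASs supplied by the caller — the network stage
is about subtype regulation, not genome-wide enhancer discovery — and a
caller who wants all ROIs simply passes them. Edges require a bound
motif occurrence inside an enriched DAS with a retained (≥ 0.04) ABC
link to a gene in the supplied gene set; TFs rank by mean differential
footprint signal and genes by expression before truncation.

## What the synthetic cohorts emulate — and what they do not

The default cohort plants 10 subtypes × 8 samples over 20,000 regions:
log-normal region baselines (mean count 50), log-normal dispersions
around 0.2, log-normal size factors, and 1% of regions per subtype
elevated by log2 effect 2. One subtype pair shares 60% of its enriched
block, reproducing the confusability of molecularly related subtypes — in
real cohorts the kinase-activated pair — so that class merging visibly
recovers accuracy. Desk-scale choices (5 cohorts, 20 null-QTL cohorts of
5,000 pairs, 10 calibration seeds of 10,000 regions, staircase recovery
at n = 10 per stage — the same per-group scale the planted-effect
recovery checks use) keep the full suite and the acceptance script within
minutes on a single CPU.

The generators cover the statistical structure the pipeline assumes —
NB counts with planted effects, staircase progenitor loci, Poisson
insertion profiles with core depletion, Hardy-Weinberg genotypes with
dosage and imbalance effects, loops and histone states with recorded
truth — and deliberately not the things the pipeline does not model:
GC and mappability structure, correlated neighbouring regions, sample
contamination or subtype label noise, linkage disequilibrium between
variants, or Tn5 sequence bias. Passing tests therefore demonstrate that
the implementations are correct and calibrated under their stated
assumptions, not that those assumptions hold in any particular real
cohort; on real data the classifiers are expected to be less clean than
the near-perfect synthetic accuracies.

## Numerical choices and degenerate inputs

IRLS caps the linear predictor at ±30, flags non-convergence after 50
iterations (those regions get missing p-values and are excluded from
BH), and solves the 2×2 normal equations in closed form across all
regions simultaneously for plain two-group designs — the path the
one-vs-rest loop takes. Size factors require at least one all-positive
region and fail loudly otherwise, pointing at a pseudo-reference
fallback rather than silently switching to one. Constant count rows
floor the dispersion at 1e-8; constant footprint scores yield no bound
calls; constant dosages skip the pair; empty query sets in overlap
fractions are an error because the fraction is undefined. Every
stochastic routine takes an explicit seed, and permutation p-values use
the add-one estimator `(1 + #{|perm| ≥ |obs|})/(B + 1)`, which can never
return zero.

## Known limitations

The Wald test is mildly conservative at small n (design-free
dispersions, no shrinkage of effect estimates). LOOCV accuracy inherits
full-cohort feature-selection optimism, as discussed. The footprint
model ignores sequence bias and scores pooled group profiles, so it has
no notion of per-sample footprint variability. The QTL combination
treats its two arms as independent, which is approximately but not
exactly true (both derive from the same reads); Fisher's method is
therefore slightly anticonservative in principle, in practice offset by
the conservative gates — the simulated null FDR stays well inside the
nominal 10%. ABC contacts use raw loop scores with no distance model;
elements without loops get zero contact rather than a power-law
pseudo-contact.
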