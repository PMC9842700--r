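---
title: "Methods: imaging transcriptomics of fMRI-defined cortical regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: imaging transcriptomics of fMRI-defined cortical regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imagetx)
```

`imagetx` characterizes fMRI-defined brain regions by anatomical gene
expression: it takes Allen Human Brain Atlas (AHBA) style per-donor
microarray bundles and thresholded statistical-map masks, and asks which
genes, gene sets and cell types distinguish the samples falling inside the
masks from the rest of the left cortex. This vignette is the package's own
account of the statistical choices, stage by stage, together with what the
synthetic benchmark does and does not establish.

## Probe selection

Microarray probes are noisy, redundant proxies for genes. Two gates reduce
them to one representative probe per gene:

* **Detection filtering.** A probe is retained when its binary
  detection call (signal above background) holds in at least `min_fraction`
  of samples, default 0.5, *inclusive* — a probe detected in exactly half
  the samples stays. Detection is pooled across all samples of all donors
  jointly; which sample universe feeds this filter is exposed as an
  argument because detection could also be assessed per donor or on a
  sub-selection, and the pooled-across-everything choice is the most
  conservative reading of "across all subjects".
* **RNA-seq concordance collapse.** For each annotated gene, the Spearman
  correlation of every surviving probe against the gene's RNA-seq profile
  is computed on the samples shared between platforms (at least 3 required,
  otherwise the correlation is undefined and the stage aborts). The probe
  with the highest correlation wins; ties resolve to the lexicographically
  smallest probe id so the result never depends on input order. A gene is
  dropped entirely if it is absent from the RNA-seq rows, all-zero across
  the matched samples (our operationalization of "not detected by
  RNA-seq"; no threshold beyond zero is imposed), or if its winning
  correlation falls strictly below `rho_min = 0.2`. Spearman uses average
  ranks (Pearson on mid-ranks), so ties are deterministic; the strict
  `< 0.2` rule is guarded by a 1e-9 tolerance so that correlations whose
  exact value sits on the threshold are not dropped by floating-point
  representation.

Every exclusion is recorded with a reason (`low_detection`,
`not_in_rnaseq`, `low_rnaseq_correlation`, `outcompeted`); kept and dropped
probes partition the annotated input, which the tests assert.

## Spatial mapping

Sample coordinates are world-space MNI millimetres; voxel and world space
only meet through the mask's 4×4 affine. A sample's mask value is the
trilinear blend of the 8 voxels surrounding its continuous index
coordinate; points outside the voxel-centre bounding box score 0 (no
extrapolation). A sample is *affected* when its value under the union
(maximum) of the supplied masks reaches `threshold`, default 0.5,
*inclusive*. The inside/outside rule for fractional interpolated values is
a declared package choice, not something the analysis tradition pins down:
0.5 makes binary-mask membership coincide with nearest-neighbour membership
while keeping the rule continuous in the mask values. Samples whose
structure label is not in the cortical selection, or which sit in the right
hemisphere, are *excluded* before any mask arithmetic; affected and control
labels partition the cortical selection.

Masks drawn on the right hemisphere are used on the left cortex by
negating the sample x-coordinate before lookup — an exact world-space
mirroring that avoids resampling the volume. The mirrored-mask equivalence
(mirroring right masks equals using pre-mirrored left masks, sample for
sample) is a tested invariant.

## Normalization

Donor identity is the dominant nuisance axis in multi-donor atlas data.
Three passes, in a fixed order:

1. **Batch removal.** Per gene, ordinary least squares on an intercept plus
   sum-to-zero donor contrasts; fitted batch terms are subtracted, the
   grand intercept retained. For a one-factor design this is the closed
   form `x − (donor mean − unweighted mean of donor means)`; the tests pin
   it against a dense OLS oracle and against `limma::removeBatchEffect`.
   A single-donor input is returned unchanged. No covariates are modelled:
   RNA-quality corrections are assumed done upstream by the atlas provider.
2. **SRS across samples.** Per gene row, the scaled robust sigmoid
   `x_y = 1/(1 + exp(−(x − median)/(IQR/1.35)))` followed by min–max
   rescaling of the *sigmoid values* to [0, 1]. Quartiles use
   linear-interpolation (type 7); 1.35 is kept verbatim as the normal
   consistency constant. The transform is strictly rank-preserving for
   non-degenerate input.
3. **SRS within samples.** The same two formulas applied within each sample
   column across genes, to absorb sample-specific gene outliers. The pass
   can be disabled (`within_sample = FALSE`) for ablation.

Degenerate scales fall back in a fixed order: zero IQR → 1.349×MAD; both
zero with unequal values → standard deviation; all values equal (or a zero
range after the sigmoid) → 0.5 everywhere. These rules keep the map total
and rank-preserving wherever ranks are defined.

The pipeline normalizes the analysis subset (affected + control samples)
rather than all loaded samples; with per-gene donor-mean removal and
rank-preserving scaling the distinction is minor, and normalizing exactly
the modelled samples keeps the batch design aligned with the DE design.

## Differential expression

The affected/control contrast is fitted per gene by generalized least
squares under a block-exchangeable correlation: correlation `rho` between
any two samples of the same donor, 0 otherwise. The model matrix is an
intercept plus affected indicator; a covariate hook exists but nothing is
added by default, since the contrast of interest is anatomical and donors
are already modelled twice (batch means, residual correlation).

* **Consensus correlation.** Per gene, a moment estimator from OLS
  residuals: the within-donor excess covariance relative to the residual
  variance, corrected exactly for the OLS projection through the trace
  identities `E[r'Ar] = σ²(tr(AM) + ρ tr(AMAM))`,
  `E[r'r] = σ²(n − p + ρ tr(AM))`, where `A` pairs samples within donors
  and `M` is the residual projector. Without this correction the fixed
  effects absorb part of any shared donor component and the estimate is
  visibly attenuated when donors are few. Per-gene estimates are clamped to
  ±0.99, pooled by a 15%-trimmed mean on Fisher's z scale and transformed
  back. All-singleton blocks return 0 with a warning. The tested acceptance
  surface is parameter recovery (truth 0.3 recovered within ±0.05 at 2000
  genes; truth 0 within ±0.03), not bit-equality with any REML iteration.
* **GLS by whitening.** The block-exchangeable correlation has a
  closed-form inverse square root, so each donor's rows are whitened
  analytically and a single ordinary fit serves all genes. `rho = 0`
  reduces exactly to OLS; a rank-deficient whitened design is fatal.
* **Empirical-Bayes moderation.** A scaled-F prior for the residual
  variances is fitted by matching the first two moments of `log s²`
  (digamma/trigamma equations; the trigamma inverse is solved by Newton
  iteration on `1/trigamma`, which is nearly linear). Posterior variances
  `(d0·s0² + df·s²)/(d0 + df)` feed moderated t-statistics with `df + d0`
  degrees of freedom, two-sided p-values. When the spread of log variances
  does not exceed sampling noise the prior degrees of freedom are infinite
  — complete pooling, every gene sharing the prior variance. This is the
  documented limit of the reference method, and it is the *typical* regime
  after SRS normalization, whose unit-interval scaling strongly homogenizes
  gene variances. Genes with exactly zero residual variance are assigned
  the prior variance and flagged. The whole path is pinned against limma
  (`lmFit` + `eBayes` at a shared correlation) to 1e-6 in the tests.
* **Calls.** BH step-up adjustment; significant means strictly `q < alpha`
  (default 0.05), split into higher/lower by the sign of the coefficient.

## Differential stability

DS measures whether a gene's regional expression pattern reproduces across
donor brains: expression is averaged per (donor, structure) cell, and DS is
the mean over donor pairs of the Pearson correlation between the two
donors' structure-mean vectors, restricted to structures both donors
sampled (pairs sharing fewer than 3 structures, or with a constant profile,
contribute nothing; genes with no contributing pair are excluded and
reported). DS is invariant to per-donor affine rescaling, which the tests
assert. DS for DE versus other genes is compared by a two-sided
Mann–Whitney U test — exact enumeration for tie-free groups of at most 20,
otherwise the tie-corrected normal approximation with continuity
correction; the reported U follows the first-group rank-sum convention.
The module recomputes DS from the data so the pipeline is self-contained,
and also accepts an external gene→DS table (`ds_table_path`) to reproduce a
cross-referencing workflow against published DS values.

## Enrichment

All set statistics are hypergeometric: `p = P(X ≥ k)` for an overlap of
`k` query genes with a set of `K` background members, drawing `n` from `N`.
The background is the gene universe covered by the selected probes; sets
are intersected with it before testing, and a set left empty is skipped —
the fold-enrichment ratio `(k/n)/(K/N)` is undefined at `K = 0`. The tests
pin the tail probability against exhaustive enumeration for all small
universes. One-tailed overrepresentation is assumed throughout (the
convention is recorded in the output); an EASE-style conservative variant
(one overlap gene discounted) sits behind `ease = TRUE`.

Two significance conventions coexist deliberately: cell-type marker sets
use Bonferroni-adjusted `p < 0.05` after discarding sets with fewer than
five markers ("at least five" keeps size-5 sets), while functional terms
use fold enrichment > 1 together with BH `q < 0.05`. Disease signature
sets are built from `(gene, disease, logFC, q)` tables with an inclusive
`q ≤ 0.05` gate and strict `|logFC| > 0.1` gates; empty sets are retained
with a warning, because tightening these gates is known to empty them.
Trimmed-mean cell-type expression log2-transforms with a +1 pseudocount
(the upstream transform of such matrices is not standardized; the choice is
recorded in the output), drops the `floor(n/4)` lowest and highest cells
per (gene, cell type) and averages the rest; types with fewer than 4 cells
cannot be trimmed and are excluded. Cell-type-exclusive DE genes — positive
trimmed mean in exactly one type, or one type carrying ≥ 90% of the gene's
mass — are reported as indications, never as significance calls.

## The synthetic benchmark

`simulate_atlas()` generates the full input surface from one seed:
gene-level expression `baseline + donor offset + inside-mask effect +
correlated residual`, probes nested in genes with a designated best probe
(lowest noise, highest detection rate), Bernoulli detection calls, RNA-seq
companions for the first donors, mirrored left/right box masks on a 40×48×40
grid with 2 mm spacing, and marker sets with controlled overlap with the
planted genes. Defaults are the package's study conditions: 6 donors × 210
samples, 2000 genes, 60 samples inside the mask versus 1200 outside
(mirroring a 61-versus-1224 style design), donor offset SD 0.8, residual SD
0.4, intra-donor correlation 0.3, 50 planted genes at 1.0 residual-SD, two
RNA-seq donors with noise SD 0.2 — values chosen once as realistic for
donor-dominated atlas data and held fixed. Probe counts per gene are
allocated deterministically from the configured proportions so shapes and
identifiers depend only on the configuration, never the seed. Inside
samples are placed at least one voxel clear of the mask boundary and
outside samples at least one voxel away from it, so trilinear membership is
unambiguous and the affected count is exact by construction.

Two donor-driven phenomena are planted separately on purpose: additive
per-donor offsets (exactly what linear batch removal eliminates) and an
exchangeable intra-donor residual correlation (what the consensus
correlation stage must recover). Note their interaction: a shared
donor-level residual component is, within one realized dataset,
indistinguishable from a batch offset, so after batch removal the residual
intra-donor correlation is essentially spent — the pipeline's consensus
estimate on normalized data is near zero, and correlation recovery is
therefore benchmarked on data where batch removal has not absorbed it.

What the generator does *not* emulate, and what passing therefore does not
show: real cortical geometry and parcellation ontologies (structure labels
are uniform draws, so regional expression patterning is not reproducible
across donors and DS is near zero for every gene — the DS stage is
validated on dedicated fixtures instead); RNA-degradation covariates;
probe-level cross-hybridization; non-additive batch structure; and any
relationship between marker sets and real cell biology. Headline results
from the original atlas analyses (specific gene lists, specific enrichment
terms) require the atlas download and external databases and are outside
what the desk-scale benchmark can reproduce.

## Problem sizes and runtime

The shipped tests and the acceptance script run the full pipeline at the
default 2000 × 1260 scale, correlation recovery at 2000 genes × 600
samples, prior recovery at 5000 variances, and the null type-I measurement
at 5000 genes × 1260 samples — sizes chosen so the complete validation
executes in a few minutes on one core while leaving the statistical bands
(recall ≥ 0.8, FDR ≤ 0.1, ρ ± 0.05, prior ± 20%, type-I in [0.04, 0.06])
well-powered. All randomness flows from explicit seeds; repeated runs are
bit-identical, including the written CSV/NIfTI/GMT fixtures.
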