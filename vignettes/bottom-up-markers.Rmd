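---
title: "Bottom-up marker discovery: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bottom-up marker discovery: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(spatmark)
```

spatmark implements a bottom-up biomarker discovery workflow for
imaging-based single-cell spatial transcriptomics of mixed-histology tumors.
The idea: operationally define the tumor fraction of a tissue from its
transcriptome (keratin-positive clusters), stringently remove histologically
normal epithelium that clustering alone cannot separate from tumor, screen
for genes whose *detection* — not abundance — is confined to tumor cells,
characterize those genes across histological subtypes and coexpression
networks, and finally test whether one selected marker stratifies survival
in an independent bulk cohort. This vignette documents the models behind
each stage, the tunable parameters, the numerical conventions, and what the
synthetic data generator does and does not emulate.

## The spatial stage, step by step

### Area normalization

Tumor cells are hypertrophic: cell area and total transcript count rise
together, so any abundance comparison between cells of different sizes is
confounded by geometry. Expression is therefore rescaled to transcript
density,

$$e_{gc} = 100\,\frac{x_{gc}}{A_c},$$

in counts per 100 µm², where $x_{gc}$ is the raw count of gene $g$ in cell
$c$ and $A_c$ the segmented cell area in µm². The transformation preserves
the sparsity pattern exactly and is invertible: multiplying back by
$A_c/100$ and rounding recovers the integer counts (a tested identity).
Detection-based statistics (dropout rates, positivity) are always computed
on raw counts, because a zero is a zero at any cell size.

### Clustering and the keratin call

`cluster_cells()` follows the contract of the standard imaging-platform
pipeline: PCA of the scaled normalized expression (default `n_pcs = 50`), a
k-nearest-neighbor graph in PC space (`k_neighbors = 15`), shared-nearest-
neighbor Jaccard edge weights with the conventional 1/(k+1) prune, and
Leiden community detection. We use the modularity objective: at the default
`resolution = 1.0` it returns exactly one community per well-separated
population on two-population benchmarks, which the CPM objective does not at
the same nominal resolution. Clusters are renumbered in descending order of
cell count, so cluster 1 is always the largest. All stochastic steps are
seeded; a fixed seed reproduces labels exactly.

The keratin score of a cell is the *sum* of its normalized KRT7 and KRT15
counts. Per cluster, `keratin_log2fc()` computes
$\log_2\!\big((\bar s_k + \varepsilon)/(\bar s_{-k} + \varepsilon)\big)$,
the mean score in the cluster against the mean over all other cells, with
pseudocount $\varepsilon = 10^{-9}$ guarding empty complements. A cluster is
keratin-positive iff its log2FC is strictly positive (a fold change of
exactly zero is negative). Summing the two keratins — rather than taking
their ratio — mirrors how pan-keratin staining is read in diagnostic
pathology: either keratin marks the epithelial compartment, and the two
genes jointly approximate the keratin classes a pan-keratin antibody
covers. Tumor content is then the proportion of cells in keratin-positive
clusters.

### The ROI audit and the failure mode it exists for

Keratin expression cannot distinguish normal epithelium from carcinoma: in
tissues containing normal epithelial foci, those cells land inside
keratin-positive clusters and silently inflate the tumor fraction and
contaminate the marker screen. `compare_positivity()` audits annotated
regions: per keratin-positive cluster with members on both sides of the ROI
boundary, a two-sided Fisher exact test of EPCAM detection
(positive/negative × inside/outside), BH-corrected across clusters. Normal
epithelium is EPCAM-low while carcinoma is EPCAM-high, so audited foci show
up with small q-values, and `exclude_cells()` removes them with a logged
reason. Per-cluster testing is the default because the audit is reported
per cluster; a pooled mode is available. Points on an ROI boundary count as
inside, and ties between ROIs resolve by region file order.

After exclusion, the tumor-content estimate counts keratin-positive cells
*minus* the excluded normal cells in the numerator, over **all** cells of
the tissue in the denominator. Exclusion reclassifies cells — the normal
epithelium is still part of the tissue — so the denominator never shrinks.
This is the purity interpretation under which the estimate is comparable to
orthogonal tumor-purity estimates, and it is the convention the recovery
tests use.

### Dropout-quadrant screening

The dropout rate of a gene in a fraction is the proportion of cells with
zero raw counts. With tumor cells = keratin-positive (post-exclusion) and
non-tumor = everything else, the plane $(d_N, d_T)$ is cut at
$\tau = 0.75$ into four categories: **tumor-specific** ($d_T < \tau$,
$d_N \ge \tau$), **normal-specific** (the mirror), **common-positive**
(both $< \tau$) and **common-negative** (both $\ge \tau$). The "expressed"
side uses strict `<` and the "dropout" side `>=`, so the four categories
partition the unit square for any $\tau$; at realistic cell numbers the
boundary carries negligible probability mass. Tissues in which some
keratin-positive clusters are themselves histologically normal are handled
by a per-cluster override table (`tumor_mask()`): whole clusters can be
reassigned to the non-tumor fraction before screening.

Candidate markers are ranked by *total raw expression in tumor cells*,
descending, ties alphabetical; the default ranking pool is all genes (so
the top-K list may legitimately contain common-positive genes), with a
strict tumor-specific-only variant available. Per-cluster heatmap summaries
z-score each gene's cluster means across clusters using the population SD
(recorded in the output metadata); a gene with identical cluster means gets
all-zero z-scores rather than 0/0. Gene lists from independent samples are
intersected as plain sorted sets.

### RGB color-space mapping

For visualization, the normalized expression of keratin-positive cells is
reduced to three components and mapped to color: component $i$ is affinely
rescaled so its minimum is 0 and its maximum 255, rounded to the nearest
integer half-away-from-zero, and assigned to (R, G, B) in component order.
A degenerate constant component maps to 0; no outlier clipping is applied
before rescaling. The scaling is invariant to positive-slope affine
transforms of a component. The default reducer is UMAP (uwot, fixed seed,
single-threaded optimization so runs are bit-reproducible); the backend is
pluggable and a deterministic 3-PC linear reducer is provided for fast
testing. Embeddings are computed within one sample only — colors are never
comparable across samples. The treemap summary tiles the tissue bounding
box (default 8 × 8) and reports, per tile, each cluster's cell count and
mean color; tile membership uses half-open `[lo, hi)` intervals in x then
y, with the far domain edge closed so no cell is lost.

### Coexpression networks

Within each histological subtype (cells annotated by containing tumor
region; subtypes may be pooled across samples first), pairwise gene–gene
association uses the biweight midcorrelation: observations are
median-centered and Tukey-biweighted with $u_i = (x_i - \mathrm{med})/(9\,
\mathrm{MAD})$, $w_i = (1-u_i^2)^2\,\mathbf 1[|u_i|<1]$, and the weighted
vectors are correlated. The MAD is unscaled (no 1.4826 consistency factor)
and the tuning constant is 9, the standard definition of the statistic.
When a vector has zero MAD (more than half its values tied at the median),
the pair falls back to Pearson and is flagged. bicor is computed on
area-normalized expression by default (consistent with the normalization
rationale), with raw counts available as an option. Networks keep an edge
when $|\mathrm{bicor}| \ge 0.2$ (a threshold is needed to draw a discrete
graph; fully configurable), retain the sign, and size nodes by mean
subtype expression.

### Bulk projection

The bulk stage dichotomizes the cohort at the marker's median — `high` is
strictly above the median, ties go to `low` — making the split invariant to
monotone transforms. Kaplan–Meier curves, the two-group log-rank test, and
a multivariable Cox model (marker-high indicator plus stage, age, smoking,
sex; Efron tie handling, which biases less than Breslow under ties) come
from the survival package behind the module surface. Stage enters
dichotomized I/II vs III/IV by default, matching the subgroup axes the
analysis reports. Subgroup analyses (stage strata, EGFR/KRAS wild-type) are
row filters applied *after* the full-cohort median split, so a patient's
group label does not depend on which subgroup panel is being drawn; this
choice is recorded in the run metadata. Mutation enrichment between marker
groups uses two-sided Fisher exact tests (conditional-MLE odds ratio
convention) with BH correction. A Cox fit that fails to converge or hits
complete separation raises an error rather than returning clipped
estimates.

## The synthetic-data generator

Real datasets of this kind are controlled-access patient data, so the
package carries a generator whose defaults define the study conditions for
all recovery tests.

**Geometry.** A 2600 × 1600 µm domain with four rectangular histology
blocks — ADC (density 25 cells per 10⁴ µm²), SCC (15), TTF1neg_p40neg
(12), stromal non_tumor (35) — and two circular normal-epithelium foci
(r = 150 µm, density 35, ≈ 200–250 cells each) in the central corridor,
so no two regions with different labels overlap. Cells are placed by a
homogeneous Poisson process per region; the realized fraction of cells in
tumor-labeled regions is the ground-truth tumor fraction. Densities were
chosen once to give a desk-scale tissue of ~7,500–8,000 cells with a tumor
fraction near 0.56 and ADC as the largest component, and foci large enough
(≥ 200 cells) for the audit's per-cluster Fisher tests to be well powered.

**Cell geometry.** Cell areas are log-normal per label; tumor labels use
meanlog log(150 µm²) against log(80 µm²) for stroma (tumor-cell
hypertrophy, enforced as a config invariant), normal epithelium log(120)
in between. Nucleus area is a uniform 0.2–0.5 fraction of cell area.

**Counts.** Gene counts are Poisson with mean
$\mathrm{rate}(\ell, g) \cdot A_c / 100$ for label $\ell$, optionally
zero-inflated per gene (default 5 % technical dropout everywhere). This is
the simplest generative model that reproduces the area–count relationship
and gives direct control of dropout quadrants; rates are expected counts
per 100 µm², so normalized expression estimates the rate directly.

**The 120-gene panel** (a desk-scale stand-in for a ~400-gene targeted
panel) plants every structure the pipeline must recover: KRT7/KRT15
expressed in tumor *and* normal epithelium but not stroma; EPCAM high in
tumor, low (rate 0.15) in normal foci; an SLC2A1-like gene with monotone
SCC > TTF1neg > ADC rates (4.5/2.2/0.8) and near-zero normal/stromal
expression; 20 tumor-specific genes (rates 0.8–2.0 in tumor, 0.03 in
stroma); 20 common-positive, 20 common-negative, 20 stroma-specific genes;
34 broadly expressed fillers; and a co-regulated pair (COEXA/COEXB) driven
by a shared mean-preserving log-normal latent factor in SCC cells only.
The per-subtype expression magnitudes are free parameters with no external
referent; they were fixed once so that each planted gene's *expected*
dropout rates sit well clear of the 0.75 boundary at these cell numbers,
and the latent-factor SD (1.0) so that the planted pair is recoverable by
the robust bicor statistic, which deliberately downweights the tail
observations a log-normal factor produces (at SD 1.0 the planted bicor is
≈ 0.6 in SCC and ≈ 0 elsewhere).

Critically, the normal foci track the ADC expression program closely
(same tumor-specific and filler rates up to a few percent) except for
EPCAM and SLC2A1. This is what makes the generator honest: conventional
clustering *cannot* separate the foci from tumor — in the default tissue
> 95 % of normal-focus cells land in keratin-positive clusters — so the
ROI audit has real work to do, and a pipeline that skipped the audit would
overestimate tumor content by the focus fraction.

**What the generator does not emulate:** spatial autocorrelation of
expression within a region beyond label effects, segmentation errors and
doublets, cell-size–dependent capture efficiency, batch effects between
samples, and any mutation process beyond Bernoulli flags in the bulk
cohort. Passing recovery tests therefore demonstrate correctness of the
*analysis logic* under the stated generative model, not robustness to
artifacts real tissues add on top.

**Bulk cohorts.** Marker expression is log-normal; event times are
exponential with
$\log h = \log h_0 + \beta\,\mathbf 1[\mathrm{expr} > \mathrm{median}] +
\beta_{\mathrm{stage}} + \beta_{\mathrm{age}} + \beta_{\mathrm{smoking}} +
\beta_{\mathrm{sex}}$,
baseline median survival 60 months, covariate effects (HR 2.2 for stage
III/IV, 1.25 per decade of age, 1.2 smoking, 1.1 male) and prevalences
chosen as typical of an adenocarcinoma surgical cohort. Censoring is
independent uniform with the horizon calibrated by root-finding so the
realized censoring proportion matches the target (default 0.3). Because
the fitted Cox model is correctly specified for this generator, the
planted log hazard ratio is recoverable and its 95 % CI covers the truth
at the nominal rate (tested across 50 seeded cohorts of n = 1000).

## Reproducibility and problem sizes

One integer seed drives every RNG stream; sub-streams are derived by fixed
offsets (placement/geometry, then counts), so adding genes never perturbs
cell positions. Identical configs and seeds reproduce byte-identical
artifacts across runs, including the UMAP stage. The test suite runs the
full spatial flow once on the default ~7,700-cell tissue and caches it;
recovery experiments use 50 cohorts of n = 1000 for CI coverage and 20
null cohorts of n = 400 for log-rank calibration; the end-to-end
determinism check uses a reduced-density tissue (~2,600 cells) with both
stages run twice. These sizes were chosen as the smallest at which the
planted effects are comfortably identified.

## Known limitations

- The keratin call is transcriptional; keratin-positive normal epithelium
  is only removed where region annotations exist (the audit quantifies,
  it does not discover — ROIs are user-drawn).
- Dropout-quadrant screening is threshold-based; genes whose true rates
  put their dropout near $\tau$ will classify unstably at small n.
- The embedding backend contract guarantees determinism per seed, not
  stability of colors across parameter changes; colors are per-sample.
- `positivity_rate()` treats a single transcript as detection; there is no
  background-correction model.
- Subtype annotation is region-based; transcriptional subtype mixing
  within a region is not modeled.
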