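# spatmark

Bottom-up tumor-marker discovery: from imaging-based single-cell spatial
transcriptomes to bulk prognostic stratification.

## The problem

Imaging-based spatial transcriptomics resolves rare and transitional tumor
cell states that bulk profiling averages away — but turning those spatially
defined states into clinically usable biomarkers requires a chain of
operational steps that each hide pitfalls: deciding which cells are tumor
without ground-truth labels, removing histologically normal epithelium that
clusters together with carcinoma, screening for genes whose signal survives
dilution into bulk tissue, and validating the survivors in an independent
cohort. spatmark implements that chain as a tested, reusable pipeline for
mixed-histology tumors (the motivating setting is lung adenosquamous
carcinoma, with intermixed adenocarcinoma (ADC), squamous (SCC) and
TTF-1⁻/p40⁻ components), together with a synthetic-data module that
generates tissues and cohorts with known ground truth so every stage can be
scored.

## The method

- **Tumor fraction.** Expression is normalized by cell area,
  `e = 100·x/A` (counts per 100 µm²), removing the cell-hypertrophy
  confound. Cells are clustered by Leiden community detection on an
  SNN-weighted kNN graph in PCA space; a cluster is *keratin-positive* iff
  its summed KRT7+KRT15 signal has `log2((mean_in+ε)/(mean_out+ε)) > 0`.
  Tumor content = fraction of cells in keratin-positive clusters.
- **ROI audit.** Normal epithelium is keratin-positive too and co-clusters
  with tumor. Annotated foci are audited per cluster with a two-sided
  Fisher exact test of EPCAM detection inside vs outside (BH-corrected) and
  excluded, with the cell count conserved in an audit log.
- **Dropout screen.** Per gene, dropout rates `d_T`, `d_N` (fraction of
  zero-count cells) in the tumor / non-tumor fractions classify genes at
  τ = 0.75 into tumor-specific (`d_T < τ ≤ d_N`), normal-specific,
  common-positive and common-negative quadrants; candidates are ranked by
  total raw tumor expression and intersected across samples.
- **Characterization.** Gene × cluster z-scores, per-subtype positivity
  with between-subtype differences, RGB-UMAP (3 UMAP components rescaled
  to 0–255 → R,G,B, overlaid on tissue coordinates, summarized per spatial
  tile), and signed coexpression networks from the biweight midcorrelation
  (unscaled MAD, tuning constant 9) within each subtype.
- **Bulk projection.** Median split of the marker (ties → low),
  Kaplan–Meier + log-rank overall and in subgroups, multivariable Cox
  (marker + stage + age + smoking + sex, Efron ties), and Fisher/BH
  mutation enrichment between marker-high and -low groups.

## Worked example

Simulate the default tissue, call the tumor fraction, audit and exclude the
normal foci, and screen markers:

```r
library(spatmark)

sim  <- simulate_cells(sim_config(seed = 1))
#> Synthetic spatial dataset: 7659 cells, 120 genes
#>   true tumor fraction: 0.5578
#>   cells per label: ADC=2061, non_tumor=2893, normal=494, SCC=1189, TTF1neg_p40neg=1022

norm     <- normalize_by_area(sim$counts, sim$cells$cell_area)
clusters <- cluster_cells(norm, seed = 1)
kp       <- classify_keratin_clusters(keratin_log2fc(norm, clusters))
tumor_content(kp, clusters)
#> 0.622   # inflated: the normal foci are keratin-positive
```

The raw estimate overshoots the truth (0.558) because all ~494
normal-epithelium cells sit inside keratin-positive clusters — exactly the
failure mode the audit exists for. EPCAM positivity inside the foci is
~16 % against ~93 % outside:

```r
rois   <- Filter(function(r) r$label == "normal", sim$regions)
ra     <- assign_rois(sim$cells, rois)
kp_cell <- unname(kp[as.character(clusters)])
compare_positivity(sim$counts[, kp_cell], "EPCAM",
                   clusters[kp_cell], (!is.na(ra))[kp_cell])
#>   cluster n_inside n_outside pos_inside pos_outside odds_ratio         p         q
#> 1       1      288      2458      0.160       0.926     0.0152 1.62e-178 1.46e-177
#> 2       3       45       283      0.178       0.922     0.0187  9.66e-26  2.90e-25
#> ...
```

After exclusion the corrected tumor fraction is 0.558 — equal to the truth
to three decimals — and the screen recovers the planted markers:

```r
post <- exclude_cells(sim, ra, sapply(rois, `[[`, "region_id"), regions = rois)
keep <- match(post$cells$cell_id, sim$cells$cell_id)
prof <- dropout_profiles(post$counts, tumor_mask(clusters[keep], kp))
top_tumor_specific(prof, K = 5)
#>     gene    d_T   d_N       category total_tumor_expression rank
#> 1   KRT7 0.0824 0.959 tumor_specific                  16215    1
#> 2  EPCAM 0.0826 0.977 tumor_specific                  15357    2
#> 3  KRT15 0.0950 0.961 tumor_specific                  14510    3
#> 4 SLC2A1 0.1971 0.995 tumor_specific                  13809    4
#> 5   TS20 0.1098 0.978 tumor_specific                  12904    5
```

Project the SLC2A1-like marker onto a simulated bulk cohort (planted hazard
ratio 2.64 on the median-split indicator):

```r
bulk <- simulate_bulk_cohort(1000, beta = log(2.64), censor_rate = 0.3, seed = 1)
sv   <- bulk_survival(bulk$cohort, "SLC2A1")
sv$cox
#>          term   coef   hr lower95 upper95        p
#> 1 marker_high 1.1445 3.14   2.677    3.69 1.14e-44
#> 2       stage 0.7389 2.09   1.795    2.44 5.56e-21
#> 3         age 0.0191 1.02   1.010    1.03 2.38e-05
#> 4     smoking 0.2588 1.30   1.114    1.51 7.86e-04
#> 5         sex 0.0745 1.08   0.928    1.25 3.29e-01
sv$overall$logrank$p
#> 4.47e-47
```

The marker-high group carries a hazard ratio near the planted value after
covariate adjustment (the 95 % CI covers 2.64 in ≈ 95 % of seeded cohorts;
any single seed can miss), and the log-rank test separates the survival
curves decisively.

Both stages also run end to end from one config — `run_spatial_stage()`,
`run_bulk_stage()`, `run_pipeline()` — writing every intermediate artifact
(clusters, audit report, dropout profiles, top-K markers, z-scores, RGB
cell table, treemap, per-subtype bicor networks, KM curves, Cox table,
enrichment) plus a machine-readable report JSON. A thin CLI wrapper with
`simulate | spatial | bulk | all` subcommands is installed at
`inst/cli/spatmark`.

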