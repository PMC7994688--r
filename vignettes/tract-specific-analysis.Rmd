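---
title: "Tract-specific analysis: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tract-specific analysis: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tractsa)
```

## The problem

Diffusion tensor imaging (DTI) models water diffusion in each voxel as a
symmetric 3x3 tensor; fractional anisotropy (FA), a scalar in [0, 1]
derived from the tensor eigenvalues, drops where white-matter axons are
lost or poorly myelinated.  Tract-specific analysis (TSA) asks where,
on the medial sheet of an individual white-matter tract, FA differs
between groups — for example between sickle cell disease patients (SCD),
non-sickle anemic controls (ACTL) and healthy controls (CTL).  Unlike
whole-white-matter skeleton methods (TBSS), TSA builds one skeleton
surface per tract, so adjacent tracts such as the corpus callosum and
cortico-spinal tract are never conflated.

`tractsa` implements the statistical core of that pipeline:

1. **Projection** (`project_metric`): each skeleton vertex carries a unit
   normal and a half-thickness (distance to the tract boundary).  The FA
   volume is sampled by trilinear interpolation along the normal over
   `[-half_thickness, +half_thickness]` and the maximum (default) or
   mean is assigned to the vertex.  Max projection follows the original
   pipelines' practice of taking the locally maximal FA, which is robust
   to slight misregistration toward the tract boundary.
2. **Vertex-wise GLM** (`vertexwise_tstat`): at each vertex,
   `FA ~ group + age + sex`; the group coefficient's t statistic forms
   the statistical map.  Age and sex are nuisance covariates because both
   modulate FA independently of disease.
3. **Cluster-mass inference** (`permutation_fwer`): vertices with
   `|t| > t0` are grouped into edge-connected components; a cluster's
   *mass* is its surface area (sum of per-vertex barycentric area
   weights).  The null distribution of the *maximal* cluster mass,
   pooled over all tracts and both contrast directions, is built by
   permutation; comparing each observed mass against it yields
   family-wise-error (FWER) corrected p-values in the Nichols–Holmes
   sense, accounting for the number of tracts automatically.
4. **Per-tract summaries** (`tract_mean_fa`, `anova_by_tract`,
   `demographics_table`, `wmh_distribution`): unweighted vertex means
   per subject feed a one-way ANOVA across the three groups; the
   demographics table uses two-sample t tests (Bonferroni within the
   table) and Pearson chi-squared; white-matter hyperintensity (WMH)
   lesions are summarized by (region, hemisphere) counts and shares.
5. **Brain–behaviour association** (`correlate_tracts_measures`):
   Pearson correlations between per-tract mean FA and nine
   neurocognitive scaled scores within one group, with
   Benjamini–Hochberg (BH) step-up control at level q over the full
   11 x 9 = 99-test family.

## Key parameters

| parameter | default | meaning |
|---|---|---|
| `cluster_forming_p` | 0.01 | two-sided vertex-level tail probability defining `t0 = qt(1 - p/2, df)` at the design's residual df |
| `n_permutations` | 10,000 | label permutations for the pooled max-mass null |
| `fwer_alpha` | 0.05 | cluster-level family-wise significance level |
| `direction` | `"both"` | run patients-lower and controls-lower analyses against the shared pooled-maximum null |
| `mode` (projection) | `"max"` | max vs mean along the vertex normal |
| `step` (projection) | 0.25 x min voxel | sampling step along the normal, mm |
| `q` (association) | 0.05 | BH false-discovery-rate level over all 99 tract x measure tests |

The cluster-forming threshold deserves a note.  The upstream literature
describes `t0` as "arbitrarily chosen" and separately reports a
threshold p of .01 with 10,000 permutations.  We read .01 as the
*vertex-level, two-sided* cluster-forming probability and map it to `t0`
through the Student quantile at the residual degrees of freedom; the
cluster-level criterion stays at `fwer_alpha = .05`.  Both numbers are
exposed in `cluster_config()`, so the alternative reading (.01 as the
cluster-level criterion) is one argument away.

Permutation respects the nuisance covariates through the Freedman–Lane
scheme: residuals of the covariate-only (intercept + age + sex) fit are
permuted and the fitted covariate effects added back before recomputing
the full model.  Plain label permutation is only exact when covariates
are absent; Freedman–Lane keeps the permutation distribution close to
exact under the reduced-model null and is the standard choice in
neuroimaging permutation tools.  When the design has no covariates and
the number of distinct group splits is below `n_permutations`, all
splits are enumerated exhaustively instead.  The permutation p-value
uses the +1 small-sample correction, `p = (1 + #{max >= observed}) /
(B + 1)`, so p is never zero and significance at level alpha is an
exact rank event.

## The synthetic cohort: what it emulates, and what it does not

`generate_cohort()` emulates the statistical structure of a three-group
anemia study so every stage is testable without patient data:

* **Group sizes** 21 CTL / 26 SCD / 19 ACTL; ages drawn per group from
  normal distributions (22.6 ± 8.9, 24.2 ± 9.7, 26.1 ± 11.7 years,
  truncated at 10, the scanner-tolerance floor of such protocols);
  female counts fixed at the tabulated proportions (13/21, 13/26, 8/19).
* **Skeletons**: parametric curved rectangular sheets per tract
  (`generate_skeletons`), carrying the same contract as fitted medial
  surfaces — vertices, triangles, outward unit normals, positive
  half-thickness — without reimplementing the cm-rep surface fit, which
  is out of scope.  Resolution 14 gives 196 vertices per tract, the
  order of magnitude of real TSA meshes at acquisition resolution.
* **FA fields**: vertex FA = `fa_baseline` (0.55, a typical deep-white-
  matter value) + `age_slope`·(age − mean) (−0.001/yr, a mild adult
  decline) + `sex_offset`·1[female] (0.005) − `effect_delta` inside a
  geodesic disk (SCD tracts: CC by default; ACTL: CC + left IFO,
  mirroring the qualitative overlap of the anemic-control findings) +
  iid Gaussian noise with SD `fa_sd` (0.04, a plausible between-subject
  spread), clamped to [0, 1].  `effect_delta` defaults to `fa_sd`
  (one between-subject SD) and `effect_radius` to 7 mm, which covers
  roughly 10% of CC vertices at resolution 14.
* **Geodesic disks** use Dijkstra shortest paths on the edge graph
  rather than exact surface geodesics; at the test resolutions the two
  differ by less than an edge length, and the unit tests pin the disk to
  an independent relaxation oracle.
* **Scores**: each of the nine scaled scores (mean 10, SD 3) is built
  from the subject's CC mean FA standardized within the cohort:
  `score = 10 + 3(rho·z + sqrt(1 − rho²)·eps)`.  This bivariate-normal
  construction makes the FA–score population correlation exactly `rho`
  per measure (defaults: the nine reported study correlations,
  .23–.57); noise is independent across measures, so inter-measure
  correlations arise only through the shared FA latent — real
  psychometric batteries are more strongly inter-correlated.
* **WMH lesions**: exactly `total_count` (132) punctate lesions with
  diameters 3–5 mm, allocated multinomially over (region, hemisphere)
  cells with weights from the tabulated counts (frontal 47/39, parietal
  8/10, temporal 2/2; the 24 untabulated lesions go to an "other"
  region split evenly), owned by carrier subjects drawn at the tabulated
  per-group carrier rates.  Lesions do not perturb the FA fields: in the
  source data the lesions were small enough not to disturb tractography,
  and modelling their microstructural footprint is beyond scope.
* **DWI**: `generate_dwi()` produces single-shell signals
  (30 directions, b = 1000 s/mm², one b = 0) from a tensor field with
  Rician noise — magnitude-MRI's noise law — and `fit_tensor()` inverts
  them by log-linear ordinary least squares, the estimator implied when
  a tool rather than a method is cited.  Multiple b = 0 volumes are
  averaged; negative eigenvalues are clamped at zero and counted.

A green test on this generator therefore establishes that the
*statistics* behave correctly (error control, localization, correlation
recovery), not that the geometry or physiology of any real cohort is
reproduced: there is no registration error, no spatially correlated
noise, no crossing-fibre FA bias, no lesion–FA coupling, and the
skeleton sheets are smoother than fitted cm-rep surfaces.

## Numerical choices

* Projection samples always include both segment endpoints; samples
  falling outside the volume are excluded from max/mean, and a vertex
  whose whole segment is outside raises an error listing the vertices.
  Trilinear interpolation is used throughout (nearest-neighbour would
  make the refinement oracle in the tests unattainable).
* Vertex area weights split each triangle's area equally among its three
  corners; degenerate triangles contribute zero with a warning.  Cluster
  mass is the sum of member vertex areas, so mass is conserved under
  mesh refinement in aggregate.
* Cluster components use shared-edge adjacency; opposite-sign vertices
  are never merged.  Components are reported sorted by decreasing mass
  with ties broken by the smallest member index, making outputs
  deterministic.
* Zero residual variance at a vertex yields t = 0 (flagged) rather than
  NaN; the zero tensor has FA defined as 0.
* Wilcoxon rank-sum uses midranks; exact enumeration when both samples
  have n ≤ 10, else the tie-corrected normal approximation with a 0.5
  continuity correction.
* Lesion-share percentages are *truncated* to one decimal (8/132 →
  6.0%), the convention that reproduces published lesion tables; count
  percentages in demographics strings are rounded to integers (13/21 →
  62%).  Truncated shares can sum slightly below 100%.
* All stochastic stages derive their seed from the global seed and the
  stage name (`derive_seed`), so pipeline outputs are byte-reproducible
  and stages can be rerun independently.

## Design choices that were genuinely open

* "One-way ANOVA with repeated measures between three groups" is
  internally inconsistent for unpaired groups; `anova_by_tract` runs a
  between-groups one-way ANOVA per tract by default and offers the mixed
  group x tract model (`repeated = TRUE`) with tract as the
  within-subject factor.
* The BH family is the full 99-test set, the conservative reading of
  correlating each measure with each tract; a per-tract family would
  reject more.
* Correlations are computed within the SCD group by default (the group
  whose FA–cognition coupling is under study); the group is selectable.
* The ACTL female fraction is set from the tabulated count (8/19) rather
  than the conflicting in-text count (10/19); it is a config field, not
  a commitment.
* Chi-squared tests are computed without Yates continuity correction by
  default (toggleable), matching how such demographic tables are
  typically produced.

## Known limitations

* The permutation engine holds all tract datasets as one dense matrix;
  at 10,000 permutations x 11 tracts x ~200 vertices this is seconds of
  work, but very large meshes (10^5 vertices) would want a compiled
  union-find.
* Freedman–Lane is approximate in finite samples when covariates are
  strongly unbalanced across groups.
* The NIfTI reader covers single-file NIfTI-1 scalar volumes
  (datatypes uint8/int16/int32/float32/float64) — not NIfTI-2, not
  .hdr/.img pairs, not 4-D time series.
* Synthetic skeletons are topological disks; real tracts with holes or
  branches would exercise the same algorithms but are not generated.
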