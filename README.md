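# tractsa

Tract-specific analysis (TSA) of white-matter microstructure from
diffusion tensor imaging, for neuroimaging researchers studying
population differences in individual tracts — e.g. sickle cell disease
(SCD) patients vs anemic (ACTL) and healthy (CTL) controls.

Rather than testing voxels across the whole brain, TSA projects a
diffusion metric — fractional anisotropy (FA),
`FA = sqrt(3/2) * ||lambda - mean(lambda)|| / ||lambda||` from the tensor
eigenvalues — onto the medial skeleton surface of each tract (corpus
callosum, cortico-spinal, inferior fronto-occipital, inferior and
superior longitudinal, uncinate; 11 sheets in all) and tests every
skeleton vertex with a general linear model `FA ~ group + age + sex`.
Vertices with `|t| > t0` (with `t0 = qt(1 - p/2, df)` at cluster-forming
p = .01) are merged into edge-connected clusters whose *mass* is their
surface area; each observed mass is compared with the permutation
distribution of the **maximal cluster mass pooled over all tracts**
(Freedman–Lane residual permutation, 10,000 permutations), giving
family-wise-error corrected cluster p-values

```
p_FWER = (1 + #{permutation maxima >= observed mass}) / (n_permutations + 1).
```

The package also provides per-tract mean-FA summaries with three-group
ANOVA, demographics tables (t / chi-squared, Bonferroni), white-matter
hyperintensity (WMH) lesion distributions, and Pearson correlation of
tract mean FA with nine neurocognitive scaled scores (mean 10, SD 3)
under Benjamini–Hochberg FDR control across the 99 tract x measure
family.  A synthetic cohort generator reproduces the whole statistical
structure of a 21/26/19 three-group study (planted FA decrements on
geodesic disks, WMH lesion sets, scores with controlled FA correlation),
so every stage is testable with no external data.  Tensor fitting from
synthetic single-shell DWI (log-linear least squares, Rician noise) and
minimal NIfTI-1 / legacy-VTK / CSV / bval-bvec IO round out the
pipeline.

## Worked example

```r
library(tractsa)

sk  <- generate_skeletons(c("CC", "CST_L", "IFO_L"), resolution = 10, seed = 1)
co  <- generate_cohort(cohort_config(seed = 42), sk)   # 21 CTL / 26 SCD / 19 ACTL
res <- analyze_tsa(co$records, co$datasets, sk, c("CTL", "SCD"),
                   cluster_config(n_permutations = 2000, seed = 7))
head(subset(res, significant), 3)
#>   tract cluster_id n_vertices mass_mm2 peak_t    direction p_fwer significant
#> 1    CC          1          4     65.7  -4.64 group2_lower  5e-04        TRUE

mfa <- tract_mean_fa_table(co$datasets)
anova_by_tract(mfa, co$records$group)
#>   tract     F      p df1 df2
#> 1    CC 2.264 0.1124   2  63
#> 2 CST_L 0.469 0.6278   2  63
#> 3 IFO_L 2.644 0.0789   2  63

assoc <- correlate_tracts_measures(mfa, co$records, group = "SCD", q = 0.05)
head(assoc[, c("tract", "measure", "n", "r", "p_raw", "p_bh", "significant")], 4)
#>    tract measure  n    r   p_raw  p_bh significant
#> 22 IFO_L score_4 26 0.62 0.00077 0.021        TRUE
#> 4     CC score_4 26 0.58 0.00176 0.024        TRUE
#> 7     CC score_7 26 0.55 0.00341 0.027        TRUE
#> 13 CST_L score_4 26 0.55 0.00394 0.027        TRUE
```

Reading the output: the planted SCD decrement on the corpus callosum is
recovered as a significant patients-lower (`group2_lower`) cluster of
4 vertices and 65.7 mm² whose mass beat all 2000 permutation maxima
(p = 1/2001).  The per-tract ANOVA at this small effect size is
non-significant, illustrating why the vertex-wise cluster analysis is
the more sensitive instrument.  The association table recovers the
generator's FA–score coupling: `score_4` (Inhibition, generator rho =
.51) tops the BH-ranked list on the CC; correlated tract means spread
the signal to neighbouring tracts.

The full pipeline — simulate → (project) → analyze → report → correlate
— runs from one JSON config:

```r
run_pipeline(default_pipeline_config(seed = 1, out = "tsa_out"))
```

or from the command line via `inst/cli/tractsa`:

```sh
tractsa run --config cohort.json --out tsa_out --seed 1
tractsa project --fa subj01.nii.gz --mesh CC.vtk --mode max --out CC_subj.csv
```

Every artifact directory carries `provenance.json` (config hash, seed);
identical config + seed reproduces byte-identical outputs.

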