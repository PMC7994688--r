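Package: tractsa
Title: Tract-Specific Analysis of Diffusion MRI Skeleton Surfaces
Version: 0.1.0
Authors@R:
    person("TSA", "Maintainers", email = "maintainers@tractsa.org", role = c("aut", "cre"))
Description: Tract-specific analysis (TSA) of white-matter microstructure:
    projection of voxel-wise diffusion metrics (fractional anisotropy, mean
    diffusivity) onto medial skeleton surfaces of individual tracts,
    vertex-wise general linear models with nuisance covariates,
    supra-threshold cluster-mass permutation inference with family-wise
    error control pooled over tracts, per-tract summary statistics and
    group comparisons, and correlation of tract mean FA with neurocognitive
    scores under Benjamini-Hochberg false-discovery-rate control.  Includes
    a diffusion tensor toolbox (log-linear tensor fitting from synthetic
    DWI), minimal NIfTI-1 and legacy VTK polydata readers and writers, a
    synthetic three-group cohort generator with planted tract effects for
    power and error-rate studies, and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
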