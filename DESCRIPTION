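Package: graindry
Title: Thin-Layer Grain Drying Kinetics, Shrinkage, Diffusivity and
    Storage Quality Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for post-harvest grain process modelling. Fits the
    classical semi-empirical thin-layer drying models (Newton, Page,
    Henderson & Pabis, Midilli and others) to dry-basis moisture records
    by bounded multi-start nonlinear least squares, with the
    goodness-of-fit statistics customary in the drying literature
    (coefficient of determination, mean relative error P, average
    estimated error SE, and a runs-test classification of the residual
    distribution) and a lexicographic model ranking. Models unit
    volumetric shrinkage of grains from tri-axial dimensions, estimates
    effective moisture diffusivity from the analytical series solution of
    Fick's second law for a sphere (method of slopes and full-series
    fit), and performs Arrhenius analysis of diffusivity against drying
    air temperature. Includes a multivariate workflow for factorial
    storage-quality experiments (standardization, Ward/Euclidean
    hierarchical clustering, per-cluster Pearson correlations and compact
    letter displays from Tukey's HSD) and seeded synthetic-data
    generators for every stage, so that each estimator can be exercised
    against data with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
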