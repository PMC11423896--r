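Package: selunit
Title: Localization, Lesioning, and Encoding Analyses of Category-Selective Units in Layered Feature Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for studying category-selective units in
    hierarchical feature models and their relation to simulated fMRI voxel
    responses. Provides an in-silico localizer (two-sample t contrasts with
    Benjamini-Hochberg FDR correction, plus a 2:1 response-ratio variant),
    causal lesioning of selective-unit groups under a sparse L1-regularized
    linear readout with per-category recognition cost profiles, non-negative
    sparse (Lasso) voxelwise encoding models with univariate and
    representational-similarity (veRSA) evaluation, Monte-Carlo noise
    ceilings, Gabor and Gist-PC baselines, and representational-geometry
    visualizations (meta-RDM MDS trajectories, PC-space tuning vectors).
    Includes generators for category-structured stimuli, planted-selectivity
    networks, and simulated voxel datasets with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    glmnet
Config/testthat/edition: 3
RoxygenNote: 7.3.3
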