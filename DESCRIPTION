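Package: imgtx
Title: Imaging Transcriptomics: Linking Voxel-Wise Brain Maps to Gene Expression Topography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for relating voxel-wise group-difference t-statistic maps
    (e.g. grey-matter volume or mean diffusivity contrasts) to the spatial
    topography of gene expression. Implements mass-univariate GLM t-maps with
    covariates, microarray-style probe filtering and normalization, per-donor
    Spearman association adjusted for spatial autocorrelation with Moran
    eigenvector maps, weighted Z-score meta-combination across donors,
    sphere-rotation (spin) permutation tests and random-gene-set bootstraps on
    ROI-level expression composites, expression-weighted cell-type enrichment
    with transcript-length and GC matching, hypergeometric gene-set overlap
    with Benjamini-Hochberg correction, and group-comparison statistics from
    printed summary data. A synthetic-data module generates spatially
    autocorrelated images, multi-donor expression with planted map-coupled
    gene sets, parcellations with spherical centroids, and marker-structured
    cell-type references, so the whole chain is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
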