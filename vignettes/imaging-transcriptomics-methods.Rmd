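---
title: "Methods: spatially adjusted imaging transcriptomics with imgtx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatially adjusted imaging transcriptomics with imgtx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imgtx)
```

# The problem

Case–control neuroimaging studies summarize where a disease process changes
brain tissue as a voxel-wise t-statistic map — for example, lower grey-matter
volume or higher mean diffusivity in premanifest Huntington's disease
carriers relative to controls. Imaging transcriptomics asks which genes'
cortical expression topography, measured in post-mortem donor atlases at
known stereotactic coordinates, covaries with that map, and then interprets
the resulting gene lists through pathway enrichment, cell-type enrichment,
and overlap with disease-derived differential-expression lists.

The statistical hazard throughout is spatial autocorrelation: both brain
maps and expression surfaces are smooth, so nearby observations are not
independent, and naive correlation p-values overstate significance by
orders of magnitude. `imgtx` carries an explicit spatial-autocorrelation
treatment through every inferential step: Moran-eigenvector adjustment at
the voxel/sample level, and sphere-rotation ("spin") permutation plus
random-gene-set bootstraps at the ROI level.

# The model chain

## Group-difference t-maps

`fit_tmap()` runs an ordinary-least-squares regression per masked voxel,

$$ y_v = X\beta_v + \varepsilon_v, \qquad
   t_v = \frac{c^\top\hat\beta_v}
              {\sqrt{\hat\sigma_v^2\, c^\top (X^\top X)^{-1} c}}, $$

with pooled residual variance $\hat\sigma_v^2 = \mathrm{RSS}_v / (n - r)$.
Categorical covariates (sex, acquisition site) are one-hot encoded with one
level dropped; t-maps are invariant to affine rescaling of any covariate
column and flip sign exactly with the contrast, both verified in tests. The
convention follows the disease direction of interest: for an atrophy
analysis the contrast is oriented so positive t means control > case. No
threshold is applied — the full unthresholded map is the object carried
forward. Voxels with zero residual variance yield `NA` and are counted,
never silently zeroed.

## Probe preparation

Donor expression tables pass through the standard microarray exclusion
cascade (`filter_probes()`), applied in a fixed order with one count per
rule so the counts partition the removals: multi-gene probes, intergenic
probes, unmapped probes, then probes called above background in fewer than
`min_cortical_samples` cortical samples. The ROI arm additionally keeps,
per gene, the probe with the highest mean intensity (ties broken by probe
id), drops probes above background in no more than half the samples
(strict "over 50%"), assigns samples to parcels within a 2 mm threshold,
and averages within donor before averaging across donors — a donor with no
samples in an ROI does not contribute to that ROI rather than dragging the
mean down. Per-gene values are normalized with the scaled robust sigmoid

$$ x \mapsto \frac{1}{1+\exp\!\big(-(x-\mathrm{median})/(\mathrm{IQR}/1.35)\big)}, $$

min–max rescaled to $[0,1]$. The IQR/1.35 scale is the normal-consistent
robust spread estimate; the normalization is monotone and invariant to
affine transforms of the raw scale.

## Spatially adjusted association

For each donor, every sample takes the t-value of its nearest voxel
(samples outside the analysis mask are dropped and counted). The Moran
eigenvector basis is built from the retained sample coordinates: with
inverse-distance weights $w_{ij} = 1/d_{ij}$, the doubly centred matrix
$H W H$ is eigendecomposed and, by default, eigenvectors with positive
eigenvalue whose Moran's I exceeds the null expectation $-1/(n-1)$ are
retained. These are the positively autocorrelated spatial patterns that can
masquerade as gene–map association. The retention rule (`mem_k`) and the
weight kernel are deliberately exposed: the literature does not fix one
variant.

`adjusted_spearman()` rank-transforms both variables (average ranks on
ties), residualizes **both** rank vectors on the intercept plus the basis —
one-sided adjustment would not be invariant to which variable is called
x — and correlates the residuals:

$$ t = \rho\sqrt{\frac{n-2-k}{1-\rho^2}}, $$

with $k$ the basis size. With an empty basis this is exactly classical
Spearman, which the tests assert against `cor(..., method = "spearman")`.
Signed z-scores come from the normal quantile of the two-tailed p, capped
at $\pm 8.21$ where $\Phi^{-1}$ saturates in double precision; caps are
flagged per probe.

Donors are combined per probe by the weighted Stouffer sum
$Z = \sum_i w_i z_i / \sqrt{\sum_i w_i^2}$ with $w_i$ the donor sample
count (configurable to $\sqrt{n}$ or equal weights); with equal weights
this is the textbook unweighted formula, asserted as an identity. Probes
collapse to genes by averaging: gene T is the mean probe T (probe T itself
being the sample-count-weighted mean of per-donor t statistics), and the
gene Z is the unweighted mean of the probes' combined Z. Treating probes
of one gene as perfectly correlated makes that mean variance-preserving
and hence conservative when probes are only partially correlated; probes
disagreeing in sign are retained. Target lists take the `ceiling(frac*N)`
genes with the largest and smallest T, with opposite tie orders so the
lists stay disjoint even on fully tied input.

## ROI-level nulls

`spin_test()` correlates two per-ROI maps and compares the observed
Spearman rho with rho between y and rotated x, over Haar-uniform rotations
(QR of a Gaussian matrix with sign correction, determinant forced to +1)
applied to unit-sphere ROI centroids, each ROI taking the value of the
nearest original centroid. Empirical p uses the $(1+k)/(1+n)$ estimator,
two-tailed on $|\rho|$, so it is never zero. A strict one-to-one
assignment (greedy by ascending match distance) is available when the
value multiset must be preserved; the default nearest-neighbour variant
may duplicate sources, as is standard for volumetric spins.

`pca_composite()` centres each gene across ROIs and takes the first right
singular vector as the per-ROI composite, sign-fixed so the mean loading
is nonnegative. `random_geneset_bootstrap()` draws random gene lists of
the target-list size (target gene excluded), recomputes the composite and
its Spearman correlation with the target gene, and reports the empirical
two-tailed p — the complementary null that asks whether the *specific*
gene set matters rather than any set of that size.

## Cell-type enrichment and overlap

Specificity is the row-normalized mean-expression matrix
$s_{gc} = \mu_{gc} / \sum_{c'} \mu_{gc'}$. The enrichment statistic for a
cell type is the summed specificity of the target list; the null resamples
lists matching the target's composition over a joint transcript-length ×
GC-content bin grid, so enrichment cannot be driven by those covariates.
p-values are upper-tail $(1+k)/(1+n_{\mathrm{perm}})$, reported with
standard deviations from the null mean and fold change, BH-corrected
across the cell types of one run. DEG-list overlaps use the inclusive
upper-tail hypergeometric $P(X \ge k)$ via `phyper`, and generic
over-representation analysis (`ora_test()`) applies the same kernel per
annotation term with BH across terms, plus a dictionary-driven
summarization of significant terms into broad categories.

Group-comparison statistics from printed summary data (`summary_stats`
module) use the pooled-variance Student t — which reproduces all six
published demographic p-values exactly, where Welch does not — and the
uncorrected Pearson chi-square on 2×2 tables.

# What the synthetic data emulates

The generators produce every input the chain consumes, with the structure
the analysis assumes and with planted ground truth:

- **Maps** (`gen_structured_map()`): unit-variance mixtures of a
  Gaussian-smoothed field (FWHM 12 mm on a $16^3$ grid of 2 mm voxels by
  default) and voxel-level white noise, 70% / 30% by variance. The nugget
  is essential, not cosmetic: a real t-map carries per-voxel estimation
  noise on top of smooth anatomy. A *pure* smooth field is a degenerate
  input for any projection-based adjustment — after residualization its
  entire remaining variance is the small leaked smooth component,
  concentrated in a handful of modes shared with the expression surfaces,
  and no weight kernel or retention rule we examined (inverse-distance,
  Gaussian, k-nearest-neighbour; positive-Moran or top-k) calibrates it.
  With the nugget present, the adjusted false-positive rate on
  confound-only data is ~0.06 at $\alpha = 0.05$ while the naive rate is
  ~0.18 (20 replicates × 200 genes; the acceptance suite re-measures
  both).
- **Cohorts** (`gen_cohort_images()`): per-subject images = baseline +
  group × effect map + covariate contributions + smoothed noise, with a
  group/age/sex/site/TIV covariate table. Site is a categorical shift,
  one-hot encoded downstream.
- **Donor expression** (`gen_donor_expression()`): per gene,
  $6 + \beta\,\tilde t(s) + \sqrt{0.7}\,\mathrm{GP}(s) + \sqrt{0.3}\,\epsilon$,
  where $\tilde t$ is the standardized map value at the sample, the GP is
  a squared-exponential process at the spatial-noise FWHM shared in form
  (not realization) across genes, and planted positive/negative sets get
  $\beta = \pm$ `coupling_beta` (default 0.5, 10% + 10% of 200 genes,
  2 donors × 120 samples). Probe multiplicity is 1–3 per gene; the probe
  table carries known counts of multi-gene, intergenic, unmapped and
  low-expression probes, the last above background in fewer than half the
  samples so the background filter has exact ground truth.
- **Parcellations** (`gen_parcellation()`): Voronoi cells of random seed
  voxels (contiguous on the grid) with volumetric centroids projected to
  the unit sphere. Spin studies use 110 ROIs — the atlas size this style
  of ROI analysis uses — because nearest-centroid reassignment is a
  discretization: at 60 ROIs it degrades Moran's I by ~25%, at 110 by
  under 10%.
- **Cell-type references** (`gen_celltype_reference()`): every gene has
  baseline mean expression 1 everywhere; each type's markers are elevated
  `marker_fold`-fold in that type only, so marker specificity is exactly
  $f/(f + n_{\mathrm{types}} - 1)$ (4/7 at fold 4 with 4 types) and
  `marker_fold = 1` is the flat reference. DEG lists are subsets of the
  markers. Marker pools can be tied to the planted association sets,
  which is how the end-to-end dissociation study wires positively coupled
  genes to astrocyte/endothelial profiles and negatively coupled genes to
  neuronal/microglial ones.

All generators fan a single master seed into fixed per-stream substreams
(covariates; per-subject noise; planted-gene assignment; probe
multiplicity; per-donor sampling; parcellation; reference; each null
engine), so adding a stream never perturbs earlier ones and every stage is
bit-reproducible — asserted with `expect_identical` in the suite.

What the synthetic data does **not** emulate: cortical geometry and
folding, diffusion-tensor physics, scanner-site intensity artefacts,
realistic microarray noise families, or the anatomical origin of real
spatial autocorrelation (here induced by Gaussian smoothing, the simplest
controllable surrogate). Passing tests therefore demonstrate the
statistical machinery — calibration, power against planted couplings,
oracle agreement — not fidelity to any particular cohort or atlas.

# Numerical choices and edge cases

- Nearest-voxel lookup rounds half to even; voxel indices are 0-based and
  all geometry is affine-driven.
- Duplicate sample coordinates make inverse-distance weights infinite;
  `build_mem_basis()` refuses them unless a jitter SD is given.
- `adjusted_spearman()` requires at least 10 pairs and errors on
  constant-after-ranking input; the t→z map caps at $|z| = 8.21$.
- Empirical p-values from permutation engines are never 0 by
  construction.
- EWCE bin grids must be scaled to the universe: 10×10 deciles suit
  atlas-scale (~15k gene) universes, while a 200-gene synthetic panel
  needs `n_bins = 5` — finer grids create singleton bins whose "matched"
  draws can only return the target genes themselves, destroying the null.
- `robust_sigmoid_normalize()` errors on zero IQR rather than returning a
  constant; `pca_composite()` errors on zero-variance input.
- BH, hypergeometric tails, Student/χ² tails, OLS and SVD go through
  `p.adjust`, `phyper`, `pt`/`pchisq`, `chol`/`qr` and `svd` — the
  package's own code is the spatial machinery, the combination rules and
  the generators.

# Study sizes

The test suite and the reproduction script run, by design, at desk scale:
20 replicates × 200 genes × 2 donors × 120 samples for calibration; 3
replicates for planted-signal recovery (AUC is saturated at 1.0 well
before the 0.95 bound); 200 map pairs × 500 rotations on 110 ROIs for
spin calibration; 20 000 permutations for the EWCE enumeration and floor
checks; 10 000 EWCE permutations in the end-to-end run. The whole suite
completes in about a minute and a half on one CPU, and
`scripts/acceptance.R` in a similar time.

# Known limitations

- Gene-level p from probe averaging assumes perfectly correlated probes
  (conservative); recomputation from pooled cross-donor ranks is out of
  scope.
- The MEM adjustment removes structure representable in the retained
  eigenvector span; confounds living strictly below that spatial
  resolution are controlled only insofar as the map's nugget dominates
  its residual (see the generator discussion above).
- Spin tests assume centroids meaningfully projected to a sphere; for
  real atlases that projection must be documented by the data adapter.
- ORA works on file-based annotation snapshots; results depend on the
  annotation version supplied, by design.
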