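#' Synthetic study generators
#'
#' These generators produce every input the analysis chain consumes —
#' subject images with a planted group effect, multi-donor expression tables
#' with genes coupled to a target map, parcellations with spherical
#' centroids, and marker-structured cell-type references — with the
#' statistical structure the downstream stages assume (spatial
#' autocorrelation, known filter classes, disjoint marker sets).
#'
#' All generators are bit-reproducible given the spec's seed. A single
#' global seed fans out into fixed per-stream substreams (covariates,
#' per-subject noise, planted-gene assignment, per-donor sampling, ...), so
#' adding a stream never perturbs earlier ones.
#'
#' @name synthetic_data
NULL

# deterministic substream seed below 2^31, Knuth multiplicative hash
substream_seed <- function(seed, id) {
  as.integer((as.double(seed) %% 65536) * 32749 + id * 7919) %% 2147483647L
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# normalized separable Gaussian smoothing of a 3-D array (mm units)
gaussian_smooth3d <- function(arr, fwhm_mm, voxel_size_mm) {
  if (fwhm_mm <= 0) return(arr)
  sigma <- fwhm_to_sigma(fwhm_mm) / voxel_size_mm
  r <- max(1L, ceiling(3 * sigma))
  kern <- exp(-((-r:r)^2) / (2 * sigma^2))
  kern <- kern / sum(kern)
  d <- dim(arr)
  conv_axis1 <- function(m, kern) {
    r <- (length(kern) - 1L) / 2L
    n <- nrow(m)
    out <- matrix(0, n, ncol(m)); wt <- numeric(n)
    for (j in seq_along(kern)) {
      off <- j - r - 1L
      src <- seq_len(n) + off
      ok <- src >= 1L & src <= n
      if (!any(ok)) next
      out[ok, ] <- out[ok, ] + kern[j] * m[src[ok], , drop = FALSE]
      wt[ok] <- wt[ok] + kern[j]
    }
    out / wt
  }
  # smooth along each axis in turn, rotating the axis of interest to front
  for (ax in 1:3) {
    perm <- c(ax, setdiff(1:3, ax))
    a <- aperm(arr, perm)
    da <- dim(a)
    m <- conv_axis1(matrix(a, da[1], da[2] * da[3]), kern)
    arr <- aperm(array(m, da), order(perm))
  }
  arr
}

# smoothed unit-variance Gaussian random field on the grid
smooth_field <- function(grid_shape, voxel_size_mm, fwhm_mm) {
  f <- gaussian_smooth3d(array(stats::rnorm(prod(grid_shape)), grid_shape),
                         fwhm_mm, voxel_size_mm)
  s <- stats::sd(f)
  if (s > 0) f <- f / s
  f
}

#' Cohort simulation spec
#'
#' @param n_control,n_case group sizes.
#' @param grid_shape integer 3-vector of voxel counts (each >= 4).
#' @param voxel_size_mm isotropic voxel edge (mm).
#' @param smooth_fwhm_mm FWHM (mm) of the Gaussian kernel applied to the
#'   white-noise component; sets the spatial autocorrelation scale.
#' @param effect_map per-voxel planted group effect (case minus control);
#'   NULL for no effect.
#' @param covariate_effects named list of per-voxel arrays, names among
#'   `age`, `sex`, `site`, `tiv`; the covariate's numeric value scales the
#'   array's contribution to each subject's image.
#' @param noise_sd marginal SD of the smoothed noise field (> 0).
#' @param seed integer master seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_control = 30, n_case = 30,
                        grid_shape = c(16L, 16L, 16L),
                        voxel_size_mm = 2, smooth_fwhm_mm = 6,
                        effect_map = NULL, covariate_effects = NULL,
                        noise_sd = 1, seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 4L))
    stop("grid_shape must be three dimensions, each >= 4")
  if (n_control < 2 || n_case < 2) stop("need at least 2 subjects per group")
  if (voxel_size_mm <= 0) stop("voxel_size_mm must be positive")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (is.null(effect_map)) effect_map <- array(0, grid_shape)
  if (!identical(dim(effect_map), grid_shape))
    stop("effect_map shape must equal grid_shape")
  for (nm in names(covariate_effects)) {
    if (!nm %in% c("age", "sex", "site", "tiv"))
      stop("unknown covariate effect: ", nm)
    if (!identical(dim(covariate_effects[[nm]]), grid_shape))
      stop("covariate effect '", nm, "' shape must equal grid_shape")
  }
  structure(list(n_control = n_control, n_case = n_case,
                 grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
                 smooth_fwhm_mm = smooth_fwhm_mm, effect_map = effect_map,
                 covariate_effects = covariate_effects,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic imaging cohort
#'
#' Each subject's image is a constant baseline plus `group * effect_map`,
#' plus any covariate contributions, plus Gaussian-kernel-smoothed white
#' noise rescaled to marginal SD `noise_sd`.
#'
#' @param spec a [cohort_spec()].
#' @return list with `images` (list of [volume_image()]) and `covariates`
#'   (data.frame with subject, group, age, sex, site, tiv).
#' @export
gen_cohort_images <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_control + spec$n_case
  aff <- diag(c(rep(spec$voxel_size_mm, 3), 1))
  cov <- with_seed(substream_seed(spec$seed, 1L), {
    data.frame(
      subject = sprintf("S%03d", seq_len(n)),
      group = rep(c(0L, 1L), c(spec$n_control, spec$n_case)),
      age = round(stats::rnorm(n, 46, 9), 1),
      sex = sample(c("M", "F"), n, replace = TRUE),
      site = sample(c("Leiden", "London", "Paris", "Vancouver"), n, replace = TRUE),
      tiv = round(stats::rnorm(n, 1500, 120), 1),
      stringsAsFactors = FALSE
    )
  })
  site_code <- as.integer(factor(cov$site,
    levels = c("Leiden", "London", "Paris", "Vancouver"))) - 1L
  sex_code <- as.integer(cov$sex == "F")
  images <- vector("list", n)
  for (i in seq_len(n)) {
    base <- array(100, spec$grid_shape)
    img <- base + cov$group[i] * spec$effect_map
    ce <- spec$covariate_effects
    if (!is.null(ce)) {
      val <- c(age = cov$age[i], sex = sex_code[i], site = site_code[i],
               tiv = cov$tiv[i])
      for (nm in names(ce)) img <- img + val[[nm]] * ce[[nm]]
    }
    noise <- with_seed(substream_seed(spec$seed, 100L + i),
                       smooth_field(spec$grid_shape, spec$voxel_size_mm,
                                    spec$smooth_fwhm_mm))
    images[[i]] <- volume_image(img + spec$noise_sd * noise, aff)
  }
  list(images = images, covariates = cov)
}

#' Generate a spatially structured scalar map
#'
#' A unit-variance field mixing a Gaussian-kernel-smoothed component with a
#' white (voxel-level) component:
#' sqrt(smooth_share) * smooth + sqrt(1 - smooth_share) * white.
#' This is the generic stand-in for a group-difference t-map, which carries
#' broad anatomical structure plus fine-scale estimation noise.
#'
#' @param grid_shape integer 3-vector.
#' @param voxel_size_mm voxel edge (mm).
#' @param fwhm_mm FWHM of the smooth component.
#' @param smooth_share variance share of the smooth component, in [0, 1].
#' @param seed integer seed.
#' @return a [volume_image()].
#' @export
gen_structured_map <- function(grid_shape = c(16L, 16L, 16L),
                               voxel_size_mm = 2, fwhm_mm = 12,
                               smooth_share = 0.7, seed = 1L) {
  if (smooth_share < 0 || smooth_share > 1)
    stop("smooth_share must be in [0, 1]")
  with_seed(substream_seed(seed, 2L), {
    s <- smooth_field(grid_shape, voxel_size_mm, fwhm_mm)
    w <- array(stats::rnorm(prod(grid_shape)), grid_shape)
    volume_image(sqrt(smooth_share) * s + sqrt(1 - smooth_share) * w,
                 diag(c(rep(voxel_size_mm, 3), 1)))
  })
}

#' Expression simulation spec
#'
#' @param n_donors number of donors (>= 1; per-donor association needs >= 2
#'   for meta-combination to differ from a single analysis).
#' @param samples_per_donor tissue samples per donor (>= 10).
#' @param n_genes number of genes.
#' @param probes_per_gene_dist probabilities of a gene carrying 1, 2 or 3
#'   probes.
#' @param pos_gene_frac,neg_gene_frac fractions of genes planted with
#'   positive / negative coupling to the target map (sum <= 1).
#' @param coupling_beta slope of expression on the standardized target
#'   t-value for planted genes (0 = null data).
#' @param spatial_noise_fwhm_mm length scale (FWHM, mm) of the spatially
#'   smooth noise shared structure in each gene's expression.
#' @param smooth_share variance share of the smooth component in each
#'   gene's unit-variance noise (the rest is an independent nugget).
#' @param n_bad_probes named counts for filter classes: `multi_gene`,
#'   `intergenic`, `unmapped`, `low_expression`.
#' @param seed integer master seed.
#' @return object of class `expression_spec`.
#' @export
expression_spec <- function(n_donors = 2, samples_per_donor = 120,
                            n_genes = 200,
                            probes_per_gene_dist = c(0.7, 0.2, 0.1),
                            pos_gene_frac = 0.1, neg_gene_frac = 0.1,
                            coupling_beta = 0.5,
                            spatial_noise_fwhm_mm = 12, smooth_share = 0.7,
                            n_bad_probes = c(multi_gene = 2, intergenic = 1,
                                             unmapped = 1, low_expression = 3),
                            seed = 1L) {
  if (samples_per_donor < 10)
    stop("samples_per_donor must be >= 10 (rank correlation unstable below)")
  if (pos_gene_frac + neg_gene_frac > 1)
    stop("pos_gene_frac + neg_gene_frac must be <= 1")
  if (length(probes_per_gene_dist) != 3 || any(probes_per_gene_dist < 0))
    stop("probes_per_gene_dist must be 3 nonnegative probabilities")
  if (smooth_share < 0 || smooth_share > 1)
    stop("smooth_share must be in [0, 1]")
  need <- c("multi_gene", "intergenic", "unmapped", "low_expression")
  nb <- n_bad_probes[need]
  nb[is.na(nb)] <- 0
  names(nb) <- need
  structure(list(n_donors = n_donors, samples_per_donor = samples_per_donor,
                 n_genes = n_genes,
                 probes_per_gene_dist = probes_per_gene_dist / sum(probes_per_gene_dist),
                 pos_gene_frac = pos_gene_frac, neg_gene_frac = neg_gene_frac,
                 coupling_beta = coupling_beta,
                 spatial_noise_fwhm_mm = spatial_noise_fwhm_mm,
                 smooth_share = smooth_share,
                 n_bad_probes = nb, seed = as.integer(seed)),
            class = "expression_spec")
}

#' Generate multi-donor expression tables coupled to a target map
#'
#' For each donor, tissue-sample locations are drawn from the target map's
#' mask; expression of planted-positive genes rises with the (standardized)
#' t-value at the sample location with slope `coupling_beta`,
#' planted-negative genes fall with it, and null genes carry only spatially
#' smooth noise (Gaussian-process draw with the requested FWHM) plus an
#' independent nugget. The probe table includes the requested counts of
#' multi-gene, intergenic, unmapped, and low-expression probes; the
#' low-expression probes are above background in fewer than half the
#' samples so the background filter has known ground truth.
#'
#' @param spec an [expression_spec()].
#' @param target a [volume_image()] of target values (e.g. a t-map's image).
#' @return list of `donor_expression` objects (one per donor), each with
#'   `donor_id`, `samples` (coordinate table with structure labels), `expr`
#'   (probe x sample matrix), `probes` (annotation data.frame),
#'   `above_background` (probe x sample logical). The planted gene sets are
#'   attached as attributes `planted_pos` / `planted_neg`.
#' @export
gen_donor_expression <- function(spec, target) {
  stopifnot(inherits(spec, "expression_spec"), inherits(target, "volume_image"))
  genes <- sprintf("G%04d", seq_len(spec$n_genes))
  n_pos <- round(spec$pos_gene_frac * spec$n_genes)
  n_neg <- round(spec$neg_gene_frac * spec$n_genes)
  planted <- with_seed(substream_seed(spec$seed, 7L),
                       sample(genes, n_pos + n_neg))
  pos_genes <- sort(planted[seq_len(n_pos)])
  neg_genes <- sort(planted[n_pos + seq_len(n_neg)])
  beta <- stats::setNames(numeric(spec$n_genes), genes)
  beta[pos_genes] <- spec$coupling_beta
  beta[neg_genes] <- -spec$coupling_beta
  # probe multiplicity per gene, shared across donors
  ppg <- with_seed(substream_seed(spec$seed, 8L),
                   sample(1:3, spec$n_genes, replace = TRUE,
                          prob = spec$probes_per_gene_dist))
  mask_idx <- which(target$mask, arr.ind = TRUE)
  if (nrow(mask_idx) < spec$samples_per_donor)
    stop("mask too small for samples_per_donor")
  tvals_all <- target$data[target$mask]
  t_mu <- mean(tvals_all); t_sd <- stats::sd(tvals_all)
  if (!is.finite(t_sd) || t_sd == 0) t_sd <- 1
  ell <- fwhm_to_sigma(spec$spatial_noise_fwhm_mm)
  donors <- vector("list", spec$n_donors)
  for (d in seq_len(spec$n_donors)) {
    donors[[d]] <- with_seed(substream_seed(spec$seed, 1000L + d), {
      pick <- sample(nrow(mask_idx), spec$samples_per_donor)
      ijk <- mask_idx[pick, , drop = FALSE] - 1L
      xyz <- voxel_to_world(target, ijk)
      tv <- (target$data[mask_idx[pick, , drop = FALSE]] - t_mu) / t_sd
      ns <- spec$samples_per_donor
      # shared spatial covariance for the smooth noise of every gene
      L <- if (ell > 0) {
        D2 <- as.matrix(stats::dist(xyz))^2
        t(chol(exp(-D2 / (2 * ell^2)) + diag(1e-6, ns)))
      } else diag(ns)
      gene_sig <- matrix(0, spec$n_genes, ns, dimnames = list(genes, NULL))
      a_sm <- sqrt(spec$smooth_share); a_wh <- sqrt(1 - spec$smooth_share)
      for (g in seq_len(spec$n_genes)) {
        smooth_part <- as.numeric(L %*% stats::rnorm(ns))
        gene_sig[g, ] <- 6 + beta[g] * tv + a_sm * smooth_part +
          a_wh * stats::rnorm(ns)
      }
      # clean probes: gene signal + probe offset + probe noise
      probe_gene <- rep(genes, times = ppg)
      n_clean <- length(probe_gene)
      expr <- gene_sig[probe_gene, , drop = FALSE] +
        matrix(0.15 * stats::rnorm(n_clean * ns), n_clean, ns)
      probes <- data.frame(
        probe_id = sprintf("P%05d", seq_len(n_clean)),
        gene_symbol = probe_gene,
        n_genes_mapped = 1L,
        intergenic = FALSE,
        class = "clean",
        stringsAsFactors = FALSE
      )
      ab <- matrix(TRUE, n_clean, ns)
      # bad probes exercising each filter class
      nb <- spec$n_bad_probes
      add_bad <- function(k, gene_symbol, n_genes_mapped, intergenic, cls,
                          low = FALSE) {
        if (k == 0) return(NULL)
        e <- matrix(2 + stats::rnorm(k * ns), k, ns)
        a <- if (low)
          matrix(stats::runif(k * ns) < 0.3, k, ns)  # above bg in <50%
        else matrix(TRUE, k, ns)
        list(expr = e, ab = a,
             probes = data.frame(probe_id = NA_character_,
                                 gene_symbol = gene_symbol,
                                 n_genes_mapped = n_genes_mapped,
                                 intergenic = intergenic, class = cls,
                                 stringsAsFactors = FALSE)[rep(1, k), ])
      }
      bads <- list(
        add_bad(nb[["multi_gene"]], "G0001///G0002", 2L, FALSE, "multi_gene"),
        add_bad(nb[["intergenic"]], "INTERGENIC", 1L, TRUE, "intergenic"),
        add_bad(nb[["unmapped"]], NA_character_, 1L, FALSE, "unmapped"),
        add_bad(nb[["low_expression"]], genes[1], 1L, FALSE, "low_expression",
                low = TRUE)
      )
      for (b in bads) {
        if (is.null(b)) next
        expr <- rbind(expr, b$expr)
        ab <- rbind(ab, b$ab)
        probes <- rbind(probes, b$probes)
      }
      probes$probe_id <- sprintf("P%05d", seq_len(nrow(probes)))
      rownames(expr) <- probes$probe_id
      rownames(ab) <- probes$probe_id
      samples <- data.frame(
        id = sprintf("D%d_S%03d", d, seq_len(ns)),
        x_mm = xyz[, 1], y_mm = xyz[, 2], z_mm = xyz[, 3],
        structure = "cortex", cortical = TRUE, hemisphere = "L",
        stringsAsFactors = FALSE
      )
      structure(list(donor_id = sprintf("donor%d", d), samples = samples,
                     expr = expr, probes = probes, above_background = ab),
                class = "donor_expression")
    })
  }
  attr(donors, "planted_pos") <- pos_genes
  attr(donors, "planted_neg") <- neg_genes
  donors
}

#' Generate a parcellation with unit-sphere centroids
#'
#' ROIs are the Euclidean Voronoi cells of randomly placed seed voxels
#' (contiguous on the box grid); each ROI's volumetric centroid, taken
#' relative to the grid centre, is projected onto the unit sphere for spin
#' testing.
#'
#' @param n_rois number of ROIs (>= 10).
#' @param grid_shape integer 3-vector.
#' @param voxel_size_mm voxel edge (mm).
#' @param seed integer seed.
#' @return list with `labels` ([volume_image()] of ROI ids 1..n_rois) and
#'   `centroids` (n_rois x 3 unit-norm matrix).
#' @export
gen_parcellation <- function(n_rois, grid_shape = c(16L, 16L, 16L),
                             voxel_size_mm = 2, seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (n_rois < 10) stop("n_rois must be >= 10")
  nvox <- prod(grid_shape)
  if (n_rois > nvox) stop("n_rois exceeds voxel count")
  with_seed(substream_seed(seed, 3L), {
    all_ijk <- as.matrix(expand.grid(i = seq_len(grid_shape[1]) - 1L,
                                     j = seq_len(grid_shape[2]) - 1L,
                                     k = seq_len(grid_shape[3]) - 1L))
    seeds <- all_ijk[sample(nvox, n_rois), , drop = FALSE]
    # nearest seed per voxel
    d2 <- outer(rowSums(all_ijk^2), rep(1, n_rois)) -
      2 * all_ijk %*% t(seeds) + outer(rep(1, nvox), rowSums(seeds^2))
    lab <- max.col(-d2, ties.method = "first")
    labels <- array(lab, grid_shape)
    ctr <- (grid_shape - 1) / 2
    cen <- t(vapply(seq_len(n_rois), function(r) {
      v <- colMeans(all_ijk[lab == r, , drop = FALSE]) - ctr
      n <- sqrt(sum(v^2))
      if (n < 1e-9) v <- v + c(1e-6, 0, 0)  # degenerate central ROI
      v / sqrt(sum(v^2))
    }, numeric(3)))
    list(labels = volume_image(labels + 0,
                               diag(c(rep(voxel_size_mm, 3), 1))),
         centroids = cen)
  })
}

#' Generate a spatially smooth per-ROI map
#'
#' Gaussian-process draw on the ROI centroids (squared-exponential
#' covariance in chord distance, plus a small nugget), used to make pairs
#' of autocorrelated maps for spin-test calibration studies.
#'
#' @param centroids n x 3 unit-sphere centroid matrix.
#' @param range correlation length (chord distance at which correlation
#'   falls to exp(-1/2)).
#' @param nugget independent variance added to the diagonal.
#' @param seed integer seed.
#' @return numeric vector, one value per ROI.
#' @export
gen_smooth_roi_map <- function(centroids, range = 0.7, nugget = 0.05,
                               seed = 1L) {
  d2 <- as.matrix(stats::dist(centroids))^2
  K <- exp(-d2 / (2 * range^2)) + diag(nugget, nrow(centroids))
  with_seed(substream_seed(seed, 4L),
            as.numeric(t(chol(K)) %*% stats::rnorm(nrow(centroids))))
}

#' Cell-type reference simulation spec
#'
#' @param n_celltypes number of cell types.
#' @param markers_per_celltype markers per type (disjoint across types).
#' @param marker_fold fold elevation of a marker in its own type (> 1).
#' @param length_range_bp range of simulated transcript lengths (bp).
#' @param gc_range range of simulated GC fractions.
#' @param deg_size size of each cell type's differentially-expressed gene
#'   list (a subset of that type's markers).
#' @param seed integer seed.
#' @return object of class `celltype_spec`.
#' @export
celltype_spec <- function(n_celltypes = 4, markers_per_celltype = 10,
                          marker_fold = 4, length_range_bp = c(500, 10000),
                          gc_range = c(0.35, 0.65), deg_size = 5, seed = 1L) {
  if (marker_fold < 1) stop("marker_fold must be >= 1 (1 = flat reference)")
  if (deg_size > markers_per_celltype)
    stop("deg_size cannot exceed markers_per_celltype")
  structure(list(n_celltypes = n_celltypes,
                 markers_per_celltype = markers_per_celltype,
                 marker_fold = marker_fold, length_range_bp = length_range_bp,
                 gc_range = gc_range, deg_size = deg_size,
                 seed = as.integer(seed)),
            class = "celltype_spec")
}

#' Generate a marker-structured cell-type reference
#'
#' Every gene has baseline mean expression 1 in every cell type; each cell
#' type's markers are elevated `marker_fold`-fold in that type only, so a
#' marker's specificity for its own type is
#' `marker_fold / (marker_fold + n_celltypes - 1)`. DEG lists are random
#' subsets of each type's markers.
#'
#' @param spec a [celltype_spec()].
#' @param genes character vector: the gene universe.
#' @param marker_pools optional named list (cell type -> candidate genes)
#'   from which that type's markers are drawn; default: any unused gene.
#' @return list with `mean_expr` (gene x cell-type matrix), `gene_info`
#'   (data.frame gene, length_bp, gc), `markers` (named list), `deg_lists`
#'   (named list).
#' @export
gen_celltype_reference <- function(spec, genes, marker_pools = NULL) {
  stopifnot(inherits(spec, "celltype_spec"))
  k <- spec$n_celltypes
  if (spec$markers_per_celltype * k > length(genes))
    stop("markers_per_celltype x n_celltypes exceeds number of genes")
  types <- if (!is.null(marker_pools)) names(marker_pools)
           else paste0("celltype", seq_len(k))
  if (length(types) != k) stop("marker_pools must have n_celltypes entries")
  with_seed(substream_seed(spec$seed, 5L), {
    used <- character(0)
    markers <- stats::setNames(vector("list", k), types)
    for (ct in types) {
      pool <- if (!is.null(marker_pools)) setdiff(marker_pools[[ct]], used)
              else setdiff(genes, used)
      if (length(pool) < spec$markers_per_celltype)
        stop("marker pool for '", ct, "' too small")
      markers[[ct]] <- sort(sample(pool, spec$markers_per_celltype))
      used <- c(used, markers[[ct]])
    }
    mean_expr <- matrix(1, length(genes), k, dimnames = list(genes, types))
    for (ct in types) mean_expr[markers[[ct]], ct] <- spec$marker_fold
    gene_info <- data.frame(
      gene = genes,
      length_bp = round(stats::runif(length(genes), spec$length_range_bp[1],
                                     spec$length_range_bp[2])),
      gc = round(stats::runif(length(genes), spec$gc_range[1],
                              spec$gc_range[2]), 3),
      stringsAsFactors = FALSE
    )
    deg_lists <- lapply(markers, function(m) sort(sample(m, spec$deg_size)))
    list(mean_expr = mean_expr, gene_info = gene_info, markers = markers,
         deg_lists = deg_lists)
  })
}
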