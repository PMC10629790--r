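#' Microarray probe filtering
#'
#' Applies the standard exclusion cascade to a donor's probe table, in
#' order, counting each removed probe under the first rule it fails:
#' (1) probes mapping more than one gene; (2) intergenic probes; (3) probes
#' with no gene mapping; (4) probes called above background in fewer than
#' `min_cortical_samples` cortical samples. Surviving probes all map to
#' exactly one gene.
#'
#' @param donor a `donor_expression` object (see [gen_donor_expression()]),
#'   or any list with `probes`, `expr`, `samples`, `above_background`.
#' @param min_cortical_samples threshold for rule 4; 0 disables it.
#' @return the filtered object, with attribute `exclusion_counts` (named
#'   vector multi_gene / intergenic / unmapped / low_expression).
#' @export
filter_probes <- function(donor, min_cortical_samples = 300) {
  pr <- donor$probes
  if (is.null(pr)) stop("no probe table")
  n <- nrow(pr)
  counts <- c(multi_gene = 0L, intergenic = 0L, unmapped = 0L,
              low_expression = 0L)
  removed <- rep(FALSE, n)
  take <- function(idx, rule) {
    idx <- idx & !removed
    counts[[rule]] <<- sum(idx)
    removed <<- removed | idx
  }
  take(pr$n_genes_mapped > 1, "multi_gene")
  take(pr$intergenic %in% TRUE, "intergenic")
  take(is.na(pr$gene_symbol) | pr$gene_symbol == "", "unmapped")
  if (min_cortical_samples > 0) {
    if (is.null(donor$above_background))
      stop("above-background flags required for the low-expression rule")
    cortical <- if (!is.null(donor$samples$cortical)) donor$samples$cortical
                else rep(TRUE, ncol(donor$above_background))
    n_above <- rowSums(donor$above_background[, cortical, drop = FALSE])
    take(n_above < min_cortical_samples, "low_expression")
  }
  keep <- !removed
  out <- donor
  out$probes <- pr[keep, , drop = FALSE]
  out$expr <- donor$expr[keep, , drop = FALSE]
  out$above_background <- donor$above_background[keep, , drop = FALSE]
  attr(out, "exclusion_counts") <- counts
  out
}

#' Restrict a donor table to one hemisphere
#'
#' @param donor a `donor_expression` object.
#' @param hemisphere label to keep (default `"L"`).
#' @return the donor object with only matching samples.
#' @export
restrict_hemisphere <- function(donor, hemisphere = "L") {
  keep <- donor$samples$hemisphere == hemisphere
  out <- donor
  out$samples <- donor$samples[keep, , drop = FALSE]
  out$expr <- donor$expr[, keep, drop = FALSE]
  out$above_background <- donor$above_background[, keep, drop = FALSE]
  out
}

#' Keep the highest-intensity probe per gene
#'
#' Per gene, keeps the probe with the largest mean expression over retained
#' samples; ties go to the lexicographically smallest probe id, so the
#' choice is stable across runs.
#'
#' @param donor a filtered `donor_expression` object.
#' @return the object with one probe per gene.
#' @export
select_probe_max_intensity <- function(donor) {
  pr <- donor$probes
  mu <- rowMeans(donor$expr)
  ord <- order(pr$gene_symbol, -mu, pr$probe_id)
  keep_ids <- pr$probe_id[ord][!duplicated(pr$gene_symbol[ord])]
  keep <- pr$probe_id %in% keep_ids
  out <- donor
  out$probes <- pr[keep, , drop = FALSE]
  out$expr <- donor$expr[keep, , drop = FALSE]
  out$above_background <- donor$above_background[keep, , drop = FALSE]
  out
}

#' Background filter
#'
#' Keeps probes called above background in strictly more than `frac` of the
#' samples ("over 50%" by default).
#'
#' @param donor a `donor_expression` object with above-background flags.
#' @param frac fraction threshold (strict inequality).
#' @return the filtered object.
#' @export
background_filter <- function(donor, frac = 0.5) {
  if (is.null(donor$above_background)) stop("above-background flags required")
  keep <- rowMeans(donor$above_background) > frac
  out <- donor
  out$probes <- donor$probes[keep, , drop = FALSE]
  out$expr <- donor$expr[keep, , drop = FALSE]
  out$above_background <- donor$above_background[keep, , drop = FALSE]
  out
}

#' Scaled robust sigmoid normalization
#'
#' Outlier-resistant normalization of one gene's values across ROIs:
#' x -> 1 / (1 + exp(-(x - median) / (IQR / 1.35))), then min-max rescaled
#' to [0, 1]. IQR/1.35 is the normal-consistent scale estimate. Strictly
#' monotone, and invariant to affine transforms of the raw scale.
#'
#' @param x numeric vector with at least 2 distinct values.
#' @return numeric vector in [0, 1].
#' @export
robust_sigmoid_normalize <- function(x) {
  if (sum(!is.na(x)) < 2) stop("need at least 2 values")
  s <- stats::IQR(x, na.rm = TRUE) / 1.35
  if (s == 0) stop("degenerate distribution: IQR is zero")
  y <- 1 / (1 + exp(-(x - stats::median(x, na.rm = TRUE)) / s))
  (y - min(y, na.rm = TRUE)) / (max(y, na.rm = TRUE) - min(y, na.rm = TRUE))
}

#' Assign tissue samples to parcellation ROIs
#'
#' A sample takes the label of the voxel containing it; samples falling on
#' an unlabeled voxel are assigned to the nearest labeled voxel's ROI if
#' its centre lies within `max_dist_mm`, otherwise left unassigned.
#'
#' @param samples coordinate table (columns x_mm, y_mm, z_mm).
#' @param parcellation output of [gen_parcellation()] or a list with a
#'   `labels` [volume_image()] (0 or NA = unlabeled).
#' @param max_dist_mm assignment radius for out-of-parcel samples.
#' @return integer vector of ROI ids (NA = unassigned).
#' @export
assign_samples_to_rois <- function(samples, parcellation, max_dist_mm = 2) {
  lab_img <- parcellation$labels
  xyz <- as.matrix(samples[, c("x_mm", "y_mm", "z_mm")])
  hit <- sample_at(lab_img, xyz)
  roi <- ifelse(hit$inside_mask & !is.na(hit$values) & hit$values > 0,
                hit$values, NA_real_)
  miss <- which(is.na(roi))
  if (length(miss)) {
    lab_idx <- which(lab_img$data > 0 & lab_img$mask, arr.ind = TRUE)
    lab_xyz <- voxel_to_world(lab_img, lab_idx - 1L)
    lab_val <- lab_img$data[lab_idx]
    for (i in miss) {
      d2 <- colSums((t(lab_xyz) - xyz[i, ])^2)
      j <- which.min(d2)
      if (sqrt(d2[j]) <= max_dist_mm) roi[i] <- lab_val[j]
    }
  }
  as.integer(roi)
}

#' Aggregate expression to ROI level across donors
#'
#' Two-stage mean: samples assigned to the same ROI are averaged within each
#' donor, then ROI means are averaged across the donors that have data for
#' that ROI (a donor without samples in an ROI simply does not contribute,
#' rather than contributing zero).
#'
#' @param donors list of `donor_expression` objects (after probe selection;
#'   rows of `expr` must be nameable by gene).
#' @param parcellation parcellation (see [assign_samples_to_rois()]).
#' @param max_dist_mm assignment radius.
#' @param normalize apply [robust_sigmoid_normalize()] per gene across ROIs.
#' @return matrix gene x ROI (columns `roi1`..`roiN`; all-missing ROIs
#'   dropped with a warning), with attribute `n_donors_per_roi`.
#' @export
aggregate_roi_expression <- function(donors, parcellation, max_dist_mm = 2,
                                     normalize = TRUE) {
  genes <- sort(unique(unlist(lapply(donors, function(d) d$probes$gene_symbol))))
  n_rois <- nrow(parcellation$centroids)
  acc <- matrix(0, length(genes), n_rois, dimnames = list(genes, NULL))
  cnt <- matrix(0L, length(genes), n_rois)
  for (d in donors) {
    roi <- assign_samples_to_rois(d$samples, parcellation, max_dist_mm)
    g <- d$probes$gene_symbol
    for (r in sort(unique(roi[!is.na(roi)]))) {
      sel <- which(roi == r)
      m <- rowMeans(d$expr[, sel, drop = FALSE])
      acc[g, r] <- acc[g, r] + m
      cnt[cbind(match(g, genes), r)] <- cnt[cbind(match(g, genes), r)] + 1L
    }
  }
  out <- acc / ifelse(cnt > 0, cnt, NA)
  have <- colSums(cnt) > 0
  if (!any(have)) stop("no ROI received any sample from any donor")
  if (!all(have)) warning(sum(!have), " ROI(s) had no data and were dropped")
  out <- out[, have, drop = FALSE]
  colnames(out) <- paste0("roi", which(have))
  if (normalize) out <- t(apply(out, 1, robust_sigmoid_normalize))
  attr(out, "n_donors_per_roi") <- colSums(cnt[, have, drop = FALSE] > 0)
  out
}
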