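#' imgtx: imaging transcriptomics analysis chain
#'
#' Links voxel-wise group-difference t-maps to the spatial topography of
#' gene expression: mass-univariate GLM t-maps, probe filtering and
#' normalization, spatially adjusted per-donor Spearman association with
#' Moran-eigenvector correction, weighted-Z donor combination, spin and
#' random-gene-set nulls, expression-weighted cell-type enrichment, and
#' hypergeometric gene-set overlap. A synthetic-data module generates
#' structured inputs so the full chain is testable without external
#' atlases.
#'
#' @keywords internal
"_PACKAGE"

#' Run the full synthetic analysis chain
#'
#' Convenience driver used by the examples and the reproduction script:
#' simulates a cohort with a planted group effect, fits the group t-map,
#' simulates donor expression coupled to that map, runs the spatially
#' adjusted association, extracts top-fraction gene lists, builds a
#' marker-structured cell-type reference whose astrocyte/endothelial
#' markers are drawn from the positively coupled genes and whose
#' neuronal/microglial markers come from the negatively coupled genes, and
#' tests EWCE enrichment plus DEG-overlap for both lists.
#'
#' @param seed master seed fanned out to every stage.
#' @param n_genes genes in the simulated expression panel.
#' @param coupling_beta planted coupling slope.
#' @param n_perm_ewce EWCE permutations.
#' @param top_frac fraction for the target lists.
#' @return list with `tmap`, `genes` (gene table), `lists`, `ewce`
#'   (per list), `overlap` (data.frame of hypergeometric tests), and the
#'   planted gene sets.
#' @export
run_synthetic_pipeline <- function(seed = 1L, n_genes = 200,
                                   coupling_beta = 0.5, n_perm_ewce = 10000,
                                   top_frac = 0.1) {
  effect <- array(0, c(16, 16, 16))
  effect[5:12, 5:12, 5:12] <- -3  # planted atrophy blob, case < control
  cs <- cohort_spec(n_control = 25, n_case = 25, effect_map = effect,
                    smooth_fwhm_mm = 6, noise_sd = 2,
                    seed = substream_seed(seed, 21L))
  cohort <- gen_cohort_images(cs)
  des <- design_matrix(cohort$covariates, covars = c("age", "sex", "site", "tiv"),
                       direction = -1)  # positive t = control > case (atrophy)
  tm <- fit_tmap(cohort$images, des)
  es <- expression_spec(n_donors = 2, samples_per_donor = 120,
                        n_genes = n_genes, coupling_beta = coupling_beta,
                        seed = substream_seed(seed, 22L))
  donors <- gen_donor_expression(es, tm$image)
  planted_pos <- attr(donors, "planted_pos")
  planted_neg <- attr(donors, "planted_neg")
  donors <- lapply(donors, restrict_hemisphere)
  donors <- lapply(donors, filter_probes,
                   min_cortical_samples = ceiling(0.5 * es$samples_per_donor))
  genes <- associate_genes(donors, tm)
  lists <- top_fraction_lists(genes, top_frac)
  pools <- list(astrocyte = planted_pos, endothelial = planted_pos,
                neuron = planted_neg, microglia = planted_neg)
  mpc <- length(planted_pos) %/% 2  # two cell types share each planted pool
  ctspec <- celltype_spec(n_celltypes = 4, markers_per_celltype = mpc,
                          marker_fold = 4, deg_size = max(3, mpc - 2),
                          seed = substream_seed(seed, 23L))
  ref <- gen_celltype_reference(ctspec, genes$gene, marker_pools = pools)
  S <- compute_specificity(ref$mean_expr)
  ewce <- list(
    positive = ewce_test(lists$positive, S, ref$gene_info,
                         n_perm = n_perm_ewce, n_bins = 5,
                         seed = substream_seed(seed, 24L)),
    negative = ewce_test(lists$negative, S, ref$gene_info,
                         n_perm = n_perm_ewce, n_bins = 5,
                         seed = substream_seed(seed, 25L))
  )
  overlap <- do.call(rbind, lapply(names(ref$deg_lists), function(ct) {
    rbind(
      data.frame(celltype = ct, list = "positive",
                 p = hypergeom_overlap(lists$positive, ref$deg_lists[[ct]],
                                       genes$gene)$p),
      data.frame(celltype = ct, list = "negative",
                 p = hypergeom_overlap(lists$negative, ref$deg_lists[[ct]],
                                       genes$gene)$p)
    )
  }))
  list(tmap = tm, genes = genes, lists = lists, ewce = ewce,
       overlap = overlap, planted_pos = planted_pos,
       planted_neg = planted_neg)
}
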