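test_that("cohort generator is deterministic and honours the zero-effect limit", {
  cs <- cohort_spec(n_control = 5, n_case = 5, grid_shape = c(6, 6, 6),
                    noise_sd = 1e-9, seed = 11)
  a <- gen_cohort_images(cs)
  b <- gen_cohort_images(cs)
  expect_identical(a$images[[3]]$data, b$images[[3]]$data)
  expect_identical(a$covariates, b$covariates)
  # noise_sd -> 0, no effect: case and control voxel means coincide
  grp <- a$covariates$group
  v <- sapply(a$images, function(im) im$data[3, 3, 3])
  expect_lt(abs(mean(v[grp == 1]) - mean(v[grp == 0])), 1e-6)
  expect_error(cohort_spec(grid_shape = c(2, 6, 6)), "grid_shape")
  expect_error(cohort_spec(noise_sd = 0), "noise_sd")
})

test_that("a planted blob effect appears in the group mean difference", {
  eff <- array(0, c(8, 8, 8)); eff[3:6, 3:6, 3:6] <- 2.5
  cs <- cohort_spec(n_control = 60, n_case = 60, grid_shape = c(8, 8, 8),
                    effect_map = eff, smooth_fwhm_mm = 4, noise_sd = 1,
                    seed = 5)
  ch <- gen_cohort_images(cs)
  grp <- ch$covariates$group
  vox <- sapply(ch$images, function(im) im$data[4, 4, 4])
  d <- mean(vox[grp == 1]) - mean(vox[grp == 0])
  se <- sqrt(var(vox[grp == 1]) / 60 + var(vox[grp == 0]) / 60)
  expect_lt(abs(d - 2.5), 3 * se)
})

test_that("smoothed fields carry significant positive spatial autocorrelation", {
  f <- gen_structured_map(c(10, 10, 10), 2, fwhm_mm = 10, smooth_share = 1,
                          seed = 9)
  idx <- which(f$mask, arr.ind = TRUE)
  set.seed(2)
  pick <- sample(nrow(idx), 80)
  co <- voxel_to_world(f, idx[pick, ] - 1)
  W <- inv_dist_weights(co)
  vals <- f$data[idx[pick, ]]
  I_obs <- moran_i(vals, W)
  I_null <- replicate(999, moran_i(sample(vals), W))
  p <- (1 + sum(I_null >= I_obs)) / 1000
  expect_lt(p, 0.01)
})

test_that("donor expression plants couplings and exercises every filter class", {
  tm <- gen_structured_map(seed = 21)
  # noiseless limit: planted-positive genes track the map almost perfectly
  es0 <- expression_spec(n_donors = 1, samples_per_donor = 50, n_genes = 30,
                         coupling_beta = 50, smooth_share = 0,
                         spatial_noise_fwhm_mm = 0, seed = 3)
  d0 <- gen_donor_expression(es0, tm)
  pos <- attr(d0, "planted_pos")
  dd <- d0[[1]]
  mt <- match_samples_to_map(tm, dd$samples)
  pr <- dd$probes[dd$probes$gene_symbol %in% pos & dd$probes$class == "clean", ]
  rhos <- apply(dd$expr[pr$probe_id, , drop = FALSE], 1,
                function(e) cor(e, mt$t_values, method = "spearman"))
  expect_gt(min(rhos), 0.99)
  # probe table carries the requested filter classes
  expect_equal(unname(table(dd$probes$class)[c("multi_gene", "intergenic",
                                               "unmapped", "low_expression")]),
               c(2L, 1L, 1L, 3L), ignore_attr = TRUE)
  # determinism
  d0b <- gen_donor_expression(es0, tm)
  expect_identical(d0[[1]]$expr, d0b[[1]]$expr)
  expect_error(expression_spec(samples_per_donor = 5), "samples_per_donor")
  expect_error(expression_spec(pos_gene_frac = 0.6, neg_gene_frac = 0.6),
               "<= 1")
})

test_that("null expression is not zero-inflated in correlation", {
  tm <- gen_structured_map(seed = 22)
  es <- expression_spec(n_donors = 1, samples_per_donor = 80, n_genes = 60,
                        coupling_beta = 0, seed = 8)
  d <- gen_donor_expression(es, tm)[[1]]
  mt <- match_samples_to_map(tm, d$samples)
  cl <- d$probes$class == "clean"
  rhos <- apply(d$expr[cl, ], 1, function(e)
    cor(e, mt$t_values, method = "spearman"))
  # spatially-noisy null: |rho| spread out, median near the null width
  expect_gt(median(abs(rhos)), 0.02)
  expect_lt(abs(median(rhos)), 0.2)
})

test_that("parcellation gives contiguous nonempty ROIs with unit centroids", {
  p <- gen_parcellation(12, grid_shape = c(10, 10, 10), seed = 4)
  expect_equal(sort(unique(as.numeric(p$labels$data))), 1:12)
  expect_true(all(abs(sqrt(rowSums(p$centroids^2)) - 1) < 1e-12))
  p2 <- gen_parcellation(12, grid_shape = c(10, 10, 10), seed = 4)
  expect_identical(p$labels$data, p2$labels$data)
  expect_error(gen_parcellation(5), "n_rois")
  expect_error(gen_parcellation(10000, grid_shape = c(4, 4, 4)),
               "exceeds voxel count")
})

test_that("cell-type reference matches the marker specificity formula", {
  genes <- sprintf("g%03d", 1:60)
  ref <- gen_celltype_reference(celltype_spec(n_celltypes = 4,
                                              markers_per_celltype = 5,
                                              marker_fold = 4, deg_size = 3,
                                              seed = 2), genes)
  S <- compute_specificity(ref$mean_expr)
  m1 <- ref$markers[[1]]
  # fold/(fold + k - 1) = 4/7 for a marker in its own type
  expect_equal(unname(S[m1, 1]), rep(4 / 7, 5), tolerance = 1e-12)
  # marker sets disjoint, DEG lists inside marker sets
  expect_equal(anyDuplicated(unlist(ref$markers)), 0L)
  for (ct in names(ref$markers))
    expect_true(all(ref$deg_lists[[ct]] %in% ref$markers[[ct]]))
  # flat reference at fold 1
  ref1 <- gen_celltype_reference(celltype_spec(marker_fold = 1, seed = 2),
                                 genes)
  S1 <- compute_specificity(ref1$mean_expr)
  expect_equal(max(abs(S1 - 0.25)), 0, tolerance = 1e-12)
  expect_error(
    gen_celltype_reference(celltype_spec(n_celltypes = 4,
                                         markers_per_celltype = 20), genes),
    "exceeds")
})
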