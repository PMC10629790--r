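test_that("filter cascade removes classes in order with correct counts", {
  probes <- rbind(
    toy_probe_row("p01", "A///B", 2L), toy_probe_row("p02", "B///C", 2L),
    toy_probe_row("p03", "A", intergenic = TRUE),
    toy_probe_row("p04", NA_character_),
    toy_probe_row("p05", "A"), toy_probe_row("p06", "B"),
    toy_probe_row("p07", "C"), toy_probe_row("p08", "D"),
    toy_probe_row("p09", "E"), toy_probe_row("p10", "F"),
    toy_probe_row("p11", "G"), toy_probe_row("p12", "H")
  )
  ns <- 10
  ab <- matrix(TRUE, 12, ns)
  ab[10:12, ] <- FALSE  # three probes below background everywhere
  expr <- matrix(rnorm(12 * ns), 12, ns)
  d <- make_toy_donor(expr, probes, ab = ab)
  out <- filter_probes(d, min_cortical_samples = 5)
  expect_equal(attr(out, "exclusion_counts"),
               c(multi_gene = 2L, intergenic = 1L, unmapped = 1L,
                 low_expression = 3L))
  expect_equal(nrow(out$probes), 5L)
  expect_true(all(out$probes$n_genes_mapped == 1))
  # rule 4 disabled removes nothing extra
  out0 <- filter_probes(d, min_cortical_samples = 0)
  expect_equal(nrow(out0$probes), 8L)
  # empty table
  e <- make_toy_donor(expr[0, , drop = FALSE], probes[0, ],
                      ab = ab[0, , drop = FALSE])
  oute <- filter_probes(e, min_cortical_samples = 5)
  expect_equal(nrow(oute$probes), 0L)
  expect_equal(sum(attr(oute, "exclusion_counts")), 0L)
})

test_that("a probe failing several rules is counted once, under the first", {
  probes <- rbind(toy_probe_row("p1", "A///B", 2L, intergenic = TRUE),
                  toy_probe_row("p2", "A"))
  d <- make_toy_donor(matrix(0, 2, 10), probes)
  out <- filter_probes(d, min_cortical_samples = 0)
  cnt <- attr(out, "exclusion_counts")
  expect_equal(sum(cnt), 1L)
  expect_equal(cnt[["multi_gene"]], 1L)
})

test_that("max-intensity probe selection is deterministic with tie-break", {
  probes <- rbind(toy_probe_row("p1", "A"), toy_probe_row("p2", "A"),
                  toy_probe_row("p3", "B"), toy_probe_row("p4", "C"),
                  toy_probe_row("p5", "C"))
  expr <- rbind(rep(3.2, 6), rep(5.1, 6), rep(1, 6), rep(2, 6), rep(2, 6))
  d <- make_toy_donor(expr, probes)
  out <- select_probe_max_intensity(d)
  expect_equal(out$probes$probe_id, c("p2", "p3", "p4"))  # p4 < p5 on ties
})

test_that("background filter uses a strict 'over frac' rule", {
  probes <- rbind(toy_probe_row("p1", "A"), toy_probe_row("p2", "B"),
                  toy_probe_row("p3", "C"))
  ab <- rbind(c(rep(TRUE, 6), rep(FALSE, 4)),   # 6/10 kept
              c(rep(TRUE, 5), rep(FALSE, 5)),   # exactly half: removed
              rep(FALSE, 10))
  d <- make_toy_donor(matrix(1, 3, 10), probes, ab = ab)
  expect_equal(background_filter(d, 0.5)$probes$probe_id, "p1")
  expect_equal(background_filter(d, 0)$probes$probe_id, c("p1", "p2"))
})

test_that("robust sigmoid normalization is monotone, symmetric and affine-invariant", {
  expect_equal(robust_sigmoid_normalize(c(-2, 0, 2)), c(0, 0.5, 1))
  x <- c(0.3, 1.9, 2.2, 4.1, 8.0, 9.5)
  y <- robust_sigmoid_normalize(x)
  expect_true(all(diff(y) > 0))
  expect_equal(range(y), c(0, 1))
  y2 <- robust_sigmoid_normalize(3.7 * x - 11)
  expect_lt(max(abs(y - y2)), 1e-10)
  expect_error(robust_sigmoid_normalize(c(1, 1, 1, 1, 5)), "IQR")
})

test_that("sample-to-ROI assignment honours the distance threshold", {
  lab <- array(0, c(10, 10, 10))
  lab[2:4, 2:4, 2:4] <- 7
  lab[8:10, 8:10, 8:10] <- 3
  parc <- list(labels = volume_image(lab, diag(c(2, 2, 2, 1))),
               centroids = matrix(0, 2, 3))
  s <- data.frame(x_mm = c(4, 7.5, 18, 10),
                  y_mm = c(4, 6, 18, 10),
                  z_mm = c(4, 6, 18, 8))
  # sample 1 inside ROI 7; sample 2 is 1.5 mm from ROI 7's nearest voxel
  # centre; sample 3 in ROI 3; sample 4 about 6 mm from any parcel
  a <- assign_samples_to_rois(s, parc, max_dist_mm = 2)
  expect_equal(a, c(7L, 7L, 3L, NA))
  expect_equal(assign_samples_to_rois(s, parc, max_dist_mm = 20)[4], 7L)
})

test_that("ROI aggregation averages within then across donors", {
  lab <- array(0, c(6, 6, 6))
  lab[1:3, , ] <- 1; lab[4:6, , ] <- 2
  parc <- list(labels = volume_image(lab, diag(c(2, 2, 2, 1))),
               centroids = matrix(c(1, 0, 0, -1, 0, 0), 2, 3, byrow = TRUE))
  probes <- rbind(toy_probe_row("p1", "A"), toy_probe_row("p2", "B"))
  mk <- function(vals_roi1, vals_roi2, id) {
    ns <- length(vals_roi1) + length(vals_roi2)
    samples <- data.frame(id = paste0(id, seq_len(ns)),
                          x_mm = c(rep(2, length(vals_roi1)),
                                   rep(8, length(vals_roi2))),
                          y_mm = 2, z_mm = 2, structure = "cortex",
                          cortical = TRUE, hemisphere = "L",
                          stringsAsFactors = FALSE)
    expr <- rbind(c(vals_roi1, vals_roi2), c(vals_roi1, vals_roi2) + 1)
    make_toy_donor(expr, probes, samples = samples)
  }
  d1 <- mk(c(0.1, 0.3), 0.6, "a")      # donor 1: ROI1 mean 0.2, ROI2 0.6
  d2 <- mk(c(0.5, 0.7), numeric(0), "b")  # donor 2: ROI1 mean 0.6, no ROI2
  m <- aggregate_roi_expression(list(d1, d2), parc, normalize = FALSE)
  expect_equal(unname(m["A", "roi1"]), 0.4)   # (0.2 + 0.6) / 2
  expect_equal(unname(m["A", "roi2"]), 0.6)   # donor 1 only, not halved
  expect_equal(unname(m["B", "roi1"]), 1.4)
})
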