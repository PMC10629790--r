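test_that("specificity rows sum to one and match hand values", {
  me <- rbind(astro_only = c(2, 0, 0),
              flat = c(1, 1, 1),
              mixed = c(3, 1, 0))
  colnames(me) <- c("astro", "neuron", "micro")
  S <- compute_specificity(me)
  expect_equal(unname(rowSums(S)), rep(1, 3), tolerance = 1e-12)
  expect_equal(unname(S["astro_only", ]), c(1, 0, 0))
  expect_equal(unname(S["flat", ]), rep(1 / 3, 3))
  expect_warning(compute_specificity(rbind(me, zero = c(0, 0, 0))),
                 "all-zero")
  expect_error(compute_specificity(rbind(me, bad = c(-1, 1, 1))),
               "nonnegative")
})

test_that("whole-universe target statistic equals the column sums exactly", {
  set.seed(1)
  me <- matrix(rexp(40 * 3), 40, 3,
               dimnames = list(sprintf("g%02d", 1:40), c("a", "b", "c")))
  S <- compute_specificity(me)
  r <- ewce_test(rownames(S), S, gene_info = NULL, n_perm = 50, seed = 1)
  expect_equal(r$observed, unname(colSums(S)), tolerance = 1e-12)
})

test_that("matched bins are balanced and matched draws track covariates", {
  set.seed(2)
  genes <- sprintf("g%03d", 1:400)
  len <- runif(400, 500, 10000); gc <- runif(400, 0.3, 0.7)
  b <- matched_bins(genes, len, gc, n_bins = 4)
  sz <- table(b)
  expect_lte(max(sz) / min(sz), 2)
  expect_equal(length(unique(matched_bins(genes, len, gc, n_bins = 1))), 1L)
  expect_error(matched_bins(genes[1:10], len[1:10], gc[1:10], n_bins = 5),
               "fewer bins")
  # a matched draw reproduces a biased target's mean transcript length
  by_bin <- split(genes, b)
  set.seed(3)
  low_bins <- names(by_bin)[1:6]   # short-transcript-heavy cells
  target <- unlist(lapply(by_bin[low_bins], sample, 6))
  tb <- table(b[target])
  draw_means <- replicate(200, {
    g <- unlist(lapply(names(tb), function(k) sample(by_bin[[k]], tb[[k]])))
    mean(len[match(g, genes)])
  })
  expect_lt(abs(mean(draw_means) - mean(len[match(target, genes)])) /
              mean(len[match(target, genes)]), 0.1)
})

test_that("bootstrap p matches the exhaustive single-gene enumeration oracle", {
  # 3 genes x 2 types; target = one gene; null draws one gene uniformly,
  # so the exact p is (1 + n_perm * P(s_null >= s_obs)) / (1 + n_perm)
  me <- rbind(g1 = c(4, 1), g2 = c(1, 1), g3 = c(1, 4))
  colnames(me) <- c("ct1", "ct2")
  S <- compute_specificity(me)
  n_perm <- 20000
  r <- ewce_test("g1", S, gene_info = NULL, n_perm = n_perm, seed = 7)
  for (ct in 1:2) {
    exact_tail <- mean(S[, ct] >= S["g1", ct])
    p_exact <- (1 + n_perm * exact_tail) / (1 + n_perm)
    mc_se <- sqrt(exact_tail * (1 - exact_tail) / n_perm)
    expect_lt(abs(r$p[ct] - p_exact), 3 * mc_se + 1e-9)
  }
})

test_that("flat specificity yields no enrichment signal", {
  me <- matrix(1, 30, 3, dimnames = list(sprintf("g%02d", 1:30),
                                         c("a", "b", "c")))
  S <- compute_specificity(me)
  r <- ewce_test(sprintf("g%02d", 1:5), S, n_perm = 1000, seed = 2)
  expect_true(all(abs(r$sd_from_mean) < 1e-8 | is.nan(r$sd_from_mean)))
  expect_true(all(r$p == 1))
})

test_that("planted markers attain the minimal attainable p in their own type", {
  genes <- sprintf("g%03d", 1:200)
  ref <- gen_celltype_reference(
    celltype_spec(n_celltypes = 4, markers_per_celltype = 10,
                  marker_fold = 4, deg_size = 5, seed = 3), genes)
  S <- compute_specificity(ref$mean_expr)
  n_perm <- 2000
  r <- ewce_test(ref$markers$celltype1, S, ref$gene_info, n_perm = n_perm,
                 n_bins = 5, seed = 5)
  i <- which(r$celltype == "celltype1")
  expect_equal(r$p[i], 1 / (1 + n_perm))
  expect_equal(which.max(r$sd_from_mean), i)
  expect_true(all(r$p_adj >= r$p))
})

test_that("hypergeometric overlap matches enumeration oracles", {
  expect_equal(hypergeom_overlap(letters[1:4], character(0), 10)$p, 1)
  # N = 10, K = 5, n = 4, k = 4 -> C(5,4)/C(10,4) = 5/210
  u <- sprintf("u%02d", 1:10)
  r <- hypergeom_overlap(u[1:4], u[1:5], u)
  expect_equal(r$k, 4)
  expect_equal(r$p, 5 / 210, tolerance = 1e-12)
  expect_equal(r$p, enum_hyper_upper(4, 5, 4, 10), tolerance = 1e-12)
  # at the expected overlap the upper tail is not small
  r2 <- hypergeom_overlap(sprintf("v%02d", 1:6),
                          sprintf("v%02d", c(1, 2, 7:12)),
                          sprintf("v%02d", 1:20))
  expect_equal(r2$k, 2)  # E[X] = 6*8/20 = 2.4, floor = 2
  expect_gte(r2$p, 0.3)
  expect_equal(r2$p, enum_hyper_upper(2, 8, 6, 20), tolerance = 1e-12)
  expect_error(hypergeom_overlap(c("x"), c("y"), u), "outside the universe")
})

test_that("hypergeometric tail equals enumeration on a grid of small instances", {
  u <- sprintf("w%02d", 1:12)
  for (K in c(2, 5, 8)) for (n in c(3, 6)) for (k in 0:min(K, n)) {
    target <- u[1:n]
    deg <- u[c(seq_len(k), if (K > k) 12 - seq_len(K - k) + 1)]
    if (length(intersect(target, deg)) != k) next
    r <- hypergeom_overlap(target, deg, u)
    expect_equal(r$p, enum_hyper_upper(k, K, n, 12), tolerance = 1e-12)
  }
})

test_that("BH adjustment follows the step-up hand rule", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(4)
  for (i in 1:5) {
    p <- runif(sample(3:12, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, hand_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-12))
    expect_true(all(adj <= pmin(p * length(p), 1) + 1e-12))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})
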