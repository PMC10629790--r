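#' Haar-uniform random 3-D rotation
#'
#' QR decomposition of a Gaussian matrix with sign correction (the R
#' factor's diagonal signs are absorbed into Q), then determinant fixed to
#' +1 by flipping one column if needed.
#'
#' @return 3 x 3 rotation matrix (orthogonal, det +1).
#' @export
random_rotation <- function() {
  M <- matrix(stats::rnorm(9), 3, 3)
  qr_ <- qr(M)
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Spin a per-ROI map by a sphere rotation
#'
#' Each ROI receives the value of the ROI whose original centroid lies
#' nearest its rotated centroid. The default greedy nearest-neighbour
#' reassignment may duplicate source ROIs; `one_to_one = TRUE` instead
#' builds a permutation greedily by ascending match distance, preserving
#' the value multiset.
#'
#' @param values numeric vector, one value per ROI.
#' @param centroids n x 3 unit-sphere centroids.
#' @param rotation 3 x 3 rotation matrix.
#' @param one_to_one force a permutation (no duplicated sources).
#' @return permuted values.
#' @export
spin_permute <- function(values, centroids, rotation, one_to_one = FALSE) {
  if (length(values) != nrow(centroids)) stop("one value per centroid needed")
  rot <- centroids %*% t(rotation)
  D <- outer(rowSums(rot^2), rep(1, nrow(centroids))) -
    2 * rot %*% t(centroids) + outer(rep(1, nrow(rot)), rowSums(centroids^2))
  if (!one_to_one) return(values[max.col(-D, ties.method = "first")])
  n <- nrow(D)
  src <- integer(n)
  ord <- order(D)
  used_r <- logical(n); used_c <- logical(n); filled <- 0L
  for (idx in ord) {
    i <- (idx - 1L) %% n + 1L
    j <- (idx - 1L) %/% n + 1L
    if (used_r[i] || used_c[j]) next
    src[i] <- j; used_r[i] <- TRUE; used_c[j] <- TRUE
    filled <- filled + 1L
    if (filled == n) break
  }
  values[src]
}

#' Spin permutation test for the correlation of two ROI maps
#'
#' Observed Spearman rho(x, y) is compared with the null distribution of
#' rho(spin(x), y) over random sphere rotations, which preserves x's
#' spatial autocorrelation while breaking its alignment with y.
#' p = (1 + #\{|rho_null| >= |rho_obs|\}) / (1 + n_perm), two-tailed, never 0.
#'
#' @param x,y numeric vectors, one value per ROI (>= 10 ROIs).
#' @param centroids n x 3 unit-sphere centroids.
#' @param n_perm number of rotations (>= 1).
#' @param seed integer seed.
#' @param one_to_one see [spin_permute()].
#' @return object of class `spin_result`: list with `rho`, `null_rho`,
#'   `p_spin`, `n_perm`, `seed`.
#' @export
spin_test <- function(x, y, centroids, n_perm = 10000, seed = 1L,
                      one_to_one = FALSE) {
  n <- length(x)
  if (n < 10) stop("need at least 10 ROIs")
  if (length(y) != n || nrow(centroids) != n) stop("length mismatch")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant map")
  if (n_perm < 1) stop("n_perm must be >= 1")
  obs <- stats::cor(x, y, method = "spearman")
  ry <- rank(y)
  null_rho <- with_seed(substream_seed(seed, 11L), {
    vapply(seq_len(n_perm), function(i) {
      xs <- spin_permute(x, centroids, random_rotation(), one_to_one)
      stats::cor(rank(xs), ry)
    }, numeric(1))
  })
  p <- (1 + sum(abs(null_rho) >= abs(obs))) / (1 + n_perm)
  structure(list(rho = obs, null_rho = null_rho, p_spin = p,
                 n_perm = n_perm, seed = seed),
            class = "spin_result")
}

#' @export
print.spin_result <- function(x, ...) {
  cat(sprintf("<spin_result> rho = %.4f, p_spin = %.4g (%d rotations)\n",
              x$rho, x$p_spin, x$n_perm))
  invisible(x)
}

#' First-principal-component composite of a gene set
#'
#' Centres each gene across ROIs and takes the first right singular vector
#' as the per-ROI composite score. The loading sign is fixed so the mean
#' loading is nonnegative, making the score's sign reproducible.
#'
#' @param expr gene x ROI numeric matrix (>= 1 gene, >= 2 ROIs).
#' @return object of class `pca_composite`: list with `scores` (per ROI),
#'   `var_frac` (PC1 variance fraction), `loadings` (unit norm, per gene).
#' @export
pca_composite <- function(expr) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 2) stop("need at least 2 ROIs")
  Xc <- expr - rowMeans(expr)
  sv <- svd(Xc)
  if (sv$d[1] < 1e-12) stop("zero-variance expression matrix")
  load <- sv$u[, 1]
  if (mean(load) < 0) load <- -load
  scores <- as.numeric(t(Xc) %*% load)
  structure(list(scores = scores, var_frac = sv$d[1]^2 / sum(sv$d^2),
                 loadings = load),
            class = "pca_composite")
}

#' Random-gene-set bootstrap for a target-composite correlation
#'
#' Null distribution of Spearman correlations between a target gene's
#' per-ROI expression and the PC1 composite of random gene lists of the
#' stated size (target gene excluded from the draws). Two-tailed empirical
#' p with the (1 + k) / (1 + n) estimator.
#'
#' @param target_values numeric vector: target gene's value per ROI.
#' @param expr gene x ROI matrix to draw random lists from.
#' @param observed_rho observed Spearman correlation to test; if NULL and
#'   `gene_list` given, computed from the list's composite.
#' @param gene_list optional character vector: the gene set whose composite
#'   defines the observed correlation.
#' @param list_size size of each random list (default: length(gene_list)).
#' @param n_boot number of draws.
#' @param seed integer seed.
#' @param exclude genes never drawn (e.g. the target's own symbol).
#' @return object of class `bootstrap_result`: list with `rho`, `null_rho`,
#'   `p`, `list_size`, `n_boot`, `seed`.
#' @export
random_geneset_bootstrap <- function(target_values, expr, observed_rho = NULL,
                                     gene_list = NULL, list_size = NULL,
                                     n_boot = 10000, seed = 1L,
                                     exclude = character(0)) {
  expr <- as.matrix(expr)
  if (is.null(list_size)) {
    if (is.null(gene_list)) stop("give list_size or gene_list")
    list_size <- length(gene_list)
  }
  pool <- setdiff(rownames(expr), exclude)
  if (list_size >= length(pool))
    stop("list_size must be smaller than the number of candidate genes")
  if (is.null(observed_rho)) {
    if (is.null(gene_list)) stop("give observed_rho or gene_list")
    comp <- pca_composite(expr[gene_list, , drop = FALSE])
    observed_rho <- stats::cor(target_values, comp$scores, method = "spearman")
  }
  rt <- rank(target_values)
  null_rho <- with_seed(substream_seed(seed, 13L), {
    vapply(seq_len(n_boot), function(i) {
      g <- sample(pool, list_size)
      comp <- pca_composite(expr[g, , drop = FALSE])
      stats::cor(rt, rank(comp$scores))
    }, numeric(1))
  })
  p <- (1 + sum(abs(null_rho) >= abs(observed_rho))) / (1 + n_boot)
  structure(list(rho = observed_rho, null_rho = null_rho, p = p,
                 list_size = list_size, n_boot = n_boot, seed = seed),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("<bootstrap_result> rho = %.4f, p = %.4g (%d draws of %d genes)\n",
              x$rho, x$p, x$n_boot, x$list_size))
  invisible(x)
}
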