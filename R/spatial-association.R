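#' Match tissue samples to a t-map
#'
#' Each sample receives the t-value of the voxel nearest its coordinates;
#' samples falling outside the map's mask are dropped and counted.
#'
#' @param tmap a `tmap` object (see [fit_tmap()]) or a [volume_image()].
#' @param samples coordinate table (columns x_mm, y_mm, z_mm).
#' @return list with `t_values` (for retained samples), `kept` (logical per
#'   input sample), `n_dropped`.
#' @export
match_samples_to_map <- function(tmap, samples) {
  img <- if (inherits(tmap, "tmap")) tmap$image else tmap
  xyz <- as.matrix(samples[, c("x_mm", "y_mm", "z_mm")])
  hit <- sample_at(img, xyz)
  kept <- hit$inside_mask & is.finite(hit$values)
  if (!any(kept)) stop("no samples fall inside the map mask")
  list(t_values = hit$values[kept], kept = kept, n_dropped = sum(!kept))
}

#' Moran's I
#'
#' Scalar spatial autocorrelation index of a mapped variable under a weight
#' matrix W: I = (n / S0) * (z' W z) / (z' z) with z the centred values and
#' S0 the sum of weights. Expected value under no autocorrelation is
#' -1/(n-1).
#'
#' @param values numeric vector.
#' @param W n x n nonnegative weight matrix, zero diagonal.
#' @return Moran's I.
#' @export
moran_i <- function(values, W) {
  z <- values - mean(values)
  n <- length(z)
  (n / sum(W)) * as.numeric(t(z) %*% W %*% z) / sum(z^2)
}

#' Inverse-distance spatial weights
#'
#' @param coords n x 3 coordinate matrix.
#' @return n x n matrix with w_ij = 1/d_ij off-diagonal, 0 diagonal.
#' @export
inv_dist_weights <- function(coords) {
  d <- as.matrix(stats::dist(coords))
  if (any(d[upper.tri(d)] == 0))
    stop("duplicate coordinates give infinite weights; jitter them first")
  W <- 1 / d
  diag(W) <- 0
  W
}

#' Build a Moran-eigenvector-map basis
#'
#' Eigenvectors of the doubly centred inverse-distance weight matrix
#' H W H (H = I - 11'/n). By default retains eigenvectors with positive
#' eigenvalue whose Moran's I exceeds the null expectation -1/(n-1) —
#' the positively autocorrelated spatial patterns that can masquerade as
#' gene–map association.
#'
#' @param coords n x 3 sample coordinates (n >= 3, non-degenerate).
#' @param k number of eigenvectors to keep; `NULL` (default) applies the
#'   positive-Moran rule; `0` returns an empty basis.
#' @param jitter_sd if > 0, Gaussian jitter applied to duplicate
#'   coordinates instead of erroring.
#' @return object of class `mem_basis`: list with `vectors` (n x k,
#'   orthonormal, orthogonal to the constant), `values` (eigenvalues,
#'   descending), `moran` (Moran's I per retained vector), `rule`.
#' @export
build_mem_basis <- function(coords, k = NULL, jitter_sd = 0) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 3) stop("need at least 3 samples")
  d <- as.matrix(stats::dist(coords))
  if (any(d[upper.tri(d)] == 0)) {
    if (jitter_sd > 0) {
      coords <- coords + matrix(stats::rnorm(length(coords), 0, jitter_sd),
                                nrow = n)
      d <- as.matrix(stats::dist(coords))
      if (any(d[upper.tri(d)] == 0)) stop("duplicates persist after jitter")
    } else stop("duplicate coordinates give infinite weights; set jitter_sd")
  }
  W <- 1 / d
  diag(W) <- 0
  ones <- rep(1, n)
  HWH <- W - outer(ones, colMeans(W)) - outer(rowMeans(W), ones) + mean(W)
  eg <- eigen((HWH + t(HWH)) / 2, symmetric = TRUE)
  if (!is.null(k) && k == 0) {
    return(structure(list(vectors = matrix(0, n, 0), values = numeric(0),
                          moran = numeric(0), rule = "k=0"),
                     class = "mem_basis"))
  }
  pos <- which(eg$values > 1e-10)
  V <- eg$vectors[, pos, drop = FALSE]
  mi <- apply(V, 2, moran_i, W = W)
  if (is.null(k)) {
    keep <- mi > (-1 / (n - 1))
    rule <- "positive-moran"
  } else {
    keep <- seq_along(pos) <= k
    rule <- paste0("top-", k)
  }
  structure(list(vectors = V[, keep, drop = FALSE],
                 values = eg$values[pos][keep], moran = mi[keep], rule = rule),
            class = "mem_basis")
}

#' @export
print.mem_basis <- function(x, ...) {
  cat("<mem_basis>", ncol(x$vectors), "eigenvectors, rule =", x$rule, "\n")
  invisible(x)
}

# z-scores from Phi^-1 overflow past |z| ~ 8.21 in double precision
Z_CAP <- 8.209536

# signed z from a two-tailed p, capped
signed_z <- function(p, sign) {
  z <- stats::qnorm(p / 2, lower.tail = FALSE)
  sign(sign) * pmin(z, Z_CAP)
}

#' Spatially adjusted Spearman correlation
#'
#' Rank-transforms both variables (average ranks for ties), residualizes
#' each rank vector on the intercept plus the MEM basis, and correlates the
#' residuals. With an empty basis this is exactly the classical Spearman
#' correlation. t = rho * sqrt((n - 2 - k) / (1 - rho^2)) with k the basis
#' size; z is the signed normal quantile of the two-tailed p, capped at
#' +/- 8.21 where the quantile function saturates.
#'
#' @param values_a,values_b numeric vectors of equal length >= 10.
#' @param basis a [build_mem_basis()] result, or NULL for no adjustment.
#' @return list with `rho`, `t_stat`, `z`, `p`, `n`, `k`, `z_capped`.
#' @export
adjusted_spearman <- function(values_a, values_b, basis = NULL) {
  n <- length(values_a)
  if (length(values_b) != n) stop("lengths differ")
  if (n < 10) stop("need at least 10 paired observations")
  ra <- rank(values_a); rb <- rank(values_b)
  if (stats::sd(ra) == 0 || stats::sd(rb) == 0)
    stop("correlation undefined: a variable is constant after ranking")
  k <- if (is.null(basis)) 0L else ncol(basis$vectors)
  if (k > 0) {
    Q <- qr.Q(qr(cbind(1, basis$vectors)))
    ra <- ra - Q %*% crossprod(Q, ra)
    rb <- rb - Q %*% crossprod(Q, rb)
  } else {
    ra <- ra - mean(ra); rb <- rb - mean(rb)
  }
  rho <- as.numeric(crossprod(ra, rb) /
                      sqrt(crossprod(ra) * crossprod(rb)))
  rho <- max(-1, min(1, rho))
  dfree <- n - 2 - k
  if (dfree < 1) stop("basis too large for sample size")
  tt <- rho * sqrt(dfree / max(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), dfree)
  z <- signed_z(max(p, .Machine$double.xmin), rho)
  list(rho = rho, t_stat = tt, z = z, p = p, n = n, k = k,
       z_capped = abs(z) >= Z_CAP)
}

#' Per-donor probe-map association
#'
#' For one donor: matches samples to the map, builds the MEM basis from the
#' retained sample coordinates, and computes the adjusted Spearman
#' correlation of every probe's expression with the map. Vectorized over
#' probes (one basis projection, shared across probes).
#'
#' @param donor a filtered `donor_expression` object.
#' @param tmap a `tmap` or [volume_image()].
#' @param mem_k MEM retention: NULL = positive-Moran rule, 0 = no
#'   adjustment, integer = top-k.
#' @return data.frame per probe: probe_id, gene_symbol, rho, t_stat, z,
#'   n_samples, donor_id.
#' @export
donor_association <- function(donor, tmap, mem_k = NULL) {
  mt <- match_samples_to_map(tmap, donor$samples)
  E <- donor$expr[, mt$kept, drop = FALSE]
  n <- ncol(E)
  if (n < 10) stop("fewer than 10 samples retained for donor")
  coords <- as.matrix(donor$samples[mt$kept, c("x_mm", "y_mm", "z_mm")])
  basis <- if (!is.null(mem_k) && mem_k == 0) NULL
           else build_mem_basis(coords, k = mem_k)
  k <- if (is.null(basis)) 0L else ncol(basis$vectors)
  rt <- rank(mt$t_values)
  RE <- t(apply(E, 1, rank))
  Q <- qr.Q(qr(cbind(matrix(1, n, 1), if (k > 0) basis$vectors)))
  rt <- rt - Q %*% crossprod(Q, rt)
  RE <- RE - t(Q %*% crossprod(Q, t(RE)))
  num <- as.numeric(RE %*% rt)
  den <- sqrt(rowSums(RE^2) * sum(rt^2))
  rho <- pmax(-1, pmin(1, num / den))
  dfree <- n - 2 - k
  if (dfree < 1) stop("MEM basis too large for donor sample count")
  tt <- rho * sqrt(dfree / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), dfree)
  z <- signed_z(pmax(p, .Machine$double.xmin), rho)
  data.frame(probe_id = donor$probes$probe_id,
             gene_symbol = donor$probes$gene_symbol,
             rho = rho, t_stat = tt, z = z,
             n_samples = n, donor_id = donor$donor_id,
             stringsAsFactors = FALSE)
}

#' Combine per-donor z-scores with a weighted Stouffer sum
#'
#' Z = sum(w_i z_i) / sqrt(sum(w_i^2)); p = 2 (1 - Phi(|Z|)). With equal
#' weights this is the classical unweighted Stouffer combination.
#'
#' @param z per-donor z-scores for one probe.
#' @param weights per-donor weights; default the donor sample counts.
#' @return list with `z` (combined) and `p` (two-tailed).
#' @export
combine_donors <- function(z, weights = rep(1, length(z))) {
  if (!length(z)) stop("no donors")
  if (length(weights) != length(z)) stop("weights length mismatch")
  if (all(weights == 0)) stop("all weights are zero")
  Z <- sum(weights * z) / sqrt(sum(weights^2))
  list(z = Z, p = 2 * stats::pnorm(-abs(Z)))
}

#' Full association stage: donors -> combined gene table
#'
#' Runs [donor_association()] per donor, combines each probe's per-donor
#' z-scores with sample-count weights, then collapses probes to genes:
#' gene T is the mean of the probes' (sample-count-weighted mean) t
#' statistics, gene Z the mean of probe combined Z (exact under perfect
#' inter-probe correlation, conservative otherwise), gene p its normal
#' two-tailed transform. Probes of one gene disagreeing in sign are kept.
#'
#' @param donors list of filtered `donor_expression` objects.
#' @param tmap a `tmap` or [volume_image()].
#' @param mem_k see [donor_association()].
#' @param weights `"n"` (donor sample count, default), `"sqrt_n"`, or
#'   `"equal"`.
#' @return object of class `gene_table`: data.frame gene, T, Z, p,
#'   n_probes, n_donors.
#' @export
associate_genes <- function(donors, tmap, mem_k = NULL, weights = "n") {
  per_donor <- lapply(donors, donor_association, tmap = tmap, mem_k = mem_k)
  all_res <- do.call(rbind, per_donor)
  wfun <- switch(weights,
                 n = function(n) n,
                 sqrt_n = function(n) sqrt(n),
                 equal = function(n) rep(1, length(n)),
                 stop("unknown weights rule: ", weights))
  probe_ids <- unique(all_res$probe_id)
  probe_stats <- do.call(rbind, lapply(probe_ids, function(pid) {
    r <- all_res[all_res$probe_id == pid, ]
    w <- wfun(r$n_samples)
    comb <- combine_donors(r$z, w)
    data.frame(probe_id = pid, gene_symbol = r$gene_symbol[1],
               t_mean = sum(w * r$t_stat) / sum(w),
               z = comb$z, n_donors = nrow(r), stringsAsFactors = FALSE)
  }))
  gene_level(probe_stats)
}

#' Collapse probe-level statistics to genes
#'
#' @param probe_stats data.frame with gene_symbol, t_mean, z, n_donors.
#' @return `gene_table` data.frame: gene, T, Z, p, n_probes, n_donors.
#' @export
gene_level <- function(probe_stats) {
  sp <- split(probe_stats, probe_stats$gene_symbol)
  out <- do.call(rbind, lapply(sp, function(r) {
    Zg <- mean(r$z)
    data.frame(gene = r$gene_symbol[1], T = mean(r$t_mean), Z = Zg,
               p = 2 * stats::pnorm(-abs(Zg)), n_probes = nrow(r),
               n_donors = max(r$n_donors), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out <- out[order(out$gene), ]
  class(out) <- c("gene_table", "data.frame")
  out
}

#' Top-fraction gene lists
#'
#' The positive list holds the `ceiling(frac * N)` genes with the largest
#' association T, the negative list the same count with the smallest; ties
#' break by gene symbol so the lists are deterministic and disjoint.
#'
#' @param genes a `gene_table`.
#' @param frac fraction in (0, 0.5].
#' @return list with `positive` and `negative` character vectors.
#' @export
top_fraction_lists <- function(genes, frac = 0.1) {
  if (frac <= 0 || frac > 0.5) stop("frac must be in (0, 0.5]")
  if (nrow(genes) < 10) stop("need at least 10 genes")
  m <- ceiling(frac * nrow(genes))
  # opposite tie orders keep the lists disjoint even on a fully tied table
  pos_ord <- order(-genes$T, xtfrm(genes$gene))
  neg_ord <- order(genes$T, -xtfrm(genes$gene))
  list(positive = genes$gene[pos_ord][seq_len(m)],
       negative = genes$gene[neg_ord][seq_len(m)])
}
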