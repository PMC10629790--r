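#' Cell-type specificity matrix
#'
#' Specificity of gene g for cell type c is its mean expression in c
#' divided by its summed mean expression over all types; rows sum to 1.
#' Genes with zero expression everywhere are dropped with a warning.
#'
#' @param mean_expr gene x cell-type matrix of nonnegative mean expression.
#' @return object of class `specificity_matrix`: matrix with rows summing
#'   to 1; dropped genes recorded in attribute `dropped`.
#' @export
compute_specificity <- function(mean_expr) {
  mean_expr <- as.matrix(mean_expr)
  if (any(mean_expr < 0)) stop("mean expression must be nonnegative")
  tot <- rowSums(mean_expr)
  drop <- tot == 0
  if (any(drop)) {
    warning(sum(drop), " all-zero gene(s) dropped: ",
            paste(utils::head(rownames(mean_expr)[drop], 5), collapse = ", "))
    mean_expr <- mean_expr[!drop, , drop = FALSE]
    tot <- tot[!drop]
  }
  S <- mean_expr / tot
  attr(S, "dropped") <- rownames(mean_expr)[drop]
  class(S) <- c("specificity_matrix", class(S))
  S
}

#' Joint transcript-length / GC decile bins
#'
#' Assigns each gene to one cell of an n_bins x n_bins grid cut at the
#' marginal quantiles of transcript length and GC content. Null gene draws
#' that respect the target list's bin composition control for both
#' covariates at once.
#'
#' @param genes character vector of gene ids.
#' @param length_bp,gc numeric vectors aligned with `genes`.
#' @param n_bins marginal bins per covariate (1 = unmatched sampling).
#' @return integer vector of bin ids named by gene.
#' @export
matched_bins <- function(genes, length_bp, gc, n_bins = 10) {
  if (!all(is.finite(length_bp)) || !all(is.finite(gc)))
    stop("length and GC must be finite")
  if (n_bins^2 > length(genes))
    stop("n_bins^2 exceeds the number of genes; use fewer bins")
  cutq <- function(x) {
    if (n_bins == 1) return(rep(1L, length(x)))
    q <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1)))
    as.integer(cut(x, q, include.lowest = TRUE))
  }
  b <- (cutq(length_bp) - 1L) * n_bins + cutq(gc)
  stats::setNames(b, genes)
}

#' Expression-weighted cell-type enrichment test
#'
#' The statistic for cell type c is the summed specificity of the target
#' list in c. The null resamples gene lists of the same size whose
#' composition over the joint length/GC bins matches the target's, so
#' enrichment cannot be driven by transcript length or GC content.
#' p = (1 + #\{null >= observed\}) / (1 + n_perm) per type (upper tail),
#' Benjamini-Hochberg corrected across the cell types of the run.
#'
#' @param target character vector of target genes; genes absent from the
#'   matrix are dropped and counted.
#' @param S a [compute_specificity()] matrix.
#' @param gene_info data.frame with columns gene, length_bp, gc; NULL
#'   disables covariate matching (single bin).
#' @param n_perm bootstrap permutations.
#' @param n_bins marginal bins for [matched_bins()].
#' @param seed integer seed.
#' @return object of class `ewce_result`: data.frame per cell type with
#'   observed, null_mean, null_sd, sd_from_mean, fold_change, p, p_adj;
#'   attributes `n_dropped`, `n_perm`, `seed`.
#' @export
ewce_test <- function(target, S, gene_info = NULL, n_perm = 100000,
                      n_bins = 10, seed = 1L) {
  genes <- rownames(S)
  dropped <- setdiff(target, genes)
  target <- intersect(target, genes)
  if (!length(target)) stop("no target genes present in the specificity matrix")
  bins <- if (is.null(gene_info)) stats::setNames(rep(1L, length(genes)), genes)
          else {
            gi <- gene_info[match(genes, gene_info$gene), ]
            matched_bins(genes, gi$length_bp, gi$gc, n_bins)
          }
  by_bin <- split(genes, bins)
  target_bins <- table(bins[target])
  obs <- colSums(S[target, , drop = FALSE])
  null_sums <- with_seed(substream_seed(seed, 17L), {
    out <- matrix(0, n_perm, ncol(S))
    for (i in seq_len(n_perm)) {
      draw <- unlist(lapply(names(target_bins), function(b) {
        pool <- by_bin[[b]]
        if (length(pool) == 1) pool
        else sample(pool, target_bins[[b]], replace = length(pool) < target_bins[[b]])
      }), use.names = FALSE)
      out[i, ] <- colSums(S[draw, , drop = FALSE])
    }
    out
  })
  null_mean <- colMeans(null_sums)
  null_sd <- apply(null_sums, 2, stats::sd)
  pvals <- (1 + colSums(null_sums >= rep(obs, each = n_perm))) / (1 + n_perm)
  res <- data.frame(
    celltype = colnames(S),
    observed = obs,
    null_mean = null_mean,
    null_sd = null_sd,
    sd_from_mean = (obs - null_mean) / null_sd,
    fold_change = obs / null_mean,
    p = pvals,
    p_adj = bh_adjust(pvals),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(res, class = c("ewce_result", "data.frame"),
            n_dropped = length(dropped), n_perm = n_perm, seed = seed)
}

#' Hypergeometric overlap of a target list with a DEG list
#'
#' Inclusive upper tail: p = P(X >= k) with
#' X ~ Hypergeometric(N, K = |deg|, n = |target|), k the overlap.
#'
#' @param target,deg character vectors, both subsets of `universe`.
#' @param universe character vector (the gene universe) or its size.
#' @return list with `k`, `K`, `n`, `N`, `p`.
#' @export
hypergeom_overlap <- function(target, deg, universe) {
  if (is.character(universe)) {
    off <- setdiff(c(target, deg), universe)
    if (length(off))
      stop("genes outside the universe: ",
           paste(utils::head(off, 5), collapse = ", "))
    N <- length(unique(universe))
  } else N <- as.integer(universe)
  target <- unique(target); deg <- unique(deg)
  k <- length(intersect(target, deg))
  K <- length(deg); n <- length(target)
  if (K > N || n > N) stop("list larger than universe")
  p <- if (k == 0) 1 else stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  list(k = k, K = K, n = n, N = N, p = p)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate correction; thin wrapper over
#' `p.adjust(method = "BH")` so every module shares one kernel.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values, original order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
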