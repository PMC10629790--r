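# Small in-code fixtures shared across test files.

# A donor-expression-like object built by hand, for exercising the probe
# filters without the full generator.
make_toy_donor <- function(expr, probes, samples = NULL, ab = NULL) {
  ns <- ncol(expr)
  if (is.null(samples))
    samples <- data.frame(id = sprintf("s%d", seq_len(ns)),
                          x_mm = seq_len(ns), y_mm = 0, z_mm = 0,
                          structure = "cortex", cortical = TRUE,
                          hemisphere = "L", stringsAsFactors = FALSE)
  if (is.null(ab)) ab <- matrix(TRUE, nrow(expr), ns)
  rownames(expr) <- probes$probe_id
  rownames(ab) <- probes$probe_id
  structure(list(donor_id = "toy", samples = samples, expr = expr,
                 probes = probes, above_background = ab),
            class = "donor_expression")
}

toy_probe_row <- function(id, gene, n_mapped = 1L, intergenic = FALSE) {
  data.frame(probe_id = id, gene_symbol = gene, n_genes_mapped = n_mapped,
             intergenic = intergenic, stringsAsFactors = FALSE)
}

# Independent hypergeometric upper-tail oracle by exhaustive enumeration
# over all subsets (small N only): P(overlap >= k) when drawing n of N
# with K marked.
enum_hyper_upper <- function(k, K, n, N) {
  total <- choose(N, n)
  sum(vapply(k:min(K, n), function(j)
    choose(K, j) * choose(N - K, n - j), numeric(1))) / total
}

# Independent BH step-up oracle applied by the hand rule.
hand_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}
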