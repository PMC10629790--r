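#' Group summary (mean, SD, n)
#'
#' Container for a group's printed summary statistics, as reported in a
#' demographics table.
#'
#' @param mean,sd,n sample mean, sample SD (>= 0), group size (>= 2).
#' @return object of class `group_summary`.
#' @export
group_summary <- function(mean, sd, n) {
  if (sd < 0) stop("sd must be nonnegative")
  if (n < 2) stop("n must be >= 2")
  structure(list(mean = mean, sd = sd, n = as.integer(n)),
            class = "group_summary")
}

#' Pooled two-sample t-test from summary statistics
#'
#' Student's pooled-variance t-test computed from each group's printed
#' mean, SD and n — identical to the raw-data pooled t-test on any dataset
#' with those moments. sp^2 = ((n_a-1)s_a^2 + (n_b-1)s_b^2) / (n_a+n_b-2);
#' t = (m_a - m_b) / (sp sqrt(1/n_a + 1/n_b)); df = n_a + n_b - 2.
#'
#' @param a,b [group_summary()] objects (or lists with mean, sd, n).
#' @return list with `t`, `df`, `p` (two-tailed).
#' @export
pooled_ttest_from_summary <- function(a, b) {
  df <- a$n + b$n - 2L
  sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
  if (sp2 == 0) {
    if (a$mean == b$mean) return(list(t = 0, df = df, p = 1))
    stop("zero pooled variance with unequal means: degenerate input")
  }
  t <- (a$mean - b$mean) / sqrt(sp2 * (1 / a$n + 1 / b$n))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Pearson chi-square test on a 2x2 table
#'
#' Uncorrected by default (no Yates continuity correction); closed form
#' chi2 = N (ad - bc)^2 / (r1 r2 c1 c2) on 1 degree of freedom.
#'
#' @param counts 2x2 matrix (or length-4 vector, row-major) of nonnegative
#'   integer counts with positive margins.
#' @param yates apply the continuity correction.
#' @return list with `chi2`, `df` (= 1), `p`.
#' @export
chi2_2x2 <- function(counts, yates = FALSE) {
  m <- if (is.matrix(counts)) counts else matrix(counts, 2, 2, byrow = TRUE)
  if (!all(dim(m) == 2)) stop("counts must be 2x2")
  if (any(m < 0)) stop("negative counts")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("zero margin: test undefined")
  N <- sum(m)
  num <- abs(m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1])
  if (yates) num <- max(0, num - N / 2)
  chi2 <- N * num^2 / prod(rowSums(m), colSums(m))
  list(chi2 = chi2, df = 1L, p = stats::pchisq(chi2, 1, lower.tail = FALSE))
}
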