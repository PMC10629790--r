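#' Over-representation analysis of a gene list against term sets
#'
#' Hypergeometric upper-tail test per term (same kernel as
#' [hypergeom_overlap()]), Benjamini-Hochberg corrected across the tested
#' terms; a term is significant when its adjusted p falls below `alpha`.
#'
#' @param target character vector, subset of `universe`.
#' @param annotations named list: term id -> character vector of genes.
#' @param universe character vector of all candidate genes.
#' @param alpha significance threshold on adjusted p.
#' @return object of class `ora_result`: data.frame term, k, K, n, N, p,
#'   p_adj, significant.
#' @export
ora_test <- function(target, annotations, universe, alpha = 0.05) {
  if (!length(universe)) stop("empty universe")
  universe <- unique(universe)
  off <- setdiff(target, universe)
  if (length(off))
    stop("target genes outside the universe: ",
         paste(utils::head(off, 5), collapse = ", "))
  target <- unique(target)
  rows <- lapply(names(annotations), function(tm) {
    gs <- intersect(unique(annotations[[tm]]), universe)
    h <- hypergeom_overlap(target, gs, universe)
    data.frame(term = tm, k = h$k, K = h$K, n = h$n, N = h$N, p = h$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out$significant <- out$p_adj < alpha
  class(out) <- c("ora_result", "data.frame")
  out
}

#' Summarize significant terms into broad categories
#'
#' @param significant_terms character vector of term ids.
#' @param dictionary named character vector or data.frame (term_id,
#'   category); terms it does not cover fall into "uncategorized".
#' @return data.frame category, count, proportion (proportions sum to 1
#'   over the significant terms; empty input gives an empty summary).
#' @export
summarize_categories <- function(significant_terms, dictionary) {
  if (is.data.frame(dictionary))
    dictionary <- stats::setNames(dictionary$category, dictionary$term_id)
  if (!length(significant_terms))
    return(data.frame(category = character(0), count = integer(0),
                      proportion = numeric(0)))
  cat_of <- dictionary[significant_terms]
  cat_of[is.na(cat_of)] <- "uncategorized"
  tb <- table(cat_of)
  out <- data.frame(category = names(tb), count = as.integer(tb),
                    proportion = as.numeric(tb) / length(significant_terms),
                    stringsAsFactors = FALSE)
  out[order(-out$count, out$category), , drop = FALSE]
}

#' Read a GMT annotation file
#'
#' Standard tab-separated gene-set format: term id, description, genes.
#'
#' @param path GMT file path.
#' @return named list of gene vectors, with term descriptions as the
#'   `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, "", 1)
  attr(sets, "descriptions") <- vapply(parts, `[`, "", 2)
  sets
}
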