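# Gene-set overlap statistics: the brain-expression filter, upper-tail
# hypergeometric overlap tests, multiple-testing adjustment, and generic
# over-representation analysis over a GMT-style collection.

#' Filter genes by mean normalized expression
#'
#' Keeps genes whose row mean is strictly greater than `threshold` — the
#' brain-expressed filter (mean RPKM-like value > 0.1 by default). A gene
#' with mean exactly equal to the threshold is excluded.
#'
#' @param rpkm Gene x sample matrix of normalized expression values.
#' @param threshold Strict lower bound on the per-gene mean.
#' @return Character vector of retained gene identifiers.
#' @export
filter_expressed <- function(rpkm, threshold = 0.1) {
  check_expression_matrix(rpkm, "normalized expression matrix")
  if (nrow(rpkm) == 0L) rlang::abort("expression matrix has no genes")
  rownames(rpkm)[rowMeans(rpkm) > threshold]
}

#' Upper-tail hypergeometric overlap test between two gene sets
#'
#' Tests whether `set_a` and `set_b` overlap more than expected among a
#' finite universe: with population `N = |universe|`, `K = |set_a|` successes
#' and `n = |set_b|` draws, `p = P(X >= k)` for the observed overlap `k`
#' (the observed value is included in the tail). Genes outside the universe
#' are dropped with a message. The test is symmetric in `set_a`/`set_b`.
#'
#' @param set_a,set_b Character vectors of gene identifiers.
#' @param universe Character vector defining the finite population.
#' @return One-row tibble: `N`, `K`, `n`, `k`, `p`.
#' @export
#' @examples
#' hypergeometric_overlap(c("a", "b"), c("b", "c"), letters[1:10])
hypergeometric_overlap <- function(set_a, set_b, universe) {
  check_genes(universe, "universe")
  if (length(universe) == 0L) rlang::abort("universe is empty")
  a <- drop_unknown_genes(unique(set_a), universe, "set_a")
  b <- drop_unknown_genes(unique(set_b), universe, "set_b")
  N <- length(universe); K <- length(a); n <- length(b)
  k <- length(intersect(a, b))
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  tibble::tibble(N = N, K = K, n = n, k = k, p = p)
}

#' Adjust p-values for multiple testing
#'
#' Bonferroni (`min(1, m * p)`) or Benjamini-Hochberg step-up with
#' monotonicity enforcement; output order matches input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param method `"bonferroni"` or `"bh"`.
#' @return Adjusted p-values in input order.
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "bh")) {
  method <- match.arg(method)
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1)) {
    rlang::abort("p-values must be numeric in [0, 1]")
  }
  stats::p.adjust(p, method = if (method == "bh") "BH" else "bonferroni")
}

#' Over-representation analysis of a query set against a collection
#'
#' One upper-tail hypergeometric test per collection set, BH-adjusted across
#' the collection. A set is flagged significant when `p <= p_cutoff` and
#' `p_adjusted <= q_cutoff`. Results are sorted by p ascending with ties
#' broken by set name.
#'
#' @param query Character vector of genes of interest.
#' @param collection A `gene_set_collection` (named list of gene vectors).
#' @param universe Background gene identifiers; query/collection genes
#'   outside it are dropped with a message.
#' @param p_cutoff,q_cutoff Significance cutoffs on raw and adjusted p.
#' @return Tibble: `set_name`, `N`, `K`, `n`, `k`, `p`, `p_adjusted`,
#'   `significant`, of class `ab_ora`.
#' @export
over_representation <- function(query, collection, universe,
                                p_cutoff = 0.01, q_cutoff = 0.05) {
  collection <- new_gene_set_collection(collection)
  check_genes(universe, "universe")
  query <- drop_unknown_genes(unique(query), universe, "query")
  if (length(collection) == 0L) {
    out <- tibble::tibble(set_name = character(0), N = integer(0),
                          K = integer(0), n = integer(0), k = integer(0),
                          p = numeric(0), p_adjusted = numeric(0),
                          significant = logical(0))
    return(structure(out, class = c("ab_ora", class(out))))
  }
  N <- length(universe); K <- length(query)
  rows <- lapply(names(collection), function(nm) {
    s <- intersect(collection[[nm]], universe)
    k <- length(intersect(query, s))
    tibble::tibble(set_name = nm, N = N, K = K, n = length(s), k = k,
                   p = stats::phyper(k - 1, K, N - K, length(s),
                                     lower.tail = FALSE))
  })
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- adjust_pvalues(out$p, "bh")
  out$significant <- out$p <= p_cutoff & out$p_adjusted <= q_cutoff
  out <- dplyr::arrange(out, .data$p, .data$set_name)
  structure(out, class = c("ab_ora", class(out)))
}

#' Compare two key gene sets
#'
#' Reports the overlap count and the overlap as a percentage of each set
#' (rounded to one decimal), the comparison used for key sets across regions.
#'
#' @param set_a,set_b Nonempty character vectors.
#' @param name_a,name_b Labels for the report.
#' @return One-row tibble: `set_a`, `set_b`, `size_a`, `size_b`, `overlap`,
#'   `pct_of_a`, `pct_of_b`.
#' @export
compare_key_sets <- function(set_a, set_b, name_a = "set_a", name_b = "set_b") {
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (length(set_a) == 0L || length(set_b) == 0L) {
    rlang::abort("compare_key_sets requires two nonempty gene sets")
  }
  k <- length(intersect(set_a, set_b))
  na_ <- length(set_a); nb_ <- length(set_b)
  tibble::tibble(
    set_a = name_a, set_b = name_b,
    size_a = na_, size_b = nb_, overlap = k,
    pct_of_a = round(100 * k / na_, 1),
    pct_of_b = round(100 * k / nb_, 1)
  )
}
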