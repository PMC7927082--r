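# Brain-expressed PPI degrees and the bootstrap comparison of a gene set's
# mean degree against the brain-expressed background.

#' Brain-expressed PPI degrees
#'
#' Keeps only edges whose both endpoints are brain-expressed and counts each
#' gene's retained partners. Every brain-expressed gene appears in the
#' result, with degree 0 when it has no retained edge (including genes
#' absent from the graph, which have no interaction evidence).
#'
#' @param graph A [ppi_graph()].
#' @param brain_expressed Nonempty character vector of brain-expressed
#'   genes.
#' @return Tibble of class `ab_degrees`: `gene`, `degree`, sorted by gene.
#' @export
bppi_degrees <- function(graph, brain_expressed) {
  stopifnot(inherits(graph, "ppi_graph"))
  check_genes(brain_expressed, "brain-expressed set")
  if (length(brain_expressed) == 0L) rlang::abort("brain-expressed set is empty")
  if (nrow(graph$edges) + length(graph$nodes) == 0L) rlang::abort("graph is empty")
  keep <- graph$edges$from %in% brain_expressed &
    graph$edges$to %in% brain_expressed
  dropped <- sum(!keep)
  if (dropped > 0) {
    rlang::inform(sprintf("dropped %d edge(s) with a non-brain-expressed endpoint", dropped))
  }
  e <- graph$edges[keep, , drop = FALSE]
  genes <- sort(unique(brain_expressed))
  deg <- stats::setNames(integer(length(genes)), genes)
  tab <- table(c(e$from, e$to))
  deg[names(tab)] <- as.integer(tab)
  out <- tibble::tibble(gene = genes, degree = unname(deg))
  structure(out, class = c("ab_degrees", class(out)))
}

#' Empirical p-values from bootstrap exceedance counts
#'
#' Raw-fraction convention used by the degree test: ties count toward
#' "larger" (`p_larger = n_ge / n_boot` with `n_ge` the number of bootstrap
#' means `>=` the observed mean), "smaller" is the strict complement, and
#' the two-tailed p is `2 * min(p_larger, p_smaller)` capped at 1. With
#' 10,000 resamples and 38 exceedances this yields `p_larger = 0.0038`.
#'
#' @param n_ge Number of bootstrap statistics `>=` the observed one.
#' @param n_boot Total number of bootstrap resamples.
#' @return List: `n_ge`, `n_lt`, `p_larger`, `p_smaller`, `p_two_tailed`.
#' @export
degree_bootstrap_pvalues <- function(n_ge, n_boot) {
  n_lt <- n_boot - n_ge
  p_larger <- n_ge / n_boot
  p_smaller <- n_lt / n_boot
  list(n_ge = n_ge, n_lt = n_lt, p_larger = p_larger, p_smaller = p_smaller,
       p_two_tailed = min(1, 2 * min(p_larger, p_smaller)))
}

#' Bootstrap test of a gene set's mean PPI degree against background
#'
#' The observed statistic is the target set's mean brain-expressed degree.
#' Each of `n_boot` bootstrap draws picks `|target|` genes uniformly without
#' replacement from all genes of the degree table and records their mean
#' degree. P-values use the raw-fraction convention:
#' `p_larger = #\{boot >= observed\} / n_boot` (ties count as larger),
#' `p_smaller = #\{boot < observed\} / n_boot`, and
#' `p_two_tailed = min(1, 2 * min(p_larger, p_smaller))`. Genes are sorted
#' internally before sampling, so results do not depend on input order.
#'
#' @param degrees Tibble from [bppi_degrees()] (columns `gene`, `degree`).
#' @param target Character vector of target genes; genes absent from the
#'   degree table are dropped with a message.
#' @param n_boot Number of bootstrap draws.
#' @param seed Integer seed.
#' @param set_name Label carried into the result.
#' @return One-row tibble of class `ab_degree_boot`: `set_name`, `n_genes`,
#'   `observed_mean`, `n_boot`, `n_ge`, `n_lt`, `p_larger`, `p_smaller`,
#'   `p_two_tailed`, `seed`. Attribute `boot_means` holds the bootstrap
#'   distribution; attribute `p_convention` records the tie rule.
#' @export
degree_bootstrap_test <- function(degrees, target, n_boot = 10000L, seed = 1L,
                                  set_name = "target") {
  stopifnot(all(c("gene", "degree") %in% names(degrees)), n_boot >= 1)
  genes <- sort(degrees$gene)
  deg <- stats::setNames(degrees$degree, degrees$gene)[genes]
  target <- drop_unknown_genes(unique(target), genes, "target set")
  if (length(target) == 0L) rlang::abort("no target gene is present in the degree table")
  if (length(target) > length(genes)) rlang::abort("target larger than background")
  m <- length(target)
  observed <- mean(deg[target])
  boot <- with_seed(seed, {
    idx <- vapply(seq_len(n_boot), function(i) sample.int(length(genes), m),
                  integer(m))
    colMeans(matrix(deg[idx], nrow = m))
  })
  n_ge <- sum(boot >= observed - 1e-12)
  pv <- degree_bootstrap_pvalues(n_ge, n_boot)
  out <- tibble::tibble(
    set_name = set_name, n_genes = m, observed_mean = observed,
    n_boot = as.integer(n_boot), n_ge = as.integer(pv$n_ge),
    n_lt = as.integer(pv$n_lt), p_larger = pv$p_larger,
    p_smaller = pv$p_smaller, p_two_tailed = pv$p_two_tailed,
    seed = as.integer(seed)
  )
  structure(out, class = c("ab_degree_boot", class(out)),
            boot_means = boot,
            p_convention = "raw fraction, ties count toward 'larger'")
}
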