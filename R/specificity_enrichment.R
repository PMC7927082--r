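# Expression-weighted specificity enrichment: per-gene specificity across
# cell types / developmental periods, and a bootstrap test of whether a gene
# set's mean specificity for a group exceeds that of random gene sets of the
# same size.

#' Specificity matrix from group mean-expression profiles
#'
#' The specificity of gene g for group c is its mean expression in c divided
#' by the sum of its means over all groups, so each row sums to 1. Genes
#' whose row is entirely zero are dropped with a message.
#'
#' @param profiles Gene x group matrix of nonnegative mean expression
#'   values; >= 2 groups with unique names.
#' @return Gene x group matrix of row-proportions.
#' @export
specificity_matrix <- function(profiles) {
  check_expression_matrix(profiles, "group profile matrix")
  if (ncol(profiles) < 2L) rlang::abort("specificity needs >= 2 groups")
  if (anyDuplicated(colnames(profiles))) rlang::abort("group names must be unique")
  if (any(profiles < 0)) rlang::abort("group profile matrix has negative entries")
  totals <- rowSums(profiles)
  zero <- totals == 0
  if (any(zero)) {
    rlang::inform(sprintf("dropped %d gene(s) with all-zero profiles", sum(zero)))
    profiles <- profiles[!zero, , drop = FALSE]
    totals <- totals[!zero]
  }
  profiles / totals
}

#' Bootstrap enrichment of a gene set's expression specificity
#'
#' For each group, compares the target set's mean specificity with the
#' distribution of mean specificities of `n_boot` random gene sets of the
#' same size, drawn uniformly (without replacement within a draw) from all
#' genes of the specificity matrix. The empirical p-value uses the
#' pseudocount convention `p = (#\{boot >= observed\} + 1) / (n_boot + 1)`,
#' so it never returns 0. Genes are sorted internally before sampling, so
#' results do not depend on input order.
#'
#' @param spec Specificity matrix from [specificity_matrix()].
#' @param target Character vector of target genes; genes absent from `spec`
#'   are dropped with a message.
#' @param n_boot Number of bootstrap draws.
#' @param seed Integer seed.
#' @param p_threshold Reporting threshold for the `significant` flag.
#' @return Tibble of class `ab_specificity`: `group`, `n_target`,
#'   `observed_mean`, `boot_mean`, `boot_sd`, `fold`, `n_boot`, `p`,
#'   `significant`. Attribute `p_convention` records the pseudocount rule.
#' @export
bootstrap_specificity <- function(spec, target, n_boot = 10000L, seed = 1L,
                                  p_threshold = 0.01) {
  stopifnot(is.matrix(spec), is.numeric(spec), n_boot >= 1)
  genes <- sort(rownames(spec))
  spec <- spec[genes, , drop = FALSE]
  target <- drop_unknown_genes(unique(target), genes, "target set")
  if (length(target) == 0L) rlang::abort("target set shares no genes with the specificity matrix")
  if (length(target) > length(genes)) rlang::abort("target larger than background")
  m <- length(target)
  observed <- colMeans(spec[target, , drop = FALSE])
  boot <- with_seed(seed, {
    idx <- vapply(seq_len(n_boot), function(i) sample.int(length(genes), m),
                  integer(m))
    vapply(seq_len(ncol(spec)), function(g) {
      colMeans(matrix(spec[idx, g], nrow = m))
    }, numeric(n_boot))
  })
  boot <- matrix(boot, nrow = n_boot)  # n_boot x groups
  n_ge <- colSums(boot >= rep(observed, each = n_boot) - 1e-12)
  out <- tibble::tibble(
    group = colnames(spec),
    n_target = m,
    observed_mean = unname(observed),
    boot_mean = colMeans(boot),
    boot_sd = apply(boot, 2, stats::sd),
    fold = unname(observed) / colMeans(boot),
    n_boot = as.integer(n_boot),
    p = (n_ge + 1) / (n_boot + 1)
  )
  out$significant <- out$p < p_threshold
  structure(out, class = c("ab_specificity", class(out)),
            p_convention = "(n_ge + 1) / (n_boot + 1)", seed = seed)
}
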