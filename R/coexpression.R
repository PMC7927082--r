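# Weighted co-expression network construction and module detection:
# soft-thresholded unsigned adjacency, scale-free fit for power selection,
# topological overlap, average-linkage module detection with a static
# cut, module eigengenes, and eigengene-based module merging.

#' Soft-thresholded unsigned adjacency matrix
#'
#' `a_ij = |cor(x_i, x_j)|^beta` (Pearson), with the diagonal set to 0 so
#' that row sums are network connectivities.
#'
#' @param expr Gene x sample matrix; >= 3 samples, no zero-variance genes.
#' @param beta Positive integer soft-thresholding power.
#' @return Symmetric gene x gene matrix with entries in `[0, 1]`.
#' @export
adjacency_matrix <- function(expr, beta = 6L) {
  check_expression_matrix(expr)
  stopifnot(beta >= 1)
  if (ncol(expr) < 3L) rlang::abort("adjacency needs >= 3 samples")
  v <- apply(expr, 1, stats::var)
  if (any(v == 0)) {
    rlang::abort(paste0("zero-variance gene(s) present: ",
                        paste(utils::head(rownames(expr)[v == 0], 5),
                              collapse = ", ")))
  }
  a <- abs(stats::cor(t(expr)))^beta
  diag(a) <- 0
  a
}

#' Pick the soft-thresholding power by scale-free fit
#'
#' For each candidate power, gene connectivities `k_i = sum_j a_ij` are
#' binned into 10 equal-width bins; the scale-free fit is the squared
#' correlation of the regression of `log10` bin frequency on `log10` mean
#' bin connectivity (empty bins dropped). The selected power is the smallest
#' one whose fit reaches `target_r2` with a negative slope; if none
#' qualifies, the negative-slope power with the best fit is returned with a
#' warning.
#'
#' Powers whose mean connectivity falls below `min_mean_connectivity` are
#' excluded before the smallest-power rule: at such powers the network is
#' effectively edgeless, the topological overlap saturates, and the
#' scale-free statistic rewards degeneracy rather than topology (the cited
#' methodology's guidance to keep mean connectivity reasonably high).
#'
#' @param expr Gene x sample matrix (>= 10 genes).
#' @param candidate_powers Ascending integer powers to try.
#' @param target_r2 Scale-free fit threshold.
#' @param n_bins Number of connectivity bins.
#' @param min_mean_connectivity Exclude powers with mean connectivity below
#'   this from selection (all fits are still reported).
#' @return List with `beta` (selected power) and `fits`, a tibble of class
#'   `ab_sft`: `beta`, `r_squared`, `slope`, `mean_connectivity`.
#' @export
pick_soft_threshold <- function(expr, candidate_powers = 1:20,
                                target_r2 = 0.9, n_bins = 10L,
                                min_mean_connectivity = 1) {
  check_expression_matrix(expr)
  stopifnot(length(candidate_powers) > 0, !is.unsorted(candidate_powers))
  if (nrow(expr) < 10L) rlang::abort("scale-free fit needs >= 10 genes")
  r <- abs(stats::cor(t(expr)))
  diag(r) <- 0
  fits <- lapply(candidate_powers, function(beta) {
    k <- rowSums(r^beta)
    fit <- scale_free_fit(k, n_bins)
    tibble::tibble(beta = as.integer(beta), r_squared = fit$r_squared,
                   slope = fit$slope, mean_connectivity = mean(k))
  })
  fits <- dplyr::bind_rows(fits)
  eligible <- fits$mean_connectivity >= min_mean_connectivity
  if (!any(eligible)) eligible <- rep(TRUE, nrow(fits))
  ok <- eligible & fits$r_squared >= target_r2 & fits$slope < 0
  if (any(ok)) {
    beta <- fits$beta[which(ok)[1]]
  } else {
    neg <- eligible & fits$slope < 0
    if (!any(neg)) rlang::abort("no candidate power yields a negative-slope fit")
    beta <- fits$beta[neg][which.max(fits$r_squared[neg])]
    rlang::warn(sprintf(
      "no power reached scale-free R^2 >= %.2f; using beta = %d (best R^2 = %.3f)",
      target_r2, beta, max(fits$r_squared[neg])))
  }
  structure(list(beta = beta, fits = structure(fits, class = c("ab_sft", class(fits)))),
            class = "ab_sft_pick")
}

# log10 frequency vs log10 mean connectivity over equal-width bins of k.
scale_free_fit <- function(k, n_bins = 10L) {
  k <- k[k > 0]
  if (length(k) < n_bins) return(list(r_squared = 0, slope = 0))
  breaks <- seq(min(k), max(k), length.out = n_bins + 1L)
  breaks[1] <- breaks[1] - 1e-9
  bin <- cut(k, breaks, include.lowest = TRUE)
  freq <- tapply(k, bin, length)
  mk <- tapply(k, bin, mean)
  keep <- !is.na(freq) & freq > 0
  if (sum(keep) < 3L) return(list(r_squared = 0, slope = 0))
  x <- log10(mk[keep]); y <- log10(freq[keep] / length(k))
  fit <- stats::lm(y ~ x)
  list(r_squared = summary(fit)$r.squared,
       slope = unname(stats::coef(fit)[2]))
}

#' Topological overlap similarity
#'
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_u a_iu a_uj`, `TOM_ii = 1`. The corresponding dissimilarity
#' used for clustering is `1 - TOM`.
#'
#' @param adj Symmetric adjacency with zero diagonal and entries in `[0, 1]`.
#' @return Symmetric TOM matrix with unit diagonal.
#' @export
tom_similarity <- function(adj) {
  stopifnot(is.matrix(adj), nrow(adj) == ncol(adj))
  if (any(adj < 0 | adj > 1)) rlang::abort("adjacency entries must be in [0, 1]")
  if (any(diag(adj) != 0)) rlang::abort("adjacency diagonal must be zero")
  if (max(abs(adj - t(adj))) > 1e-12) rlang::abort("adjacency must be symmetric")
  k <- rowSums(adj)
  l <- adj %*% adj
  denom <- outer(k, k, pmin) + 1 - adj
  tom <- (l + adj) / denom
  diag(tom) <- 1
  tom <- (tom + t(tom)) / 2
  dimnames(tom) <- dimnames(adj)
  tom
}

#' Detect modules by average-linkage clustering with a static cut
#'
#' Genes are sorted by identifier (so the partition is invariant to input
#' order), clustered by average linkage on the TOM dissimilarity, and the
#' dendrogram is cut at the fixed height `cut_height` on the dissimilarity
#' scale (the static tree cut; branches that only join above the cut stay
#' separate). Clusters with at least `min_module_size` genes become modules,
#' labelled `m1, m2, ...` by decreasing size (ties broken by smallest member
#' identifier); all other genes are `"unassigned"`.
#'
#' @param diss Symmetric dissimilarity matrix (zero diagonal) with gene
#'   dimnames, typically `1 - tom_similarity(adj)`.
#' @param min_module_size Minimum genes per retained module.
#' @param cut_height Absolute dissimilarity at which to cut the dendrogram.
#' @return Tibble of class `ab_partition`: `gene`, `module`.
#' @export
detect_modules <- function(diss, min_module_size = 30L, cut_height = 0.99) {
  stopifnot(is.matrix(diss), nrow(diss) == ncol(diss),
            !is.null(rownames(diss)))
  genes <- sort(rownames(diss))
  if (length(genes) < min_module_size) {
    rlang::warn("fewer genes than min_module_size; all genes unassigned")
    return(new_partition(genes, rep("unassigned", length(genes))))
  }
  diss <- diss[genes, genes]
  hc <- stats::hclust(stats::as.dist(diss), method = "average")
  cl <- stats::cutree(hc, h = cut_height)
  sizes <- table(cl)
  keep <- as.integer(names(sizes)[sizes >= min_module_size])
  labels <- rep("unassigned", length(genes))
  if (length(keep) > 0) {
    first_gene <- vapply(keep, function(cid) min(genes[cl == cid]), character(1))
    ord <- order(-as.integer(sizes[as.character(keep)]), first_gene)
    for (i in seq_along(ord)) {
      labels[cl == keep[ord[i]]] <- sprintf("m%d", i)
    }
  }
  new_partition(genes, labels)
}

new_partition <- function(genes, labels) {
  out <- tibble::tibble(gene = genes, module = labels)
  structure(out, class = c("ab_partition", class(out)))
}

#' Module eigengene
#'
#' First principal component across samples of the per-gene z-scored module
#' submatrix, unit norm, with the sign oriented so that the mean correlation
#' with member-gene profiles is positive. The fraction of variance explained
#' is attached as attribute `var_explained`.
#'
#' @param expr Gene x sample matrix containing the module's genes.
#' @param partition An `ab_partition` tibble (`gene`, `module`).
#' @param module Module label with >= 2 genes.
#' @return Named numeric vector over samples.
#' @export
module_eigengene <- function(expr, partition, module) {
  check_expression_matrix(expr)
  members <- partition$gene[partition$module == module]
  if (length(members) == 0L) rlang::abort(sprintf("module '%s' not found or empty", module))
  if (length(members) < 2L) rlang::abort("module eigengene needs >= 2 genes")
  members <- intersect(rownames(expr), members)
  x <- t(scale(t(expr[members, , drop = FALSE])))  # z-score each gene
  sv <- svd(t(x), nu = 1, nv = 0)
  e <- sv$u[, 1]
  if (mean(stats::cor(e, t(x))) < 0) e <- -e
  names(e) <- colnames(expr)
  attr(e, "var_explained") <- sv$d[1]^2 / sum(sv$d^2)
  e
}

#' Merge modules with correlated eigengenes
#'
#' Repeatedly merges the pair of modules whose eigengene dissimilarity
#' (`1 - cor`) is smallest, while that dissimilarity is below
#' `merge_height`, recomputing eigengenes after every merge. The
#' `"unassigned"` label never participates. Final modules are relabelled
#' `m1, m2, ...` by decreasing size.
#'
#' @param expr Gene x sample matrix.
#' @param partition An `ab_partition` tibble.
#' @param merge_height Dissimilarity threshold below which modules merge.
#' @return Tibble of class `ab_partition`.
#' @export
merge_close_modules <- function(expr, partition, merge_height = 0.25) {
  check_expression_matrix(expr)
  labels <- stats::setNames(partition$module, partition$gene)
  repeat {
    mods <- sort(setdiff(unique(labels), "unassigned"))
    if (length(mods) < 2L) break
    me <- vapply(mods, function(m) {
      module_eigengene(expr, new_partition(names(labels), unname(labels)), m)
    }, numeric(ncol(expr)))
    d <- 1 - stats::cor(me)
    diag(d) <- Inf
    ij <- which(d == min(d), arr.ind = TRUE)[1, ]
    if (d[ij[1], ij[2]] >= merge_height) break
    from <- mods[max(ij)]; into <- mods[min(ij)]
    labels[labels == from] <- into
  }
  relabel_by_size(new_partition(partition$gene,
                                unname(labels[partition$gene])))
}

# Rename modules m1..mk by decreasing size, ties by smallest member id.
relabel_by_size <- function(partition) {
  mods <- setdiff(unique(partition$module), "unassigned")
  if (length(mods) == 0L) return(partition)
  sizes <- vapply(mods, function(m) sum(partition$module == m), integer(1))
  first <- vapply(mods, function(m) min(partition$gene[partition$module == m]),
                  character(1))
  ord <- order(-sizes, first)
  map <- stats::setNames(sprintf("m%d", seq_along(ord)), mods[ord])
  lab <- partition$module
  assigned <- lab != "unassigned"
  lab[assigned] <- map[lab[assigned]]
  new_partition(partition$gene, lab)
}

#' Full co-expression network fit: power selection to merged modules
#'
#' Removes zero-variance genes (with a message), selects the
#' soft-thresholding power by scale-free fit, builds the unsigned adjacency
#' and topological overlap, detects modules with the static quantile cut,
#' and merges modules with correlated eigengenes.
#'
#' @param expr Gene x sample matrix (typically log2(normalized + 1)).
#' @param candidate_powers,target_r2 Passed to [pick_soft_threshold()].
#' @param min_module_size,cut_height Passed to [detect_modules()].
#' @param merge_height Passed to [merge_close_modules()].
#' @return Object of class `ab_coexpression`: list with `partition`
#'   (`ab_partition` tibble), `beta`, `fits`, `n_genes`, `n_samples`.
#' @export
fit_coexpression <- function(expr, candidate_powers = 1:20, target_r2 = 0.9,
                             min_module_size = 30L, cut_height = 0.99,
                             merge_height = 0.25) {
  check_expression_matrix(expr)
  v <- apply(expr, 1, stats::var)
  if (any(v == 0)) {
    rlang::inform(sprintf("removed %d zero-variance gene(s) before network construction",
                          sum(v == 0)))
    expr <- expr[v > 0, , drop = FALSE]
  }
  pick <- pick_soft_threshold(expr, candidate_powers, target_r2)
  adj <- adjacency_matrix(expr, pick$beta)
  tom <- tom_similarity(adj)
  part <- detect_modules(1 - tom, min_module_size, cut_height)
  part <- merge_close_modules(expr, part, merge_height)
  structure(list(partition = part, beta = pick$beta, fits = pick$fits,
                 n_genes = nrow(expr), n_samples = ncol(expr)),
            class = "ab_coexpression")
}

#' @export
print.ab_coexpression <- function(x, ...) {
  mods <- setdiff(unique(x$partition$module), "unassigned")
  cat(sprintf("<ab_coexpression> %d genes, %d samples, beta = %d, %d module(s)\n",
              x$n_genes, x$n_samples, x$beta, length(mods)))
  invisible(x)
}
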