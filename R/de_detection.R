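# Case-control differential expression on count data: median-of-ratios
# size factors, method-of-moments negative-binomial dispersion, and a Wald
# test of the two-group log-mean difference.

#' Median-of-ratios size factors
#'
#' For each sample, the factor is the median over reference genes (genes
#' with nonzero counts in every sample) of the ratio of the sample's count
#' to the gene's geometric mean across samples; factors are rescaled to
#' geometric mean 1.
#'
#' @param counts Gene x sample count matrix.
#' @return Named numeric vector of positive per-sample factors.
#' @export
size_factors <- function(counts) {
  check_expression_matrix(counts, "count matrix")
  log_gm <- rowMeans(log(counts))
  ok <- is.finite(log_gm)
  if (!any(ok)) {
    rlang::abort("no gene has nonzero counts in all samples; pre-filter low-count genes")
  }
  sf <- apply(counts[ok, , drop = FALSE], 2, function(col) {
    exp(stats::median(log(col) - log_gm[ok]))
  })
  sf <- sf / exp(mean(log(sf)))
  sf
}

#' Negative-binomial Wald test of case vs control expression
#'
#' Per gene: counts are normalized by [size_factors()]; dispersion is
#' estimated by method of moments from the pooled within-group variance of
#' normalized counts (floored at 1e-8); the log fold change is the log ratio
#' of fitted group means; its Wald standard error uses the NB variance
#' `mu + alpha * mu^2` of each group mean. When a group mean is zero the
#' group means are recomputed from raw group sums with a 0.5 pseudocount
#' before normalization. P-values are BH-adjusted across all tested genes.
#'
#' @param counts Gene x sample count matrix.
#' @param labels Character vector (length `ncol(counts)`) with values
#'   `"case"`/`"control"`; each group needs >= 2 samples.
#' @return Tibble of class `ab_de`: `gene`, `base_mean`, `log2_fc`
#'   (case vs control), `p`, `p_adjusted`.
#' @export
test_de <- function(counts, labels) {
  check_expression_matrix(counts, "count matrix")
  labels <- as.character(labels)
  stopifnot(length(labels) == ncol(counts))
  if (!all(labels %in% c("case", "control"))) {
    rlang::abort("labels must be 'case' or 'control'")
  }
  n1 <- sum(labels == "case"); n0 <- sum(labels == "control")
  if (n1 < 2 || n0 < 2) rlang::abort("each group needs at least 2 samples")

  sf <- size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")
  case <- labels == "case"; ctrl <- !case

  m1 <- rowMeans(norm[, case, drop = FALSE])
  m0 <- rowMeans(norm[, ctrl, drop = FALSE])
  ss1 <- rowSums((norm[, case, drop = FALSE] - m1)^2)
  ss0 <- rowSums((norm[, ctrl, drop = FALSE] - m0)^2)
  v <- (ss1 + ss0) / (n1 + n0 - 2)
  mu <- (n1 * m1 + n0 * m0) / (n1 + n0)
  alpha <- ifelse(mu > 0, pmax((v - mu) / mu^2, 1e-8), 1e-8)

  # pseudocount fallback only when a fitted group mean is zero
  zero <- (m1 == 0 | m0 == 0)
  if (any(zero)) {
    raw1 <- rowSums(counts[, case, drop = FALSE])[zero]
    raw0 <- rowSums(counts[, ctrl, drop = FALSE])[zero]
    m1[zero] <- (raw1 + 0.5) / sum(sf[case])
    m0[zero] <- (raw0 + 0.5) / sum(sf[ctrl])
  }

  beta <- log(m1) - log(m0)
  se <- sqrt((m1 + alpha * m1^2) / (n1 * m1^2) +
             (m0 + alpha * m0^2) / (n0 * m0^2))
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))

  silent <- mu == 0
  beta[silent] <- 0
  p[silent] <- 1

  out <- tibble::tibble(
    gene = rownames(counts),
    base_mean = unname(mu),
    log2_fc = unname(beta) / log(2),
    p = unname(p),
    p_adjusted = adjust_pvalues(unname(p), "bh")
  )
  structure(out, class = c("ab_de", class(out)))
}

#' Call differentially expressed genes
#'
#' A gene is a DEG when its adjusted p-value is strictly below
#' `p_adj_threshold` and its absolute fold change strictly exceeds
#' `fc_threshold` in either direction. `fc_scale` selects whether
#' `fc_threshold` is on the linear fold-change scale (default: 1.2 means
#' |log2FC| > log2(1.2)) or already a log2 value. `direction` restricts to
#' up- or down-regulated genes.
#'
#' @param results A tibble from [test_de()].
#' @param p_adj_threshold Strict upper bound on adjusted p.
#' @param fc_threshold Fold-change bound (interpretation set by `fc_scale`).
#' @param fc_scale `"linear"` or `"log2"`.
#' @param direction `"both"`, `"up"` or `"down"`.
#' @return Character vector of DEG identifiers.
#' @export
call_degs <- function(results, p_adj_threshold = 0.05, fc_threshold = 1.2,
                      fc_scale = c("linear", "log2"),
                      direction = c("both", "up", "down")) {
  fc_scale <- match.arg(fc_scale)
  direction <- match.arg(direction)
  stopifnot(all(c("gene", "log2_fc", "p_adjusted") %in% names(results)),
            nrow(results) > 0)
  cut <- if (fc_scale == "linear") log2(fc_threshold) else fc_threshold
  keep <- results$p_adjusted < p_adj_threshold &
    switch(direction,
           both = abs(results$log2_fc) > cut,
           up = results$log2_fc > cut,
           down = results$log2_fc < -cut)
  results$gene[keep]
}
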