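# ggplot2 autoplot() methods for the main result types. These replace the
# paper-style figures with plain, scriptable ggplots: volcano plot for DE
# results, scale-free fit curve, odds-ratio bars for module enrichment,
# specificity enrichment bars, and the bootstrap degree distribution.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Volcano plot of differential expression results
#'
#' @param object An `ab_de` tibble from [test_de()].
#' @param p_adj_threshold,fc_threshold DEG thresholds drawn as guides
#'   (linear fold-change scale).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ab_de <- function(object, p_adj_threshold = 0.05,
                           fc_threshold = 1.2, ...) {
  cut <- log2(fc_threshold)
  df <- tibble::as_tibble(object)
  df$deg <- df$p_adjusted < p_adj_threshold & abs(df$log2_fc) > cut
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2_fc,
                                   y = -log10(pmax(.data$p, 1e-300)),
                                   colour = .data$deg)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_vline(xintercept = c(-cut, cut), linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50", `TRUE` = "firebrick"),
                                 name = "DEG") +
    ggplot2::labs(x = "log2 fold change (case vs control)",
                  y = "-log10 p")
}

#' Scale-free fit across candidate soft-thresholding powers
#'
#' @param object An `ab_sft` tibble (the `fits` element of
#'   [pick_soft_threshold()]).
#' @param target_r2 Horizontal guide for the fit target.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ab_sft <- function(object, target_r2 = 0.9, ...) {
  df <- tibble::as_tibble(object)
  df$signed_r2 <- -sign(df$slope) * df$r_squared
  ggplot2::ggplot(df, ggplot2::aes(x = .data$beta, y = .data$signed_r2)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = target_r2, linetype = 2) +
    ggplot2::labs(x = "soft-thresholding power",
                  y = "signed scale-free fit R²")
}

#' Odds-ratio bar chart of module enrichment
#'
#' @param object An `ab_module_enrichment` tibble from [module_or_test()].
#' @param p_threshold Modules with `p` below this are highlighted.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ab_module_enrichment <- function(object, p_threshold = 0.01, ...) {
  df <- tibble::as_tibble(object)
  df$significant <- df$p < p_threshold
  ggplot2::ggplot(df, ggplot2::aes(x = .data$module, y = .data$odds_ratio,
                                   fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70", `TRUE` = "firebrick"),
                               name = sprintf("p < %.2g", p_threshold)) +
    ggplot2::labs(x = "module", y = "odds ratio")
}

#' Specificity bootstrap enrichment per group
#'
#' @param object An `ab_specificity` tibble from [bootstrap_specificity()].
#' @param p_threshold Dashed guide for the reporting threshold.
#' @param ... Unused.
#' @return A ggplot of -log10 p per group.
#' @export
autoplot.ab_specificity <- function(object, p_threshold = 0.01, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = -log10(.data$p))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = -log10(p_threshold), linetype = 2) +
    ggplot2::labs(x = "group", y = "-log10 bootstrap p")
}

#' Bootstrap degree distribution against the observed mean degree
#'
#' @param object An `ab_degree_boot` result from [degree_bootstrap_test()].
#' @param ... Unused.
#' @return A ggplot histogram of bootstrap mean degrees with the observed
#'   value marked.
#' @export
autoplot.ab_degree_boot <- function(object, ...) {
  boot <- attr(object, "boot_means")
  df <- tibble::tibble(boot_mean = boot)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$boot_mean)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$observed_mean, colour = "firebrick") +
    ggplot2::labs(x = "bootstrap mean degree", y = "count",
                  subtitle = sprintf("%s: observed %.2f, p(larger) = %.4g",
                                     object$set_name, object$observed_mean,
                                     object$p_larger))
}
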