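# Key-module identification: per-module 2x2 enrichment of a target gene set
# (odds ratio + chi-square test over the network gene universe) and the
# highest-OR selection rule that defines the key gene classes.

#' Per-module odds-ratio / chi-square enrichment of a target set
#'
#' For every non-"unassigned" module, forms the 2x2 table over the network
#' gene universe (module membership x target membership; unassigned genes
#' count in the out-of-module margin). The odds ratio is `(a*d)/(b*c)` with
#' a Haldane-Anscombe correction of 0.5 added to every cell when any cell is
#' zero (recorded in `haldane`); the chi-square test of independence (1 df)
#' is computed on the uncorrected table, without continuity correction by
#' default.
#'
#' @param partition An `ab_partition` tibble (`gene`, `module`).
#' @param target Character vector of target genes; must intersect the
#'   network universe.
#' @param universe Optional universe; defaults to all partition genes.
#'   Target genes outside it are dropped with a message.
#' @param yates Apply Yates continuity correction to the chi-square test.
#' @return Tibble of class `ab_module_enrichment`: `module`, `a`, `b`, `c`,
#'   `d`, `odds_ratio`, `haldane`, `chi2`, `p`.
#' @export
module_or_test <- function(partition, target, universe = NULL, yates = FALSE) {
  stopifnot(all(c("gene", "module") %in% names(partition)))
  universe <- universe %||% partition$gene
  check_genes(universe, "universe")
  target <- drop_unknown_genes(unique(target), universe, "target set")
  if (length(target) == 0L) rlang::abort("target set does not intersect the universe")
  part <- partition[partition$gene %in% universe, , drop = FALSE]
  mods <- sort(setdiff(unique(part$module), "unassigned"))
  if (length(mods) == 0L) {
    out <- tibble::tibble(module = character(0), a = integer(0), b = integer(0),
                          c = integer(0), d = integer(0), odds_ratio = numeric(0),
                          haldane = logical(0), chi2 = numeric(0), p = numeric(0))
    return(structure(out, class = c("ab_module_enrichment", class(out))))
  }
  n_univ <- length(universe)
  in_target <- part$gene %in% target
  rows <- lapply(mods, function(m) {
    in_mod <- part$module == m
    a <- sum(in_mod & in_target)
    b <- sum(in_mod & !in_target)
    cc <- length(target) - a
    d <- n_univ - a - b - cc
    haldane <- any(c(a, b, cc, d) == 0)
    h <- if (haldane) 0.5 else 0
    or <- ((a + h) * (d + h)) / ((b + h) * (cc + h))
    cs <- chi2_independence(a, b, cc, d, yates = yates)
    tibble::tibble(module = m, a = a, b = b, c = cc, d = d,
                   odds_ratio = or, haldane = haldane,
                   chi2 = cs$stat, p = cs$p)
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("ab_module_enrichment", class(out)))
}

# 1-df chi-square test of independence on a 2x2 table; degenerate margins
# give stat 0, p 1.
chi2_independence <- function(a, b, cc, d, yates = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b); cc <- as.numeric(cc); d <- as.numeric(d)
  n <- a + b + cc + d
  r1 <- a + b; r2 <- cc + d; c1 <- a + cc; c2 <- b + d
  if (n == 0 || r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) {
    return(list(stat = 0, p = 1))
  }
  dev <- abs(a * d - b * cc)
  if (yates) dev <- max(0, dev - n / 2)
  stat <- n * dev^2 / (r1 * r2 * c1 * c2)
  list(stat = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Select the key module
#'
#' Among *enriched* modules (odds ratio > 1, the direction the selection is
#' about; a depleted module can also have a small two-sided chi-square p)
#' with chi-square `p < p_threshold`, returns the one with the highest odds
#' ratio; ties go to the smaller p, then to label sort order. Returns `NA`
#' (with a message) when no module passes.
#'
#' @param enrichments Tibble from [module_or_test()].
#' @param p_threshold Strict p-value threshold.
#' @return Module label, or `NA_character_`.
#' @export
select_key_module <- function(enrichments, p_threshold = 0.01) {
  stopifnot(all(c("module", "odds_ratio", "p") %in% names(enrichments)))
  cand <- enrichments[enrichments$p < p_threshold & enrichments$odds_ratio > 1,
                      , drop = FALSE]
  if (nrow(cand) == 0L) {
    rlang::inform("no module passes the chi-square p threshold; no key module selected")
    return(NA_character_)
  }
  cand <- cand[order(-cand$odds_ratio, cand$p, cand$module), , drop = FALSE]
  cand$module[[1]]
}

#' Key gene set: all members of the key module
#'
#' The key genes are the whole module, not its intersection with the target
#' set.
#'
#' @param partition An `ab_partition` tibble.
#' @param key_module Module label present in the partition.
#' @return Character vector of the module's genes.
#' @export
key_gene_set <- function(partition, key_module) {
  stopifnot(all(c("gene", "module") %in% names(partition)),
            is.character(key_module), length(key_module) == 1L, !is.na(key_module))
  genes <- partition$gene[partition$module == key_module]
  if (length(genes) == 0L) {
    rlang::abort(sprintf("module '%s' not found in partition or empty", key_module))
  }
  genes
}
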