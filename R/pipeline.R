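# End-to-end orchestration: sample filtering, expression filter, DE calling,
# overlap tests, AB-restricted co-expression networks, key-module selection
# per gene-evidence type, and characterization of the key sets (ORA,
# specificity bootstrap, PPI degree bootstrap).

#' Pipeline configuration
#'
#' Collects the inputs and thresholds of the integrative analysis. Matrix /
#' graph / collection arguments accept either in-memory objects or file
#' paths in the package's plain-text formats ([read_expression_tsv()],
#' [read_gmt()], [read_edge_list()]).
#'
#' @param counts,rpkm Named lists (one entry per region) of gene x sample
#'   matrices or TSV paths.
#' @param metadata Tibble (or TSV path) with columns `sample`, `diagnosis`
#'   (`case`/`control`), `region`, and optionally `age`.
#' @param gene_sets Collection (or GMT path) containing sets named `AB`,
#'   `CNV`, `DNM`.
#' @param collection Optional annotation collection (or GMT path) for
#'   over-representation analysis of the key sets.
#' @param ppi Optional [ppi_graph()] or edge-list TSV path.
#' @param profiles Optional gene x group matrix or TSV path for specificity
#'   enrichment.
#' @param rpkm_threshold Expression filter (strict mean > threshold).
#' @param min_age Keep samples with age strictly above this (when an `age`
#'   column exists).
#' @param p_adj_threshold,fc_threshold DEG calling thresholds.
#' @param fc_scale `"linear"` or `"log2"` interpretation of `fc_threshold`.
#' @param target_r2,min_module_size,merge_height,cut_height Network
#'   construction parameters (see [fit_coexpression()]).
#' @param module_p Chi-square threshold for key-module selection.
#' @param ora_p,ora_q Over-representation cutoffs.
#' @param n_boot Bootstrap resamples for specificity and degree tests.
#' @param seed Base seed; stochastic stages use documented fixed offsets
#'   (specificity: `seed + 101 + stage index`; degree test:
#'   `seed + 201 + stage index`).
#' @param out_dir Optional directory for TSV/JSON outputs.
#' @return List of class `ab_pipeline_config`.
#' @export
pipeline_config <- function(counts, rpkm, metadata, gene_sets,
                            collection = NULL, ppi = NULL, profiles = NULL,
                            rpkm_threshold = 0.1, min_age = 18,
                            p_adj_threshold = 0.05, fc_threshold = 1.2,
                            fc_scale = "linear",
                            target_r2 = 0.9, min_module_size = 30L,
                            merge_height = 0.25, cut_height = 0.99,
                            module_p = 0.01, ora_p = 0.01, ora_q = 0.05,
                            n_boot = 10000L, seed = 1L, out_dir = NULL) {
  stopifnot(is.list(counts), is.list(rpkm),
            length(counts) == length(rpkm),
            !is.null(names(counts)), identical(names(counts), names(rpkm)),
            rpkm_threshold >= 0, p_adj_threshold > 0, p_adj_threshold <= 1,
            fc_threshold > 0, target_r2 > 0, target_r2 <= 1,
            min_module_size > 0, merge_height >= 0, merge_height <= 1,
            module_p > 0, module_p <= 1, n_boot >= 1)
  structure(list(counts = counts, rpkm = rpkm, metadata = metadata,
                 gene_sets = gene_sets, collection = collection, ppi = ppi,
                 profiles = profiles, rpkm_threshold = rpkm_threshold,
                 min_age = min_age, p_adj_threshold = p_adj_threshold,
                 fc_threshold = fc_threshold, fc_scale = fc_scale,
                 target_r2 = target_r2,
                 min_module_size = as.integer(min_module_size),
                 merge_height = merge_height, cut_height = cut_height,
                 module_p = module_p, ora_p = ora_p, ora_q = ora_q,
                 n_boot = as.integer(n_boot), seed = as.integer(seed),
                 out_dir = out_dir),
            class = "ab_pipeline_config")
}

#' Pipeline configuration from a simulated study
#'
#' Wires the outputs of [simulate_study()] into a [pipeline_config()].
#'
#' @param study Result of [simulate_study()].
#' @param ... Threshold/seed arguments passed on to [pipeline_config()].
#' @return List of class `ab_pipeline_config`.
#' @export
study_pipeline_config <- function(study, ...) {
  pipeline_config(
    counts = lapply(study$expression, `[[`, "counts"),
    rpkm = lapply(study$expression, `[[`, "rpkm"),
    metadata = dplyr::bind_rows(lapply(study$expression, `[[`, "metadata")),
    gene_sets = list(AB = study$truth$ab_set, CNV = study$truth$cnv_set,
                     DNM = study$truth$dnm_set),
    collection = study$collection, ppi = study$ppi,
    profiles = study$profiles, ...
  )
}

load_matrix <- function(x) if (is.character(x)) read_expression_tsv(x) else check_expression_matrix(x)
load_collection <- function(x) if (is.character(x)) read_gmt(x) else new_gene_set_collection(x)
load_graph <- function(x) if (is.character(x)) read_edge_list(x) else { stopifnot(inherits(x, "ppi_graph")); x }
load_metadata <- function(x) {
  if (is.character(x)) {
    x <- utils::read.delim(x, sep = "\t", stringsAsFactors = FALSE)
  }
  x <- tibble::as_tibble(x)
  stopifnot(all(c("sample", "diagnosis", "region") %in% names(x)))
  x
}

#' Run the integrative key-gene analysis
#'
#' Per region: filters samples by age, filters genes by mean normalized
#' expression, calls DEGs, tests AB overlaps with DEG/CNV/DNM sets
#' (hypergeometric, Bonferroni across all overlap tests of the run), builds
#' the co-expression network on AB-restricted `log2(normalized + 1)`
#' expression, selects the key module for the DEG-in-AB and MUT-in-AB
#' targets (MUT = CNV union DNM), and characterizes each key gene set by
#' over-representation, specificity bootstrap and PPI-degree bootstrap where
#' the corresponding inputs are supplied. Finishes with pairwise key-set
#' overlap comparisons.
#'
#' @param config An [pipeline_config()] object.
#' @return Object of class `ab_run_report`: list with `params`, `overlaps`,
#'   per-region `regions` (DE table, DEG set, network fit, module
#'   enrichments, key sets), `key_sets`, `ora`, `specificity`, `ppi_tests`,
#'   `comparisons`, and a `stage_log` tibble recording gene counts in/out
#'   per stage.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "ab_pipeline_config"))
  sets <- load_collection(config$gene_sets)
  if (!all(c("AB", "CNV", "DNM") %in% names(sets))) {
    rlang::abort("gene_sets must contain sets named 'AB', 'CNV' and 'DNM'")
  }
  metadata <- load_metadata(config$metadata)
  regions <- names(config$counts)
  log_rows <- list()
  note <- function(region, stage, n_in, n_out) {
    log_rows[[length(log_rows) + 1L]] <<- tibble::tibble(
      region = region, stage = stage, n_in = n_in, n_out = n_out,
      n_dropped = n_in - n_out)
  }

  overlaps <- list()
  region_out <- list()
  key_sets <- list()
  expressed_by_region <- list()

  for (r in regions) {
    counts <- load_matrix(config$counts[[r]])
    rpkm <- load_matrix(config$rpkm[[r]])
    meta_r <- metadata[metadata$region == r, , drop = FALSE]
    if (nrow(meta_r) == 0L) rlang::abort(sprintf("no metadata samples for region '%s'", r))
    samples <- intersect(colnames(counts), meta_r$sample)
    if ("age" %in% names(meta_r)) {
      keep <- meta_r$sample[meta_r$age > config$min_age]
      note(r, "age_filter", length(samples), length(intersect(samples, keep)))
      samples <- intersect(samples, keep)
    }
    if (length(samples) < 4L) rlang::abort(sprintf("region '%s': too few samples after filtering", r))
    counts <- counts[, samples, drop = FALSE]
    rpkm <- rpkm[, samples, drop = FALSE]
    labels <- meta_r$diagnosis[match(samples, meta_r$sample)]

    expressed <- filter_expressed(rpkm, config$rpkm_threshold)
    note(r, "expression_filter", nrow(rpkm), length(expressed))
    expressed_by_region[[r]] <- expressed

    de <- test_de(counts[expressed, , drop = FALSE], labels)
    degs <- call_degs(de, config$p_adj_threshold, config$fc_threshold,
                      fc_scale = config$fc_scale)
    note(r, "deg_calling", length(expressed), length(degs))

    ab <- intersect(sets$AB, expressed)
    note(r, "ab_expression_filter", length(sets$AB), length(ab))
    for (nm in c("DEG", "CNV", "DNM")) {
      other <- switch(nm, DEG = degs, CNV = intersect(sets$CNV, expressed),
                      DNM = intersect(sets$DNM, expressed))
      ov <- hypergeometric_overlap(ab, other, expressed)
      ov$region <- r; ov$comparison <- paste0("AB_vs_", nm)
      overlaps[[paste(r, nm, sep = "_")]] <- ov
    }

    net_expr <- log2(rpkm[ab, , drop = FALSE] + 1)
    fit <- fit_coexpression(net_expr,
                            target_r2 = config$target_r2,
                            min_module_size = config$min_module_size,
                            cut_height = config$cut_height,
                            merge_height = config$merge_height)
    n_mod <- length(setdiff(unique(fit$partition$module), "unassigned"))
    note(r, "module_detection", length(ab), n_mod)

    targets <- list(
      kDEG = intersect(degs, ab),
      kMUT = intersect(union(sets$CNV, sets$DNM), ab)
    )
    enr <- list(); selected <- list()
    for (tt in names(targets)) {
      if (length(intersect(targets[[tt]], fit$partition$gene)) == 0L) {
        rlang::inform(sprintf("%s %s: target set empty on the network; skipped", r, tt))
        enr[[tt]] <- NULL; selected[[tt]] <- NA_character_
        next
      }
      e <- module_or_test(fit$partition, targets[[tt]])
      sel <- select_key_module(e, config$module_p)
      e$selected <- !is.na(sel) & e$module == sel
      enr[[tt]] <- e
      selected[[tt]] <- sel
      if (!is.na(sel)) {
        key_sets[[sprintf("%s-%s", r, tt)]] <- key_gene_set(fit$partition, sel)
      }
    }
    region_out[[r]] <- list(samples = samples, de = de, degs = degs,
                            ab_expressed = ab, fit = fit,
                            targets = targets, enrichments = enr,
                            selected = selected)
  }

  overlap_tbl <- dplyr::bind_rows(overlaps)
  overlap_tbl$p_adjusted <- adjust_pvalues(overlap_tbl$p, "bonferroni")

  # characterization of the key sets
  ora <- list(); spec_tests <- list(); ppi_tests <- list()
  collection <- if (!is.null(config$collection)) load_collection(config$collection)
  spec <- if (!is.null(config$profiles)) specificity_matrix(load_matrix(config$profiles))
  deg_table <- if (!is.null(config$ppi)) {
    all_expressed <- sort(unique(unlist(expressed_by_region)))
    bppi_degrees(load_graph(config$ppi), all_expressed)
  }
  i <- 0L
  for (ks in names(key_sets)) {
    i <- i + 1L
    r <- sub("-k.*$", "", ks)
    if (!is.null(collection)) {
      ora[[ks]] <- over_representation(key_sets[[ks]], collection,
                                       expressed_by_region[[r]],
                                       config$ora_p, config$ora_q)
    }
    if (!is.null(spec)) {
      spec_tests[[ks]] <- bootstrap_specificity(spec, key_sets[[ks]],
                                                n_boot = config$n_boot,
                                                seed = config$seed + 101L + i)
    }
    if (!is.null(deg_table)) {
      ppi_tests[[ks]] <- degree_bootstrap_test(deg_table, key_sets[[ks]],
                                               n_boot = config$n_boot,
                                               seed = config$seed + 201L + i,
                                               set_name = ks)
    }
  }

  comparisons <- NULL
  if (length(key_sets) >= 2L) {
    nms <- names(key_sets)
    pairs <- utils::combn(nms, 2L)
    comparisons <- dplyr::bind_rows(lapply(seq_len(ncol(pairs)), function(j) {
      compare_key_sets(key_sets[[pairs[1, j]]], key_sets[[pairs[2, j]]],
                       pairs[1, j], pairs[2, j])
    }))
  }

  report <- structure(list(
    params = config[setdiff(names(config), c("counts", "rpkm", "metadata",
                                             "gene_sets", "collection",
                                             "ppi", "profiles"))],
    overlaps = overlap_tbl, regions = region_out, key_sets = key_sets,
    ora = ora, specificity = spec_tests,
    ppi_tests = if (length(ppi_tests)) dplyr::bind_rows(ppi_tests),
    comparisons = comparisons,
    stage_log = dplyr::bind_rows(log_rows)
  ), class = "ab_run_report")
  if (!is.null(config$out_dir)) write_run_report(report, config$out_dir)
  report
}

#' @export
print.ab_run_report <- function(x, ...) {
  cat(sprintf("<ab_run_report> %d region(s), %d key gene set(s)\n",
              length(x$regions), length(x$key_sets)))
  for (ks in names(x$key_sets)) {
    cat(sprintf("  %s: %d genes\n", ks, length(x$key_sets[[ks]])))
  }
  invisible(x)
}

#' Write a run report's tables to disk
#'
#' Emits TSV summaries (overlaps, per-region DE tables and partitions,
#' module enrichments, key sets as GMT, bootstrap tests, comparisons, stage
#' log) plus a JSON report of parameters and key-set sizes.
#'
#' @param report An `ab_run_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_report <- function(report, dir) {
  stopifnot(inherits(report, "ab_run_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) utils::write.table(x, file.path(dir, f), sep = "\t",
                                          quote = FALSE, row.names = FALSE,
                                          eol = "\n")
  wt(report$overlaps, "overlaps.tsv")
  wt(report$stage_log, "stage_log.tsv")
  for (r in names(report$regions)) {
    reg <- report$regions[[r]]
    wt(reg$de, sprintf("de_%s.tsv", r))
    wt(reg$fit$partition, sprintf("partition_%s.tsv", r))
    wt(reg$fit$fits, sprintf("scale_free_fit_%s.tsv", r))
    for (tt in names(reg$enrichments)) {
      if (!is.null(reg$enrichments[[tt]])) {
        wt(reg$enrichments[[tt]], sprintf("module_enrichment_%s_%s.tsv", r, tt))
      }
    }
  }
  if (length(report$key_sets)) {
    write_gmt(report$key_sets, file.path(dir, "key_sets.gmt"))
  }
  for (ks in names(report$ora)) wt(report$ora[[ks]], sprintf("ora_%s.tsv", ks))
  for (ks in names(report$specificity)) {
    wt(report$specificity[[ks]], sprintf("specificity_%s.tsv", ks))
  }
  if (!is.null(report$ppi_tests)) wt(report$ppi_tests, "ppi_degree_tests.tsv")
  if (!is.null(report$comparisons)) wt(report$comparisons, "key_set_comparisons.tsv")
  jsonlite::write_json(
    list(params = report$params,
         key_set_sizes = lapply(report$key_sets, length)),
    file.path(dir, "run_report.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
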