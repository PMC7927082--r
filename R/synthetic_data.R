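# Synthetic-data generators: case-control RNA-seq counts with planted
# co-expression modules and differential expression, annotation gene sets
# enriched in planted modules, a preferential-attachment PPI graph with a
# planted hub set, and group (cell-type / developmental-period) expression
# profiles with planted specific genes. Everything is deterministic under
# the config seed, so the whole pipeline is testable offline.

#' Simulation configuration
#'
#' Builds a validated configuration for the synthetic-data generators. The
#' defaults define a desk-scale case-control study: 1000 genes, 5 planted
#' co-expression modules of 30 genes, 60 cases vs 60 controls, strong planted
#' effects (fold change 4, annotation odds 8) chosen so that every planted
#' signal is recoverable by the downstream stages.
#'
#' @param n_genes Number of genes.
#' @param n_cases,n_controls Samples per diagnosis group.
#' @param n_modules Number of planted co-expression modules (0 = none).
#' @param module_size Genes per planted module; `n_modules * module_size`
#'   must not exceed `n_genes`.
#' @param factor_loading Loading of the per-module latent factor on the
#'   log-scale gene mean. One standard-normal factor per module per sample;
#'   loading 1 gives within-module Pearson correlations around 0.85-0.9 on
#'   log-transformed counts.
#' @param nb_dispersion Negative-binomial dispersion `alpha` (shared across
#'   genes), variance `mu + alpha * mu^2`.
#' @param baseline_log_mean_range Range (natural log) from which per-gene
#'   baseline log means are drawn uniformly.
#' @param de_fraction Background probability that a gene is differentially
#'   expressed.
#' @param de_fold_change Multiplier applied to the case-group mean of each
#'   planted DE gene (> 1).
#' @param de_enrichment Odds multiplier for genes of the designated DE module
#'   (the first planted module) to enter the DE set; emulates a
#'   disease-perturbed module.
#' @param annotation_enrichment Odds multiplier for planted-module genes to
#'   enter the AB-like annotation set (>= 1).
#' @param ab_base_rate Background probability of AB-set membership.
#' @param cnv_size,dnm_size Sizes of the CNV-like and DNM-like mutation sets.
#' @param mut_enrichment Weight multiplier for genes of the designated
#'   mutation module (the second planted module) in CNV/DNM sampling.
#' @param mut_ab_weight Weight multiplier for AB-set genes in CNV/DNM
#'   sampling (controls the realized MUT-AB overlap).
#' @param ppi_edges_per_node Edges added per node during preferential
#'   attachment.
#' @param hub_set_size Number of earliest-attached (hence high-degree) nodes
#'   recorded as the planted hub set.
#' @param n_groups Number of cell-type / period groups for profile
#'   generation (>= 2).
#' @param specific_fraction Fraction of genes made group-specific.
#' @param region Region label written into sample metadata.
#' @param seed Integer seed; identical seeds give bitwise-identical output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 1000L,
                       n_cases = 60L,
                       n_controls = 60L,
                       n_modules = 5L,
                       module_size = 30L,
                       factor_loading = 1.0,
                       nb_dispersion = 0.05,
                       baseline_log_mean_range = c(1.5, 5.5),
                       de_fraction = 0.1,
                       de_fold_change = 4,
                       de_enrichment = 1,
                       annotation_enrichment = 8,
                       ab_base_rate = 0.3,
                       cnv_size = 150L,
                       dnm_size = 150L,
                       mut_enrichment = 8,
                       mut_ab_weight = 2,
                       ppi_edges_per_node = 2L,
                       hub_set_size = 20L,
                       n_groups = 10L,
                       specific_fraction = 0.1,
                       region = "DLPFC",
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), n_cases = as.integer(n_cases),
    n_controls = as.integer(n_controls), n_modules = as.integer(n_modules),
    module_size = as.integer(module_size), factor_loading = factor_loading,
    nb_dispersion = nb_dispersion,
    baseline_log_mean_range = baseline_log_mean_range,
    de_fraction = de_fraction, de_fold_change = de_fold_change,
    de_enrichment = de_enrichment,
    annotation_enrichment = annotation_enrichment,
    ab_base_rate = ab_base_rate,
    cnv_size = as.integer(cnv_size), dnm_size = as.integer(dnm_size),
    mut_enrichment = mut_enrichment, mut_ab_weight = mut_ab_weight,
    ppi_edges_per_node = as.integer(ppi_edges_per_node),
    hub_set_size = as.integer(hub_set_size),
    n_groups = as.integer(n_groups), specific_fraction = specific_fraction,
    region = region, seed = as.integer(seed)
  )
  with(cfg, {
    stopifnot(n_genes > 0, n_cases > 0, n_controls > 0, n_modules >= 0,
              module_size > 0, factor_loading >= 0, nb_dispersion > 0,
              length(baseline_log_mean_range) == 2,
              de_fraction >= 0, de_fraction <= 1, de_fold_change > 1,
              annotation_enrichment >= 1, ab_base_rate > 0, ab_base_rate < 1,
              ppi_edges_per_node > 0, hub_set_size > 0, n_groups > 0,
              specific_fraction >= 0, specific_fraction <= 1)
  })
  if (cfg$n_modules * cfg$module_size > cfg$n_genes) {
    rlang::abort("configuration error: n_modules * module_size exceeds n_genes")
  }
  structure(cfg, class = "sim_config")
}

gene_ids <- function(n) sprintf("g%04d", seq_len(n))

# Bernoulli membership with odds multiplied by `enrichment` for flagged genes.
enriched_membership <- function(flagged, base_rate, enrichment) {
  odds <- base_rate / (1 - base_rate)
  p <- ifelse(flagged, enrichment * odds / (1 + enrichment * odds), base_rate)
  stats::runif(length(p)) < p
}

#' Simulate a case-control expression study with planted structure
#'
#' Counts are negative-binomial draws with log-scale gene means
#' `baseline_g + loading * factor_m(sample) + log(fold_change) * is_case` for
#' genes of planted module m / planted DE genes. The normalized matrix scales
#' each sample to a common library size of 1e6 and divides by a fixed 1 kb
#' pseudo-length, i.e. an RPKM-like scale without real gene models.
#'
#' DE genes are drawn Bernoulli with probability `de_fraction`, with odds
#' multiplied by `de_enrichment` inside the first planted module (the
#' designated disease-expression module).
#'
#' @param config A [sim_config()].
#' @return List with `counts` (integer gene x sample matrix), `rpkm`
#'   (normalized matrix on the RPKM-like scale), `metadata` (tibble: sample,
#'   diagnosis, region, age) and `truth` (list: `module_membership`,
#'   `de_genes`, `de_fold_change`, `de_module`, `mut_module`).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n_g <- config$n_genes
    n_s <- config$n_cases + config$n_controls
    genes <- gene_ids(n_g)
    samples <- sprintf("s%03d", seq_len(n_s))
    diagnosis <- rep(c("case", "control"), c(config$n_cases, config$n_controls))

    membership <- rep("unassigned", n_g)
    if (config$n_modules > 0) {
      idx <- seq_len(config$n_modules * config$module_size)
      membership[idx] <- rep(sprintf("m%d", seq_len(config$n_modules)),
                             each = config$module_size)
    }
    names(membership) <- genes

    de_module <- if (config$n_modules >= 1) "m1" else NA_character_
    mut_module <- if (config$n_modules >= 2) "m2" else NA_character_
    de_flag <- enriched_membership(!is.na(de_module) & membership == de_module,
                                   config$de_fraction, config$de_enrichment)
    de_genes <- genes[de_flag]

    baseline <- stats::runif(n_g, config$baseline_log_mean_range[1],
                             config$baseline_log_mean_range[2])
    log_mu <- matrix(baseline, nrow = n_g, ncol = n_s)
    if (config$n_modules > 0) {
      factors <- matrix(stats::rnorm(config$n_modules * n_s),
                        nrow = config$n_modules)
      for (m in seq_len(config$n_modules)) {
        rows <- membership == sprintf("m%d", m)
        log_mu[rows, ] <- log_mu[rows, ] +
          config$factor_loading * rep(factors[m, ], each = sum(rows))
      }
    }
    case_cols <- diagnosis == "case"
    # bidirectional DE: background DE genes are up- or down-regulated in
    # cases with equal probability (a one-directional burden of strong DE
    # would bias the median-of-ratios reference itself); DE genes inside the
    # designated disease module share one direction, as a co-regulated
    # module responds coherently
    de_sign <- sample(c(1, -1), sum(de_flag), replace = TRUE)
    names(de_sign) <- de_genes
    in_de_module <- !is.na(de_module) & membership[de_genes] == de_module
    if (any(in_de_module)) de_sign[in_de_module] <- sample(c(1, -1), 1)
    log_mu[de_flag, case_cols] <- log_mu[de_flag, case_cols] +
      unname(de_sign) * log(config$de_fold_change)

    mu <- exp(log_mu)
    counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                    size = 1 / config$nb_dispersion),
                     nrow = n_g, dimnames = list(genes, samples))

    lib <- colSums(counts)
    lib[lib == 0] <- 1
    rpkm <- sweep(counts, 2, lib / 1e6, "/")  # per-kb with 1 kb pseudo-length

    metadata <- tibble::tibble(
      sample = samples, diagnosis = diagnosis, region = config$region,
      age = round(stats::runif(n_s, 16, 80), 1)
    )
    truth <- list(module_membership = membership, de_genes = de_genes,
                  de_sign = de_sign,
                  de_fold_change = config$de_fold_change,
                  de_module = de_module, mut_module = mut_module)
    list(counts = counts, rpkm = rpkm, metadata = metadata, truth = truth)
  })
}

#' Simulate annotation gene sets (AB-like, CNV-like, DNM-like)
#'
#' The AB-like set is drawn per gene with background probability
#' `ab_base_rate` and odds multiplied by `annotation_enrichment` for genes in
#' any planted module. CNV-like and DNM-like sets are weighted random subsets
#' of fixed size: genes of the designated mutation module carry weight
#' `mut_enrichment` and AB members additionally `mut_ab_weight`, which
#' controls the realized overlap with AB.
#'
#' @param truth Truth list from [simulate_expression()].
#' @param config The same [sim_config()].
#' @param enriched_modules Module labels whose genes receive the AB odds
#'   boost; defaults to all planted modules.
#' @return Updated truth list with `ab_set`, `cnv_set`, `dnm_set` and
#'   `ab_enriched_modules` added.
#' @export
simulate_gene_sets <- function(truth, config,
                               enriched_modules = NULL) {
  stopifnot(inherits(config, "sim_config"))
  membership <- truth$module_membership
  genes <- names(membership)
  enriched_modules <- enriched_modules %||%
    setdiff(unique(membership), "unassigned")
  with_seed(config$seed + 1L, {
    flagged <- membership %in% enriched_modules
    ab <- genes[enriched_membership(flagged, config$ab_base_rate,
                                    config$annotation_enrichment)]
    w <- rep(1, length(genes))
    if (!is.na(truth$mut_module %||% NA_character_)) {
      w[membership == truth$mut_module] <- config$mut_enrichment
    }
    w[genes %in% ab] <- w[genes %in% ab] * config$mut_ab_weight
    cnv <- sample(genes, min(config$cnv_size, length(genes)), prob = w)
    dnm <- sample(genes, min(config$dnm_size, length(genes)), prob = w)
    truth$ab_set <- ab
    truth$cnv_set <- sort(cnv)
    truth$dnm_set <- sort(dnm)
    truth$ab_enriched_modules <- enriched_modules
    truth
  })
}

#' Simulate a PPI graph by preferential attachment with a planted hub set
#'
#' Grows an undirected simple graph (Barabasi-Albert preferential attachment,
#' `ppi_edges_per_node` edges per new node). The earliest-attached nodes
#' accumulate the highest degrees; the first `hub_set_size` attachment
#' positions, mapped to a random permutation of the supplied genes, form the
#' planted hub set.
#'
#' @param genes Character vector of node identifiers.
#' @param config A [sim_config()].
#' @return List with `graph` (a [ppi_graph()]) and `hub_genes`.
#' @export
simulate_ppi <- function(genes, config) {
  stopifnot(inherits(config, "sim_config"))
  check_genes(genes, "PPI gene list")
  if (config$hub_set_size > length(genes)) {
    rlang::abort("hub_set_size exceeds the number of genes")
  }
  with_seed(config$seed + 2L, {
    perm <- sample(genes)
    g <- igraph::sample_pa(length(genes), m = config$ppi_edges_per_node,
                           directed = FALSE)
    el <- igraph::as_edgelist(g, names = FALSE)
    graph <- ppi_graph(perm[el[, 1]], perm[el[, 2]])
    list(graph = graph, hub_genes = sort(perm[seq_len(config$hub_set_size)]))
  })
}

#' Simulate group mean-expression profiles with planted specific genes
#'
#' Non-specific genes get near-uniform expression across groups (multiplicative
#' noise of +/- 15% around a per-gene baseline). Specific genes have their
#' assigned group's value set so that it carries 85% of the row total, i.e.
#' row specificity >= 0.8 by construction.
#'
#' @param genes Character vector of gene identifiers.
#' @param config A [sim_config()]; `n_groups` must be >= 2.
#' @param specificity_target Row share given to a specific gene's assigned
#'   group.
#' @return List with `profiles` (gene x group matrix of nonnegative means)
#'   and `specific_genes` (named character: gene -> assigned group).
#' @export
simulate_group_profiles <- function(genes, config, specificity_target = 0.85) {
  stopifnot(inherits(config, "sim_config"))
  check_genes(genes, "profile gene list")
  if (config$n_groups < 2L) {
    rlang::abort("n_groups must be >= 2 for group profiles")
  }
  stopifnot(specificity_target > 0.8, specificity_target < 1)
  with_seed(config$seed + 3L, {
    n_g <- length(genes)
    groups <- sprintf("c%02d", seq_len(config$n_groups))
    base <- exp(stats::runif(n_g, config$baseline_log_mean_range[1],
                             config$baseline_log_mean_range[2]))
    noise <- matrix(stats::runif(n_g * config$n_groups, 0.85, 1.15),
                    nrow = n_g)
    profiles <- base * noise
    dimnames(profiles) <- list(genes, groups)

    n_spec <- round(config$specific_fraction * n_g)
    specific <- character(0)
    if (n_spec > 0) {
      spec_genes <- sample(genes, n_spec)
      spec_groups <- sample(groups, n_spec, replace = TRUE)
      for (i in seq_len(n_spec)) {
        row <- profiles[spec_genes[i], ]
        others <- sum(row[groups != spec_groups[i]])
        profiles[spec_genes[i], spec_groups[i]] <-
          others * specificity_target / (1 - specificity_target)
      }
      specific <- stats::setNames(spec_groups, spec_genes)
    }
    list(profiles = profiles, specific_genes = specific)
  })
}

#' Simulate every input of the integrative analysis for one or two regions
#'
#' Convenience wrapper that runs [simulate_expression()] once per region
#' (seeds offset per region so regions differ), builds the annotation sets
#' from the first region's module structure, and adds a PPI graph, group
#' profiles, and an annotation collection for over-representation analysis.
#'
#' @param config A [sim_config()].
#' @param regions Character vector of region labels.
#' @return List with per-region `expression`, shared `truth`, `ppi`,
#'   `profiles`, `specific_genes`, and `collection` (planted-module sets plus
#'   random decoy sets, GMT-ready).
#' @export
simulate_study <- function(config, regions = c("DLPFC", "HIPPO")) {
  stopifnot(inherits(config, "sim_config"), length(regions) >= 1)
  expression <- lapply(seq_along(regions), function(i) {
    cfg <- config
    cfg$region <- regions[[i]]
    cfg$seed <- config$seed + 10L * (i - 1L)
    ex <- simulate_expression(cfg)
    ids <- paste(regions[[i]], ex$metadata$sample, sep = "_")
    colnames(ex$counts) <- ids
    colnames(ex$rpkm) <- ids
    ex$metadata$sample <- ids
    ex
  })
  names(expression) <- regions
  truth <- simulate_gene_sets(expression[[1]]$truth, config)
  genes <- names(truth$module_membership)
  ppi <- simulate_ppi(genes, config)
  prof <- simulate_group_profiles(genes, config)
  truth$hub_genes <- ppi$hub_genes
  truth$specific_genes <- prof$specific_genes

  collection <- with_seed(config$seed + 4L, {
    mods <- setdiff(unique(truth$module_membership), "unassigned")
    sets <- lapply(mods, function(m) names(truth$module_membership)[
      truth$module_membership == m])
    names(sets) <- paste0("planted_", mods)
    for (i in seq_len(20L)) {
      sets[[sprintf("random_%02d", i)]] <-
        sample(genes, sample(20:80, 1))
    }
    new_gene_set_collection(sets)
  })

  list(expression = expression, truth = truth, ppi = ppi$graph,
       profiles = prof$profiles, collection = collection,
       config = config, regions = regions)
}

#' Write a simulated study to disk in the pipeline's plain-text formats
#'
#' Emits, per region, `counts_<region>.tsv` and `rpkm_<region>.tsv`, plus
#' `metadata.tsv`, `sets.gmt` (AB/CNV/DNM), `collection.gmt`, `ppi.tsv`,
#' `profiles.tsv` and `truth.json`.
#'
#' @param study Result of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- NULL
  for (r in study$regions) {
    ex <- study$expression[[r]]
    write_expression_tsv(ex$counts, file.path(dir, sprintf("counts_%s.tsv", r)))
    write_expression_tsv(ex$rpkm, file.path(dir, sprintf("rpkm_%s.tsv", r)))
    meta <- rbind(meta, ex$metadata)
  }
  utils::write.table(meta, file.path(dir, "metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, eol = "\n")
  write_gmt(list(AB = study$truth$ab_set, CNV = study$truth$cnv_set,
                 DNM = study$truth$dnm_set),
            file.path(dir, "sets.gmt"))
  write_gmt(study$collection, file.path(dir, "collection.gmt"))
  write_edge_list(study$ppi, file.path(dir, "ppi.tsv"))
  write_expression_tsv(study$profiles, file.path(dir, "profiles.tsv"))
  jsonlite::write_json(
    study$truth[c("de_genes", "ab_set", "cnv_set", "dnm_set", "hub_genes")],
    file.path(dir, "truth.json"))
  invisible(dir)
}
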