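test_that("generators are deterministic under a fixed seed", {
  cfg <- sim_config(n_genes = 100L, n_cases = 10L, n_controls = 10L,
                    n_modules = 2L, module_size = 10L, seed = 3L)
  a <- simulate_expression(cfg)
  b <- simulate_expression(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth, b$truth)
  expect_identical(simulate_ppi(rownames(a$counts), cfg),
                   simulate_ppi(rownames(a$counts), cfg))
  expect_identical(simulate_group_profiles(rownames(a$counts), cfg),
                   simulate_group_profiles(rownames(a$counts), cfg))
})

test_that("counts are nonnegative integers and rpkm nonnegative", {
  sim <- simulate_expression(sim_config(n_genes = 200L, n_cases = 10L,
                                        n_controls = 10L, seed = 2L))
  expect_true(all(sim$counts >= 0))
  expect_true(all(sim$counts == round(sim$counts)))
  expect_true(all(sim$rpkm >= 0))
  expect_identical(dim(sim$counts), dim(sim$rpkm))
})

test_that("invalid module layout is a configuration error", {
  expect_error(sim_config(n_genes = 100L, n_modules = 5L, module_size = 30L),
               "configuration error")
})

test_that("without planted modules, pairwise correlations average to zero", {
  sim <- simulate_expression(sim_config(
    n_genes = 200L, n_cases = 50L, n_controls = 50L, n_modules = 0L,
    de_fraction = 0, seed = 3L))
  cc <- cor(t(log2(sim$rpkm + 1)))
  expect_lt(abs(mean(cc[upper.tri(cc)])), 0.02)
})

test_that("planted fold changes are realized on the count scale", {
  ratios <- vapply(1:3, function(s) {
    sim <- simulate_expression(sim_config(seed = s))
    cs <- sim$metadata$diagnosis == "case"
    sg <- sim$truth$de_sign
    mean((rowMeans(sim$counts[names(sg), cs]) /
            rowMeans(sim$counts[names(sg), !cs]))^sg)
  }, numeric(1))
  expect_true(all(ratios >= 3.2 & ratios <= 4.8))
})

test_that("null annotation sets carry no module enrichment", {
  # realized AB-by-module odds ratio over 20 seeds: pooled 2x2 table
  # (a single seed's OR has sd(log OR) ~ 0.19 at these margins)
  cells <- rowSums(vapply(1:20, function(s) {
    cfg <- sim_config(annotation_enrichment = 1, seed = s)
    sim <- simulate_expression(cfg)
    tr <- simulate_gene_sets(sim$truth, cfg)
    mm <- tr$module_membership
    inab <- names(mm) %in% tr$ab_set
    inmod <- mm != "unassigned"
    c(sum(inab & inmod), sum(!inab & inmod),
      sum(inab & !inmod), sum(!inab & !inmod))
  }, numeric(4)))
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  expect_gte(or, 0.7)
  expect_lte(or, 1.4)
})

test_that("without planted modules the AB set is a uniform subset", {
  cfg <- sim_config(n_genes = 500L, n_modules = 0L, seed = 4L)
  sim <- simulate_expression(cfg)
  tr <- simulate_gene_sets(sim$truth, cfg)
  rate <- length(tr$ab_set) / cfg$n_genes
  expect_gt(rate, 0.2)
  expect_lt(rate, 0.4)
})

test_that("preferential-attachment graph satisfies the handshake identity", {
  cfg <- sim_config(n_genes = 500L, ppi_edges_per_node = 2L, seed = 5L)
  sp <- simulate_ppi(sprintf("g%04d", 1:500), cfg)
  deg <- bppi_degrees(sp$graph, sprintf("g%04d", 1:500))
  expect_identical(sum(deg$degree), 2L * nrow(sp$graph$edges))
  expect_equal(mean(deg$degree), 2 * nrow(sp$graph$edges) / 500)
  expect_equal(mean(deg$degree), 4, tolerance = 0.05)
})

test_that("three nodes at one edge per node form a tree", {
  cfg <- sim_config(n_genes = 3L, ppi_edges_per_node = 1L, hub_set_size = 1L,
                    n_modules = 0L, seed = 1L)
  sp <- simulate_ppi(c("a", "b", "c"), cfg)
  expect_equal(nrow(sp$graph$edges), 2L)
})

test_that("planted hubs out-degree the background in every seed", {
  wins <- vapply(1:20, function(s) {
    cfg <- sim_config(n_genes = 500L, hub_set_size = 20L, seed = s)
    sp <- simulate_ppi(sprintf("g%04d", 1:500), cfg)
    deg <- bppi_degrees(sp$graph, sprintf("g%04d", 1:500))
    d <- setNames(deg$degree, deg$gene)
    mean(d[sp$hub_genes]) > mean(d[setdiff(names(d), sp$hub_genes)])
  }, logical(1))
  expect_true(all(wins))
})

test_that("group profiles plant specificity as promised", {
  cfg <- sim_config(n_genes = 500L, n_groups = 10L, seed = 6L)
  pr <- simulate_group_profiles(sprintf("g%04d", 1:500), cfg)
  spm <- specificity_matrix(pr$profiles)
  for (g in names(pr$specific_genes)) {
    expect_gte(spm[g, pr$specific_genes[[g]]], 0.8)
  }
  nonspec <- setdiff(rownames(spm), names(pr$specific_genes))
  expect_lte(max(spm[nonspec, ]), 0.25)
})

test_that("group profiles require at least two groups", {
  cfg <- sim_config(n_groups = 1L)
  expect_error(simulate_group_profiles(c("a", "b"), cfg), ">= 2")
})

test_that("a simulated study bundles every pipeline input", {
  study <- quiet(simulate_study(sim_config(
    n_genes = 200L, n_cases = 10L, n_controls = 10L, n_modules = 2L,
    module_size = 20L, cnv_size = 30L, dnm_size = 30L, seed = 8L)))
  expect_named(study$expression, c("DLPFC", "HIPPO"))
  expect_true(all(c("ab_set", "cnv_set", "dnm_set", "hub_genes",
                    "specific_genes") %in% names(study$truth)))
  expect_s3_class(study$ppi, "ppi_graph")
  expect_true(any(grepl("^planted_", names(study$collection))))
  # regions have distinct sample identifiers
  expect_length(intersect(colnames(study$expression$DLPFC$counts),
                          colnames(study$expression$HIPPO$counts)), 0L)
})

test_that("write_simulation emits readable plain-text inputs", {
  dir <- withr::local_tempdir()
  study <- quiet(simulate_study(sim_config(
    n_genes = 100L, n_cases = 8L, n_controls = 8L, n_modules = 2L,
    module_size = 15L, cnv_size = 20L, dnm_size = 20L, seed = 9L)))
  quiet(write_simulation(study, dir))
  expect_identical(read_expression_tsv(file.path(dir, "counts_DLPFC.tsv")),
                   study$expression$DLPFC$counts)
  sets <- read_gmt(file.path(dir, "sets.gmt"))
  expect_setequal(sets$AB, study$truth$ab_set)
  g <- read_edge_list(file.path(dir, "ppi.tsv"))
  expect_identical(g$edges, study$ppi$edges)
})
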