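# A 100-gene universe realizing the 2x2 table a=10, b=10, c=10, d=70:
# one 20-gene module, a 20-gene target sharing 10 genes with it.
or_fixture <- function() {
  genes <- sprintf("g%03d", 1:100)
  membership <- setNames(rep("unassigned", 100), genes)
  membership[1:20] <- "m1"
  target <- genes[c(1:10, 21:30)]
  list(partition = as_partition(membership), target = target)
}

test_that("module odds ratios follow ad/bc on the 2x2 table", {
  fx <- or_fixture()
  res <- module_or_test(fx$partition, fx$target)
  expect_equal(res$a, 10L)
  expect_equal(res$b, 10L)
  expect_equal(res$c, 10L)
  expect_equal(res$d, 70L)
  expect_equal(res$odds_ratio, 7)
  expect_false(res$haldane)
})

test_that("empty cells trigger the Haldane correction", {
  genes <- sprintf("g%03d", 1:90)
  membership <- setNames(rep("unassigned", 90), genes)
  membership[1:10] <- "m1"
  target <- genes[11:20]  # a = 0, b = 10, c = 10, d = 70
  res <- module_or_test(as_partition(membership), target)
  expect_true(res$haldane)
  expect_equal(res$odds_ratio, (0.5 * 70.5) / (10.5 * 10.5))
  expect_true(is.finite(res$odds_ratio))
})

test_that("chi-square p agrees with the reference implementation", {
  tables <- list(c(10, 10, 10, 70), c(3, 27, 40, 430), c(25, 5, 75, 395),
                 c(1, 29, 31, 439))
  for (tb in tables) {
    res <- abkey:::chi2_independence(tb[1], tb[2], tb[3], tb[4])
    ref <- suppressWarnings(
      stats::chisq.test(matrix(tb, 2, byrow = TRUE), correct = FALSE))
    expect_equal(res$stat, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(res$p, unname(ref$p.value), tolerance = 1e-10)
  }
  yates <- abkey:::chi2_independence(10, 10, 10, 70, yates = TRUE)
  ref <- suppressWarnings(
    stats::chisq.test(matrix(c(10, 10, 10, 70), 2, byrow = TRUE)))
  expect_equal(yates$p, unname(ref$p.value), tolerance = 1e-10)
})

test_that("the a-cells add up to the assigned target overlap", {
  sim <- simulate_expression(sim_config(n_genes = 400L, n_cases = 5L,
                                        n_controls = 5L, n_modules = 4L,
                                        module_size = 40L, seed = 3L))
  mm <- sim$truth$module_membership
  set.seed(7)
  target <- sample(names(mm), 120)
  res <- module_or_test(as_partition(mm), target)
  expect_identical(sum(res$a),
                   length(intersect(target,
                                    names(mm)[mm != "unassigned"])))
})

test_that("key-module selection follows the highest-OR rule with tie-breaks", {
  enr <- tibble::tibble(module = c("m1", "m2"),
                        odds_ratio = c(5.2, 2.0), p = c(1e-19, 0.5))
  expect_identical(select_key_module(enr), "m1")

  none <- tibble::tibble(module = c("m1", "m2"),
                         odds_ratio = c(2, 3), p = c(0.02, 0.5))
  expect_message(sel <- select_key_module(none), "no module")
  expect_identical(sel, NA_character_)

  tie <- tibble::tibble(module = c("m1", "m2"),
                        odds_ratio = c(3, 3), p = c(0.001, 0.0001))
  expect_identical(select_key_module(tie), "m2")

  depleted <- tibble::tibble(module = c("m1", "m2"),
                             odds_ratio = c(0.05, 1.5), p = c(1e-6, 0.5))
  expect_message(sel <- select_key_module(depleted), "no module")
  expect_identical(sel, NA_character_)
})

test_that("key gene sets are whole modules", {
  fx <- or_fixture()
  ks <- key_gene_set(fx$partition, "m1")
  expect_length(ks, 20L)
  expect_true(all(ks %in% fx$partition$gene))
  expect_error(key_gene_set(fx$partition, "m9"), "not found")
})

test_that("planted enrichment drives selection; null targets rarely pass", {
  hits <- vapply(1:20, function(s) {
    cfg <- sim_config(annotation_enrichment = 8, seed = s)
    sim <- simulate_expression(cfg)
    tr <- simulate_gene_sets(sim$truth, cfg, enriched_modules = "m3")
    e <- module_or_test(as_partition(tr$module_membership), tr$ab_set)
    expect_gt(e$odds_ratio[e$module == "m3"], 2)
    identical(select_key_module(e), "m3")
  }, logical(1))
  expect_gte(sum(hits), 18L)

  sim <- simulate_expression(sim_config(annotation_enrichment = 1, seed = 1))
  part <- as_partition(sim$truth$module_membership)
  n_sig <- 0L; n_tot <- 0L
  for (i in 1:50) {
    cfg <- sim_config(annotation_enrichment = 1, seed = 500L + i)
    tr <- simulate_gene_sets(sim$truth, cfg)
    e <- module_or_test(part, tr$ab_set)
    n_sig <- n_sig + sum(e$p < 0.01)
    n_tot <- n_tot + nrow(e)
  }
  expect_lte(n_sig / n_tot, 0.03)
})
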