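test_that("expression filter uses a strict threshold", {
  m <- matrix(c(0.05, 0.2, 0.1), 3, 1,
              dimnames = list(c("g1", "g2", "g3"), "s1"))
  m <- cbind(m, m)
  colnames(m) <- c("s1", "s2")
  expect_identical(filter_expressed(m, 0.1), "g2")
  expect_identical(filter_expressed(m, 0), c("g1", "g2", "g3"))
  expect_identical(formals(filter_expressed)$threshold, 0.1)
})

test_that("hypergeometric overlap matches hand-enumerated probabilities", {
  univ <- sprintf("u%02d", 1:10)
  # N = 10, K = 4, n = 5, k = 3: 66 of the 252 size-5 draws hit >= 3
  res <- hypergeometric_overlap(univ[1:4], univ[c(1:3, 5, 6)], univ)
  expect_equal(res$k, 3L)
  expect_equal(res$p, 66 / 252, tolerance = 1e-12)

  disjoint <- hypergeometric_overlap(univ[1:3], univ[4:6], univ)
  expect_equal(disjoint$p, 1)

  full <- hypergeometric_overlap(univ, univ, univ)
  expect_equal(full$k, 10L)
  expect_equal(full$p, 1)
})

test_that("hypergeometric overlap is symmetric in its two sets", {
  univ <- sprintf("u%02d", 1:30)
  set.seed(1)
  for (i in 1:10) {
    a <- sample(univ, sample(3:12, 1))
    b <- sample(univ, sample(3:12, 1))
    expect_equal(hypergeometric_overlap(a, b, univ)$p,
                 hypergeometric_overlap(b, a, univ)$p, tolerance = 1e-12)
  }
})

test_that("genes outside the universe are dropped with a message", {
  univ <- c("a", "b", "c", "d")
  expect_message(res <- hypergeometric_overlap(c("a", "zz"), c("a", "b"), univ),
                 "dropped 1")
  expect_equal(res$K, 1L)
  expect_error(hypergeometric_overlap("a", "b", character(0)))
})

test_that("p-value adjustment follows the closed forms", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "bh"),
               rep(0.04, 4))
  expect_equal(adjust_pvalues(0.5, "bonferroni"), 0.5)
  expect_equal(adjust_pvalues(c(0.7, 0.9), "bonferroni"), c(1, 1))
  expect_error(adjust_pvalues(c(0.5, 1.2), "bh"), "\\[0, 1\\]")
})

test_that("BH output is monotone on sorted input", {
  set.seed(2)
  p <- sort(runif(50))
  expect_false(is.unsorted(adjust_pvalues(p, "bh")))
})

test_that("over-representation ranks the matching set first", {
  univ <- sprintf("u%03d", 1:200)
  coll <- list(hit = univ[1:20], miss = univ[101:130], part = univ[15:40])
  res <- quiet(over_representation(univ[1:20], coll, univ))
  expect_identical(res$set_name[[1]], "hit")
  expect_true(res$significant[[1]])

  none <- quiet(over_representation(univ[150:160],
                                    list(s = univ[1:20]), univ))
  expect_false(any(none$significant))

  empty <- over_representation(univ[1:5], list(), univ)
  expect_equal(nrow(empty), 0L)
})

test_that("planted annotation sets are recovered by over-representation", {
  hits <- vapply(1:20, function(s) {
    cfg <- sim_config(annotation_enrichment = 8, seed = s)
    sim <- simulate_expression(cfg)
    tr <- simulate_gene_sets(sim$truth, cfg, enriched_modules = "m2")
    mm <- tr$module_membership
    coll <- list(planted = names(mm)[mm == "m2"],
                 decoy = names(mm)[seq(500, 579)])
    res <- quiet(over_representation(tr$ab_set, coll, names(mm)))
    res$significant[res$set_name == "planted"]
  }, logical(1))
  expect_gte(sum(hits), 18L)
})

test_that("key-set comparison reports one-decimal percentages", {
  a <- sprintf("a%03d", 1:88)
  b <- c(a[1:42], sprintf("b%03d", 1:234))
  res <- compare_key_sets(a, b)
  expect_equal(res$overlap, 42L)
  expect_equal(res$pct_of_a, 47.7)

  expect_equal(compare_key_sets(c("x", "y"), c("p", "q"))$pct_of_a, 0)
  same <- compare_key_sets(c("x", "y"), c("y", "x"))
  expect_equal(same$pct_of_a, 100)
  expect_equal(same$pct_of_b, 100)
  expect_error(compare_key_sets(character(0), "a"), "nonempty")
})
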