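test_that("adjacency follows |cor|^beta", {
  x <- matrix(c(1, 0, 0,
                0, 1, 0), 2, 3, byrow = TRUE,
              dimnames = list(c("gA", "gB"), c("s1", "s2", "s3")))
  a <- adjacency_matrix(x, beta = 2L)
  expect_equal(a["gA", "gB"], 0.25)  # cor = -0.5 exactly
  expect_equal(diag(a), c(gA = 0, gB = 0))

  dup <- rbind(g1 = c(1, 2, 3, 5), g2 = c(1, 2, 3, 5) * 3 + 1)
  colnames(dup) <- sprintf("s%d", 1:4)
  for (b in c(1L, 4L, 9L)) {
    expect_equal(adjacency_matrix(dup, b)["g1", "g2"], 1)
  }
})

test_that("adjacency decreases monotonically in beta when |cor| < 1", {
  set.seed(1)
  x <- matrix(rnorm(4 * 20), 4, 20,
              dimnames = list(sprintf("g%d", 1:4), sprintf("s%d", 1:20)))
  vals <- vapply(1:6, function(b) adjacency_matrix(x, b)[1, 2], numeric(1))
  expect_false(is.unsorted(rev(vals)))
})

test_that("zero-variance genes are rejected with their names", {
  x <- rbind(g1 = c(1, 1, 1, 1), g2 = c(1, 2, 3, 4))
  colnames(x) <- sprintf("s%d", 1:4)
  expect_error(adjacency_matrix(x, 2), "g1")
})

test_that("topological overlap matches hand-computed cases", {
  # isolated pair with a = 1
  a <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  expect_equal(tom_similarity(a)["x", "y"], 1)

  # no adjacency, no shared neighbours
  z <- matrix(0, 2, 2, dimnames = dimnames(a))
  expect_equal(tom_similarity(z)["x", "y"], 0)

  # triangle with unit adjacency: (1 + 1) / (2 + 1 - 1) = 1
  tri <- matrix(1, 3, 3) - diag(3)
  dimnames(tri) <- list(letters[1:3], letters[1:3])
  expect_equal(unname(tom_similarity(tri)[1, 2]), 1)
})

test_that("TOM is symmetric with entries in [0, 1] on random adjacency", {
  set.seed(3)
  for (i in 1:5) {
    n <- 30
    a <- matrix(runif(n * n), n, n)
    a <- (a + t(a)) / 2
    diag(a) <- 0
    dimnames(a) <- list(sprintf("g%02d", 1:n), sprintf("g%02d", 1:n))
    tom <- tom_similarity(a)
    expect_equal(tom, t(tom))
    expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
    expect_equal(unname(diag(tom)), rep(1, n))
  }
})

test_that("TOM validates its input", {
  a <- matrix(c(0, 2, 2, 0), 2, 2)
  expect_error(tom_similarity(a), "\\[0, 1\\]")
  b <- diag(2) * 0.5
  expect_error(tom_similarity(b), "diagonal")
})

test_that("perfectly separated blocks are detected exactly", {
  x <- two_block_expr(block = 30L)
  a <- adjacency_matrix(x, 6L)
  part <- detect_modules(1 - tom_similarity(a), min_module_size = 30L)
  expect_setequal(setdiff(unique(part$module), "unassigned"), c("m1", "m2"))
  lab <- setNames(part$module, part$gene)
  expect_length(unique(lab[sprintf("g%03d", 1:30)]), 1L)
  expect_length(unique(lab[sprintf("g%03d", 31:60)]), 1L)
  expect_false(lab[["g001"]] == lab[["g031"]])
})

test_that("the partition does not depend on gene input order", {
  x <- two_block_expr(block = 15L)
  a <- adjacency_matrix(x, 6L)
  d <- 1 - tom_similarity(a)
  p1 <- detect_modules(d, min_module_size = 10L)
  perm <- sample(nrow(d))
  p2 <- detect_modules(d[perm, perm], min_module_size = 10L)
  expect_identical(p1, p2)
})

test_that("raising the minimum module size never adds modules", {
  sim <- simulate_expression(sim_config(n_genes = 300L, n_cases = 30L,
                                        n_controls = 30L, n_modules = 3L,
                                        module_size = 25L, seed = 11L))
  d <- 1 - tom_similarity(adjacency_matrix(log2(sim$rpkm + 1), 6L))
  counts <- vapply(c(5L, 15L, 25L, 40L), function(ms) {
    part <- detect_modules(d, min_module_size = ms)
    length(setdiff(unique(part$module), "unassigned"))
  }, integer(1))
  expect_false(is.unsorted(rev(counts)))
})

test_that("too few genes yields an all-unassigned partition with a warning", {
  x <- two_block_expr(block = 5L)
  d <- 1 - tom_similarity(adjacency_matrix(x, 2L))
  expect_warning(part <- detect_modules(d, min_module_size = 30L),
                 "unassigned")
  expect_true(all(part$module == "unassigned"))
})

test_that("soft-threshold selection applies the smallest-power rule", {
  sim <- simulate_expression(sim_config(seed = 13L))
  pick <- quiet(pick_soft_threshold(log2(sim$rpkm + 1)))
  fits <- pick$fits
  expect_true(pick$beta %in% fits$beta)
  expect_lt(fits$slope[fits$beta == pick$beta], 0)
  eligible <- fits$mean_connectivity >= 1
  ok <- eligible & fits$r_squared >= 0.9 & fits$slope < 0
  if (any(ok)) expect_identical(pick$beta, fits$beta[which(ok)[1]])
  expect_identical(formals(pick_soft_threshold)$target_r2, 0.9)
})

test_that("module eigengenes summarize and orient their module", {
  sim <- simulate_expression(sim_config(n_genes = 200L, n_cases = 30L,
                                        n_controls = 30L, n_modules = 2L,
                                        module_size = 30L, seed = 17L))
  expr <- log2(sim$rpkm + 1)
  part <- as_partition(sim$truth$module_membership)
  e <- module_eigengene(expr, part, "m1")
  expect_length(e, ncol(expr))
  expect_gte(attr(e, "var_explained"), 0.4)
  members <- part$gene[part$module == "m1"]
  z <- t(scale(t(expr[members, ])))
  expect_gt(mean(cor(e, t(z))), 0)

  # sign-flipped input re-orients: correlation with members stays positive
  e2 <- module_eigengene(-expr, part, "m1")
  z2 <- t(scale(t(-expr[members, ])))
  expect_gt(mean(cor(e2, t(z2))), 0)

  expect_error(module_eigengene(expr, part, "m99"), "not found")
})

test_that("modules with correlated eigengenes merge; independent ones do not", {
  set.seed(21)
  f <- rnorm(50)
  g <- rnorm(50)
  mk <- function(base, n, noise) t(sapply(seq_len(n), function(i) base + rnorm(50, sd = noise)))
  x <- rbind(mk(f, 12, 0.2), mk(f, 12, 0.2), mk(g, 12, 0.2))
  rownames(x) <- sprintf("g%02d", 1:36)
  colnames(x) <- sprintf("s%02d", 1:50)
  part <- as_partition(setNames(rep(c("m1", "m2", "m3"), each = 12),
                                rownames(x)))
  merged <- merge_close_modules(x, part, merge_height = 0.25)
  mods <- setdiff(unique(merged$module), "unassigned")
  expect_length(mods, 2L)
  lab <- setNames(merged$module, merged$gene)
  expect_length(unique(lab[sprintf("g%02d", 1:24)]), 1L)  # the two f-modules
  expect_false(lab[["g01"]] == lab[["g25"]])

  untouched <- merge_close_modules(x, merged, merge_height = 0.25)
  expect_identical(sort(unique(untouched$module)), sort(unique(merged$module)))
})

test_that("planted modules are recovered end to end", {
  sim <- simulate_expression(sim_config(seed = 31L))
  fit <- quiet(fit_coexpression(log2(sim$rpkm + 1)))
  tr <- sim$truth$module_membership
  planted <- names(tr)[tr != "unassigned"]
  det <- setNames(fit$partition$module, fit$partition$gene)
  expect_gte(mclust::adjustedRandIndex(tr[planted], det[planted]), 0.8)
  g <- glance(fit)
  expect_identical(g$n_genes, 1000L)
  expect_gte(g$n_modules, 5L)
  expect_identical(nrow(tidy(fit)), 1000L)
})
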