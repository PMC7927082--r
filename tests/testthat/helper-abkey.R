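# Shared helpers: quiet wrappers and small constructors used across tests.

quiet <- function(expr) suppressWarnings(suppressMessages(expr))

# A partition tibble straight from a named membership vector.
as_partition <- function(membership) {
  tibble::tibble(gene = names(membership), module = unname(membership))
}

# Expression matrix with two perfectly separated blocks of `block` genes
# plus optional background genes, for module-detection tests.
two_block_expr <- function(block = 30L, n_samples = 40L, seed = 1L) {
  set.seed(seed)
  f1 <- rnorm(n_samples); f2 <- rnorm(n_samples)
  x <- rbind(
    t(sapply(seq_len(block), function(i) i * f1)),
    t(sapply(seq_len(block), function(i) i * f2))
  )
  rownames(x) <- sprintf("g%03d", seq_len(2 * block))
  colnames(x) <- sprintf("s%03d", seq_len(n_samples))
  x
}

# Hand-built degree table.
degree_table <- function(degrees) {
  tibble::tibble(gene = names(degrees), degree = unname(degrees))
}
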