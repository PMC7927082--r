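# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate code with a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state, so that
#' seeded operations never perturb the global random stream.
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Validate a gene-identifier character vector: no NA, no empty strings,
# duplicates optionally allowed.
check_genes <- function(genes, what = "gene set", allow_dup = FALSE) {
  if (!is.character(genes)) {
    rlang::abort(sprintf("%s must be a character vector of gene identifiers", what))
  }
  if (anyNA(genes) || any(!nzchar(genes))) {
    rlang::abort(sprintf("%s contains missing or empty gene identifiers", what))
  }
  if (!allow_dup && anyDuplicated(genes)) {
    rlang::abort(sprintf("%s contains duplicated gene identifiers", what))
  }
  invisible(genes)
}

# Validate a gene x sample numeric matrix with dimnames.
check_expression_matrix <- function(x, what = "expression matrix") {
  if (!is.matrix(x) || !is.numeric(x)) {
    rlang::abort(sprintf("%s must be a numeric matrix (genes x samples)", what))
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    rlang::abort(sprintf("%s must have gene rownames and sample colnames", what))
  }
  if (anyNA(x)) rlang::abort(sprintf("%s contains missing values", what))
  invisible(x)
}

# Drop elements of `genes` not present in `universe`, with an informative
# message when anything is dropped. Returns the retained genes.
drop_unknown_genes <- function(genes, universe, what = "gene set") {
  keep <- genes %in% universe
  if (!all(keep)) {
    rlang::inform(sprintf("%s: dropped %d gene(s) absent from the universe",
                          what, sum(!keep)))
  }
  genes[keep]
}

new_gene_set_collection <- function(sets) {
  stopifnot(is.list(sets))
  nm <- names(sets) %||% character(length(sets))
  if (length(sets) > 0 &&
      (anyDuplicated(nm) || any(!nzchar(nm)))) {
    rlang::abort("gene set collection requires unique, nonempty set names")
  }
  structure(lapply(sets, function(g) unique(as.character(g))),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d set(s)\n", length(x)))
  sizes <- vapply(x, length, integer(1))
  show <- utils::head(seq_along(x), 10L)
  for (i in show) cat(sprintf("  %s: %d genes\n", names(x)[i], sizes[i]))
  if (length(x) > 10L) cat(sprintf("  ... and %d more\n", length(x) - 10L))
  invisible(x)
}
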