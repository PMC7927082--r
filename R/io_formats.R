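# Readers/writers for the plain-text formats the pipeline exchanges:
# GMT gene-set collections, TSV expression matrices, TSV edge lists.
# All outputs are UTF-8, tab-delimited, LF. Gene identifiers are exact
# case-sensitive strings; only surrounding whitespace is stripped.

#' Read a GMT gene-set collection
#'
#' Each line of a GMT file is `name<TAB>description<TAB>gene1<TAB>gene2...`.
#' Duplicate genes within a line are removed with a message; duplicate set
#' names across lines are an error.
#'
#' @param path Path to a GMT file.
#' @return A `gene_set_collection`: a named list of character vectors.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".gmt")
#' writeLines("S1\tdesc\tA\tB", tf)
#' read_gmt(tf)
read_gmt <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(new_gene_set_collection(list()))
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- trimws(strsplit(lines[[i]], "\t", fixed = TRUE)[[1]])
    if (length(fields) < 3L) {
      rlang::abort(sprintf("GMT format error at line %d: fewer than 3 tab-separated fields", i))
    }
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      rlang::inform(sprintf("GMT line %d ('%s'): removed %d duplicate gene(s)",
                            i, fields[[1]], sum(duplicated(genes))))
      genes <- unique(genes)
    }
    nms[[i]] <- fields[[1]]
    sets[[i]] <- genes
  }
  if (anyDuplicated(nms)) {
    rlang::abort(sprintf("duplicate set name in GMT: '%s'", nms[duplicated(nms)][[1]]))
  }
  names(sets) <- nms
  new_gene_set_collection(sets)
}

#' Write a GMT gene-set collection
#'
#' @param collection A named list of character vectors (or a
#'   `gene_set_collection`).
#' @param path Output path.
#' @param descriptions Optional character vector of per-set descriptions;
#'   defaults to the set names.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path, descriptions = NULL) {
  collection <- new_gene_set_collection(collection)
  descriptions <- descriptions %||% names(collection)
  stopifnot(length(descriptions) == length(collection))
  lines <- vapply(seq_along(collection), function(i) {
    paste(c(names(collection)[i], descriptions[i], collection[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = FALSE)
  invisible(path)
}

#' Read a gene x sample expression matrix from TSV
#'
#' The first column holds gene identifiers; the header row holds sample
#' identifiers. Every cell must be numeric: missing values, non-numeric
#' cells and duplicated gene identifiers are errors.
#'
#' @param path Path to a TSV file.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_expression_tsv <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", quote = "", comment.char = "")
  if (ncol(df) < 2L) rlang::abort("expression TSV needs a gene column plus >= 1 sample column")
  genes <- trimws(df[[1]])
  if (anyDuplicated(genes)) {
    rlang::abort(sprintf("duplicated gene identifier in expression TSV: '%s'",
                         genes[duplicated(genes)][[1]]))
  }
  vals <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(vals), nrow = nrow(vals)))
  bad2 <- which(is.na(num), arr.ind = TRUE)
  if (nrow(bad2) > 0L) {
    rlang::abort(sprintf(
      "non-numeric or missing cell in expression TSV at gene '%s', sample '%s'",
      genes[bad2[1, 1]], colnames(vals)[bad2[1, 2]]))
  }
  dimnames(num) <- list(genes, colnames(vals))
  num
}

#' Write a gene x sample expression matrix as TSV
#'
#' @param mat Numeric matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @param gene_col Name for the gene-identifier column header.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(mat, path, gene_col = "gene") {
  check_expression_matrix(mat)
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- gene_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, eol = "\n")
  invisible(path)
}

#' Construct an undirected PPI graph from an edge table
#'
#' Self-loops are dropped and reciprocal duplicate edges collapsed, with a
#' message reporting how many of each were removed.
#'
#' @param from,to Character vectors of equal length naming edge endpoints.
#' @return A `ppi_graph`: list with `edges` (tibble `from`/`to`, each
#'   unordered pair stored once with `from < to`) and `nodes`.
#' @export
ppi_graph <- function(from, to) {
  stopifnot(length(from) == length(to))
  from <- trimws(as.character(from)); to <- trimws(as.character(to))
  if (any(!nzchar(from)) || any(!nzchar(to)) || anyNA(from) || anyNA(to)) {
    rlang::abort("edge list contains an empty gene field")
  }
  nodes <- sort(unique(c(from, to)))
  self <- from == to
  if (any(self)) {
    rlang::inform(sprintf("dropped %d self-loop(s)", sum(self)))
    from <- from[!self]; to <- to[!self]
  }
  a <- pmin(from, to); b <- pmax(from, to)
  key <- paste(a, b, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    rlang::inform(sprintf("collapsed %d duplicate edge(s)", sum(dup)))
  }
  edges <- tibble::tibble(from = a[!dup], to = b[!dup])
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  structure(list(edges = edges, nodes = nodes), class = "ppi_graph")
}

#' @export
print.ppi_graph <- function(x, ...) {
  cat(sprintf("<ppi_graph> %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Read a two-column PPI edge list from TSV
#'
#' @param path Path to a headerless TSV with >= 2 tab-separated columns per
#'   line; extra columns are ignored.
#' @return A [ppi_graph()].
#' @export
read_edge_list <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(ppi_graph(character(0), character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(parts, length, integer(1)) < 2L
  if (any(short)) {
    rlang::abort(sprintf("edge-list format error at line %d: fewer than 2 columns",
                         which(short)[[1]]))
  }
  ppi_graph(vapply(parts, `[[`, character(1), 1L),
            vapply(parts, `[[`, character(1), 2L))
}

#' Write a PPI graph as a two-column TSV edge list
#'
#' @param graph A [ppi_graph()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  stopifnot(inherits(graph, "ppi_graph"))
  utils::write.table(graph$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, eol = "\n")
  invisible(path)
}
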