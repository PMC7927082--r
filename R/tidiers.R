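# broom-style tidy()/glance() methods for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a co-expression fit into a gene-module table
#'
#' @param x An `ab_coexpression` object from [fit_coexpression()].
#' @param ... Unused.
#' @return Tibble with `gene`, `module`.
#' @export
tidy.ab_coexpression <- function(x, ...) {
  tibble::as_tibble(x$partition)
}

#' One-row summary of a co-expression fit
#'
#' @param x An `ab_coexpression` object.
#' @param ... Unused.
#' @return Tibble with `n_genes`, `n_samples`, `beta`, `r_squared` (fit at
#'   the selected power), `n_modules`, `n_unassigned`.
#' @export
glance.ab_coexpression <- function(x, ...) {
  mods <- setdiff(unique(x$partition$module), "unassigned")
  tibble::tibble(
    n_genes = x$n_genes, n_samples = x$n_samples, beta = x$beta,
    r_squared = x$fits$r_squared[match(x$beta, x$fits$beta)],
    n_modules = length(mods),
    n_unassigned = sum(x$partition$module == "unassigned")
  )
}

#' Tidy a run report's module enrichments
#'
#' @param x An `ab_run_report` from [run_pipeline()].
#' @param ... Unused.
#' @return Tibble of all module enrichment tables with `region` and
#'   `target` columns.
#' @export
tidy.ab_run_report <- function(x, ...) {
  rows <- list()
  for (r in names(x$regions)) {
    for (tt in names(x$regions[[r]]$enrichments)) {
      e <- x$regions[[r]]$enrichments[[tt]]
      if (is.null(e)) next
      e$region <- r; e$target <- tt
      rows[[paste(r, tt)]] <- e
    }
  }
  dplyr::bind_rows(rows)
}

#' One-row summary of a pipeline run
#'
#' @param x An `ab_run_report`.
#' @param ... Unused.
#' @return Tibble with region count, key-set count and sizes.
#' @export
glance.ab_run_report <- function(x, ...) {
  tibble::tibble(
    n_regions = length(x$regions),
    n_key_sets = length(x$key_sets),
    key_sets = paste(sprintf("%s(%d)", names(x$key_sets),
                             vapply(x$key_sets, length, integer(1))),
                     collapse = ", ")
  )
}
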