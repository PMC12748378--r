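# Light S3 container for cell-by-gene count data. Counts are stored
# genes-in-rows (10x convention) as a sparse dgCMatrix; per-cell metadata
# travels alongside as a tibble so downstream verbs stay tidyverse-native.

#' Construct a cell matrix container
#'
#' Bundles a sparse gene-by-cell count matrix with per-cell metadata.
#' `n_genes_detected` is recomputed from the counts when missing and
#' validated against them when present.
#'
#' @param counts Gene-by-cell matrix (coerced to `dgCMatrix`) with gene
#'   symbols as rownames and cell barcodes as colnames.
#' @param cells Data frame with one row per cell: `cell_id` matching
#'   `colnames(counts)`, plus `sample`, `cell_type`, optional
#'   `n_genes_detected` and `mito_frac` (proportion in `[0, 1]`).
#' @return An object of class `cell_matrix` with elements `counts` and
#'   `cells`.
#' @export
cell_matrix <- function(counts, cells) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  cells <- as_tibble(cells)
  if (!"cell_id" %in% names(cells)) {
    stop_input("`cells` must have a `cell_id` column.")
  }
  cn <- colnames(counts) %||% character(0)
  if (ncol(counts) != nrow(cells) ||
      !identical(cn, as.character(cells$cell_id))) {
    stop_input("`cells$cell_id` must match colnames(counts) in order.")
  }
  if (any(counts@x < 0)) stop_input("counts must be nonnegative.")
  detected <- Matrix::colSums(counts > 0)
  if (!"n_genes_detected" %in% names(cells)) {
    cells$n_genes_detected <- as.integer(detected)
  } else if (!isTRUE(all(cells$n_genes_detected == detected))) {
    stop_input("`n_genes_detected` inconsistent with the count matrix.")
  }
  if ("mito_frac" %in% names(cells)) {
    check_prob(cells$mito_frac, "cells$mito_frac")
  }
  structure(list(counts = counts, cells = cells), class = "cell_matrix")
}

#' @export
print.cell_matrix <- function(x, ...) {
  n_samp <- if ("sample" %in% names(x$cells)) {
    dplyr::n_distinct(x$cells$sample)
  } else {
    NA_integer_
  }
  cat(sprintf(
    "<cell_matrix> %d genes x %d cells (%s samples)\n",
    nrow(x$counts), ncol(x$counts), n_samp
  ))
  invisible(x)
}

#' @export
dim.cell_matrix <- function(x) dim(x$counts)
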