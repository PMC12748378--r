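# Container for one spatial transcriptomics section: a gene-by-spot
# expression matrix plus 2-D spot coordinates. Expression may be raw
# counts or already-normalized values; the proximity machinery is
# rank-based and accepts either.

#' Construct a spatial section
#'
#' @param section_id Character id for the tissue section.
#' @param expr Gene-by-spot numeric matrix (rownames = genes, colnames =
#'   spot ids); nonnegative.
#' @param coords Data frame with one row per spot: `spot_id` matching
#'   `colnames(expr)` plus numeric `x`, `y` (section units; authoritative
#'   for all distance computations) and optional integer `row`, `col`
#'   (array indices, reporting only).
#' @return An object of class `spatial_section`.
#' @export
spatial_section <- function(section_id, expr, coords) {
  expr <- as.matrix(expr)
  coords <- as_tibble(coords)
  if (!all(c("spot_id", "x", "y") %in% names(coords))) {
    stop_input("`coords` needs columns spot_id, x, y.")
  }
  if (anyDuplicated(coords$spot_id)) {
    stop_input("duplicate spot_id in `coords`.")
  }
  if (ncol(expr) != nrow(coords) ||
      !setequal(colnames(expr), coords$spot_id)) {
    missing <- setdiff(colnames(expr), coords$spot_id)
    stop_input(sprintf(
      "spots in the expression matrix lack coordinates: %s",
      paste(head(missing, 5), collapse = ", ")
    ))
  }
  coords <- coords[match(colnames(expr), coords$spot_id), ]
  if (any(expr < 0)) stop_input("expression values must be nonnegative.")
  structure(
    list(section_id = as.character(section_id), expr = expr, coords = coords),
    class = "spatial_section"
  )
}

#' @export
print.spatial_section <- function(x, ...) {
  cat(sprintf("<spatial_section '%s'> %d genes x %d spots\n",
              x$section_id, nrow(x$expr), ncol(x$expr)))
  invisible(x)
}

#' @export
dim.spatial_section <- function(x) dim(x$expr)
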