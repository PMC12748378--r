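# QC filtering, log-normalization, per-sample quartile stratification of
# epithelial cells by anchor-gene expression, and rank-sum differential
# expression between the high and low groups.

#' Quality-control filter for cells
#'
#' Retains cells with a detected-gene count between `min_genes` and
#' `max_genes` (inclusive) and a mitochondrial fraction at or below
#' `max_mito` — only cells strictly exceeding the mitochondrial bound are
#' removed. Counts removed per criterion are reported. Idempotent.
#'
#' @param x A [cell_matrix()] whose metadata carries `n_genes_detected`
#'   and `mito_frac`.
#' @param min_genes,max_genes Detected-gene bounds (defaults 50 / 9000).
#' @param max_mito Mitochondrial-fraction bound (default 0.15).
#' @return Filtered [cell_matrix()].
#' @export
qc_filter <- function(x, min_genes = 50L, max_genes = 9000L,
                      max_mito = 0.15) {
  if (!inherits(x, "cell_matrix")) stop_input("`x` must be a cell_matrix.")
  cells <- x$cells
  if (!"mito_frac" %in% names(cells)) {
    stop_input("metadata lacks `mito_frac`; cannot QC-filter.")
  }
  low <- cells$n_genes_detected < min_genes
  high <- cells$n_genes_detected > max_genes
  mito <- cells$mito_frac > max_mito
  keep <- !(low | high | mito)
  rlang::inform(sprintf(
    "qc_filter: removed %d low-gene, %d high-gene, %d high-mito cells; %d kept.",
    sum(low), sum(high), sum(mito & !low & !high), sum(keep)
  ))
  cell_matrix(x$counts[, keep, drop = FALSE],
              cells[keep, , drop = FALSE])
}

#' Log-normalize counts
#'
#' Per cell: counts divided by the cell total, scaled to `scale_factor`
#' (default 10,000) and transformed with `log(1 + x)`. Cells with zero
#' total counts are an error (named), never silently dropped.
#'
#' @param x A [cell_matrix()] of raw counts.
#' @param scale_factor Library-size scale, default `1e4`.
#' @return A [cell_matrix()] holding normalized values, flagged with
#'   attribute `normalized = TRUE`.
#' @export
normalize_log <- function(x, scale_factor = 1e4) {
  if (!inherits(x, "cell_matrix")) stop_input("`x` must be a cell_matrix.")
  totals <- Matrix::colSums(x$counts)
  if (any(totals == 0)) {
    bad <- colnames(x$counts)[totals == 0]
    stop_input(sprintf("cell(s) with zero total counts: %s",
                       paste(head(bad, 5), collapse = ", ")))
  }
  m <- x$counts
  if (length(m@x)) {
    m@x <- m@x / rep.int(totals, diff(m@p)) * scale_factor
    m@x <- log1p(m@x)
  }
  out <- cell_matrix(m, x$cells)
  attr(out, "normalized") <- TRUE
  out
}

#' Assign epithelial cells to anchor-high / anchor-low quartile groups
#'
#' Within each sample's epithelial cells, the anchor gene's normalized
#' expression is scaled (by default a within-sample z-score) and the 25th
#' and 75th percentiles are computed by linear interpolation (R's default
#' type-7 convention). Cells at or above the 75th percentile are `high`,
#' at or below the 25th `low`; intermediates and all non-epithelial cells
#' are `excluded`. Samples with fewer than 4 epithelial cells, or whose
#' two percentiles coincide (constant expression), are skipped with a
#' warning and contribute only excluded cells.
#'
#' @param x A normalized [cell_matrix()] (see [normalize_log()]).
#' @param anchor Anchor gene symbol.
#' @param epithelial_label Value of `cell_type` marking epithelial cells.
#' @param scaling `"zscore"` (default) or `"lognorm"` to rank on the raw
#'   log-normalized value.
#' @param per_sample Compute quartiles within each sample (default) or
#'   globally across all epithelial cells.
#' @param quartiles Closed percentile bounds, default `c(0.25, 0.75)`.
#' @return A tibble (class `group_assignment`): `cell_id`, `sample`,
#'   `scaled_value`, `label`; per-sample thresholds in
#'   `attr(, "thresholds")`.
#' @export
assign_groups <- function(x, anchor = "CCNE1",
                          epithelial_label = "epithelial",
                          scaling = c("zscore", "lognorm"),
                          per_sample = TRUE,
                          quartiles = c(0.25, 0.75)) {
  scaling <- match.arg(scaling)
  if (!inherits(x, "cell_matrix")) stop_input("`x` must be a cell_matrix.")
  if (!anchor %in% rownames(x$counts)) {
    stop_input(sprintf("anchor gene '%s' absent from the matrix.", anchor))
  }
  if (!"cell_type" %in% names(x$cells)) {
    stop_input("metadata lacks `cell_type`.")
  }
  cells <- x$cells
  if (!"sample" %in% names(cells)) cells$sample <- "sample1"
  expr <- as.numeric(x$counts[anchor, ])
  out <- tibble(
    cell_id = cells$cell_id, sample = cells$sample,
    cell_type = cells$cell_type, value = expr,
    scaled_value = NA_real_, label = "excluded"
  )
  epi <- out$cell_type == epithelial_label
  groups <- if (per_sample) split(which(epi), out$sample[epi]) else
    list(all = which(epi))
  thresholds <- purrr::imap(groups, function(idx, sample_id) {
    v <- out$value[idx]
    if (length(idx) < 4) {
      rlang::warn(sprintf(
        "sample '%s' has %d epithelial cell(s) (< 4); skipped.",
        sample_id, length(idx)
      ))
      return(tibble(sample = sample_id, n_epithelial = length(idx),
                    q_low = NA_real_, q_high = NA_real_, skipped = TRUE,
                    reason = "too-few-epithelial-cells"))
    }
    s <- if (scaling == "zscore") {
      sdv <- stats::sd(v)
      if (sdv > 0) (v - mean(v)) / sdv else v - mean(v)
    } else {
      v
    }
    q_low <- percentile(s, quartiles[1])
    q_high <- percentile(s, quartiles[2])
    out$scaled_value[idx] <<- s
    if (q_high == q_low) {
      rlang::warn(sprintf(
        "sample '%s': degenerate anchor distribution (q%g == q%g); all cells excluded.",
        sample_id, 100 * quartiles[2], 100 * quartiles[1]
      ))
      return(tibble(sample = sample_id, n_epithelial = length(idx),
                    q_low = q_low, q_high = q_high, skipped = TRUE,
                    reason = "degenerate-distribution"))
    }
    out$label[idx[s >= q_high]] <<- "high"
    out$label[idx[s <= q_low]] <<- "low"
    tibble(sample = sample_id, n_epithelial = length(idx),
           q_low = q_low, q_high = q_high, skipped = FALSE,
           reason = NA_character_)
  })
  res <- dplyr::select(out, "cell_id", "sample", "scaled_value", "label")
  attr(res, "thresholds") <- dplyr::bind_rows(thresholds)
  attr(res, "anchor") <- anchor
  class(res) <- c("group_assignment", class(res))
  res
}

#' Rank-sum differential expression between anchor-high and -low cells
#'
#' For every gene detected in at least `min_cells` cells across the two
#' groups: `avg_log2FC = log2((mean_high + pc) / (mean_low + pc))` with
#' pseudocount `pc = 1`, where the group means are taken on the de-logged
#' normalized expression (`expm1` of the log-normalized values, i.e.
#' counts per 10k — the convention of Seurat's `FindMarkers`, so that a
#' planted k-fold expression shift yields an avg_log2FC near `log2(k)`
#' rather than a doubly-logged, compressed value); a two-sided Wilcoxon
#' rank-sum p on the (monotone-equivalent) log values, exact enumeration
#' when both groups have at most 10 cells and tie-corrected normal
#' approximation otherwise; Benjamini-Hochberg adjustment across tested
#' genes; and a pass flag at `|avg_log2FC| > log2fc_threshold` and
#' adjusted p `< alpha`.
#'
#' @param x A normalized [cell_matrix()].
#' @param assignment A [assign_groups()] result.
#' @param log2fc_threshold Absolute avg_log2FC threshold (default 2).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param min_cells Minimum detection across both groups (default 3).
#' @param pseudocount Pseudocount inside both group means (default 1).
#' @return Tibble: `gene`, `avg_log2FC`, `p_value`, `p_adjusted`, `pass`,
#'   sorted by `p_adjusted` then `p_value` then gene.
#' @export
differential_expression <- function(x, assignment,
                                    log2fc_threshold = 2, alpha = 0.05,
                                    min_cells = 3L, pseudocount = 1) {
  if (!inherits(x, "cell_matrix")) stop_input("`x` must be a cell_matrix.")
  idx_high <- match(assignment$cell_id[assignment$label == "high"],
                    colnames(x$counts))
  idx_low <- match(assignment$cell_id[assignment$label == "low"],
                   colnames(x$counts))
  if (length(idx_high) == 0 || length(idx_low) == 0) {
    stop_input("both the high and the low group must be nonempty.")
  }
  mh <- as.matrix(x$counts[, idx_high, drop = FALSE])
  ml <- as.matrix(x$counts[, idx_low, drop = FALSE])
  detected <- rowSums(mh > 0) + rowSums(ml > 0)
  tested <- which(detected >= min_cells)
  if (length(tested) == 0) {
    rlang::warn("no gene passes the detection threshold; empty result.")
    return(tibble(gene = character(0), avg_log2FC = numeric(0),
                  p_value = numeric(0), p_adjusted = numeric(0),
                  pass = logical(0)))
  }
  lfc <- log2((rowMeans(expm1(mh[tested, , drop = FALSE])) + pseudocount) /
                (rowMeans(expm1(ml[tested, , drop = FALSE])) + pseudocount))
  pvals <- vapply(tested, function(i) {
    ranksum_p(mh[i, ], ml[i, ], alternative = "two.sided", exact_max = 10L)
  }, numeric(1))
  res <- tibble(
    gene = rownames(x$counts)[tested],
    avg_log2FC = unname(lfc),
    p_value = pvals,
    p_adjusted = bh_adjust(pvals)
  ) |>
    dplyr::mutate(pass = abs(.data$avg_log2FC) > log2fc_threshold &
                    .data$p_adjusted < alpha) |>
    dplyr::arrange(.data$p_adjusted, .data$p_value, .data$gene)
  res
}
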