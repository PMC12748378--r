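#' Configuration for a synthetic single-cell count matrix
#'
#' Describes a multi-sample single-cell experiment in which the anchor
#' gene's expression is epithelial-restricted and, within the epithelial
#' compartment of each sample, a high-expressing subpopulation carries the
#' anchor shift plus a set of planted differential genes. All counts are
#' negative binomial: rank-based downstream tests need only ordinal
#' structure and the NB mean/dispersion parameterisation matches standard
#' scRNA-seq overdispersion conventions.
#'
#' @param n_samples,cells_per_sample,n_genes Experiment dimensions.
#' @param anchor Anchor gene symbol; always included in the gene list.
#' @param epithelial_fraction Fraction of each sample's cells labeled
#'   epithelial.
#' @param high_subpop_fraction Fraction of epithelial cells per sample in
#'   the anchor-high subpopulation.
#' @param anchor_log2_shift Log2 fold shift of the anchor-gene mean in the
#'   high subpopulation.
#' @param planted_deg Data frame with columns `gene`, `log2fc`: genes whose
#'   NB mean is shifted by `2^log2fc` in the high subpopulation.
#' @param base_mean_shape,base_mean_rate Gamma hyperparameters for per-gene
#'   baseline NB means.
#' @param dispersion NB dispersion (1/size); shared across genes.
#' @param mito_shape1,mito_shape2 Beta parameters for simulated per-cell
#'   mitochondrial fractions.
#' @param genes Optional explicit gene list; must contain `anchor` and all
#'   planted genes. Default: anchor + planted + autogenerated background.
#' @param seed Integer RNG seed.
#' @return A validated `cell_config` list.
#' @seealso [generate_cell_matrix()]
#' @export
cell_config <- function(n_samples = 3L,
                        cells_per_sample = 500L,
                        n_genes = 200L,
                        anchor = "CCNE1",
                        epithelial_fraction = 0.5,
                        high_subpop_fraction = 0.25,
                        anchor_log2_shift = 2,
                        planted_deg = NULL,
                        base_mean_shape = 0.7,
                        base_mean_rate = 0.35,
                        dispersion = 0.5,
                        mito_shape1 = 2,
                        mito_shape2 = 20,
                        genes = NULL,
                        seed = 1L) {
  check_count(n_samples, "n_samples")
  check_count(cells_per_sample, "cells_per_sample")
  check_count(n_genes, "n_genes")
  check_prob(epithelial_fraction, "epithelial_fraction")
  check_prob(high_subpop_fraction, "high_subpop_fraction")
  if (!is.null(planted_deg)) {
    planted_deg <- as_tibble(planted_deg)
    if (!all(c("gene", "log2fc") %in% names(planted_deg))) {
      stop_config("`planted_deg` needs columns gene, log2fc.")
    }
    if (anchor %in% planted_deg$gene) {
      stop_config("the anchor gene cannot also be a planted DEG.")
    }
  }
  n_planted <- if (is.null(planted_deg)) 0L else nrow(planted_deg)
  if (n_genes < n_planted + 1L) {
    stop_config("`n_genes` must be at least the number of planted genes + 1.")
  }
  if (is.null(genes)) {
    n_bg <- n_genes - n_planted - 1L
    genes <- c(anchor,
               if (n_planted) planted_deg$gene,
               sprintf("G%04d", seq_len(n_bg)))
  } else {
    genes <- as.character(genes)
    missing <- setdiff(c(anchor, if (n_planted) planted_deg$gene), genes)
    if (length(missing)) {
      stop_config(sprintf(
        "planted/anchor gene(s) not in gene list: %s",
        paste(missing, collapse = ", ")
      ))
    }
    if (length(genes) != n_genes) {
      stop_config("`genes` length must equal `n_genes`.")
    }
  }
  if (anyDuplicated(genes)) stop_config("gene list must be unique.")
  if (dispersion < 0) stop_config("`dispersion` must be >= 0.")
  structure(
    list(
      n_samples = as.integer(n_samples),
      cells_per_sample = as.integer(cells_per_sample),
      n_genes = as.integer(n_genes),
      anchor = anchor,
      epithelial_fraction = epithelial_fraction,
      high_subpop_fraction = high_subpop_fraction,
      anchor_log2_shift = anchor_log2_shift,
      planted_deg = planted_deg,
      base_mean_shape = base_mean_shape,
      base_mean_rate = base_mean_rate,
      dispersion = dispersion,
      mito_shape1 = mito_shape1,
      mito_shape2 = mito_shape2,
      genes = genes,
      seed = as.integer(seed)
    ),
    class = "cell_config"
  )
}

# NB draw that degrades gracefully to Poisson/deterministic at dispersion 0
rnb <- function(n, mu, dispersion) {
  if (dispersion <= 0) {
    stats::rpois(n, lambda = mu)
  } else {
    stats::rnbinom(n, mu = mu, size = 1 / dispersion)
  }
}

#' Generate a synthetic cell-by-gene count matrix
#'
#' Baseline per-gene NB means are drawn once from a Gamma prior; the anchor
#' gene's baseline is anchored at 1.0 so its quartile structure is stable.
#' Within each sample (its own deterministic sub-stream) the first
#' `epithelial_fraction` of cells is flagged epithelial, and the first
#' `high_subpop_fraction` of those receives the anchor shift and the
#' planted log2 fold changes, applied multiplicatively to the NB mean.
#'
#' @param config A [cell_config()].
#' @return A [cell_matrix()] whose `cells` tibble carries `sample`,
#'   `cell_type` (`"epithelial"`/`"stromal"`), the ground-truth
#'   `true_high` flag, `n_genes_detected` and a simulated `mito_frac`.
#' @export
generate_cell_matrix <- function(config) {
  if (!inherits(config, "cell_config")) {
    stop_config("`config` must be created by cell_config().")
  }
  genes <- config$genes
  mu0 <- with_seed(substream_seed(config$seed, "gene_means"), {
    mu <- stats::rgamma(length(genes), shape = config$base_mean_shape,
                        rate = config$base_mean_rate)
    names(mu) <- genes
    mu[config$anchor] <- 1.0
    mu
  })
  lfc <- stats::setNames(rep(0, length(genes)), genes)
  lfc[config$anchor] <- config$anchor_log2_shift
  if (!is.null(config$planted_deg)) {
    lfc[config$planted_deg$gene] <- config$planted_deg$log2fc
  }
  per_sample <- purrr::map(seq_len(config$n_samples), function(s) {
    sample_id <- sprintf("S%02d", s)
    with_seed(substream_seed(config$seed, sample_id), {
      nc <- config$cells_per_sample
      n_epi <- round(config$epithelial_fraction * nc)
      n_high <- round(config$high_subpop_fraction * n_epi)
      is_epi <- seq_len(nc) <= n_epi
      is_high <- seq_len(nc) <= n_high
      counts <- vapply(seq_len(nc), function(i) {
        mu <- if (is_high[i]) mu0 * 2^lfc else mu0
        rnb(length(genes), mu, config$dispersion)
      }, numeric(length(genes)))
      counts <- matrix(counts, nrow = length(genes))
      rownames(counts) <- genes
      colnames(counts) <- sprintf("%s_c%04d", sample_id, seq_len(nc))
      meta <- tibble(
        cell_id = colnames(counts),
        sample = rep(sample_id, nc),
        cell_type = ifelse(is_epi, "epithelial", "stromal"),
        true_high = is_high,
        mito_frac = stats::rbeta(nc, config$mito_shape1, config$mito_shape2)
      )
      list(counts = counts, meta = meta)
    })
  })
  counts <- do.call(cbind, purrr::map(per_sample, "counts"))
  if (is.null(counts)) {
    counts <- matrix(0, nrow = length(genes), ncol = 0,
                     dimnames = list(genes, character(0)))
  }
  meta <- dplyr::bind_rows(purrr::map(per_sample, "meta"))
  if (nrow(meta) == 0) {
    meta <- tibble(cell_id = character(0), sample = character(0),
                   cell_type = character(0), true_high = logical(0),
                   mito_frac = numeric(0))
  }
  cell_matrix(counts, meta)
}
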