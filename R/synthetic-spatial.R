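#' Configuration for a synthetic spatial section
#'
#' Describes one spatial transcriptomics section on a regular grid with a
#' circular epithelial-like niche. Inside the niche the anchor gene's NB
#' mean is multiplied by `2^anchor_strength`; each partner gene is likewise
#' elevated by `2^strength`, so planted log2 effects stay interpretable.
#' Background genes are spatially exchangeable (same mean everywhere).
#'
#' @param rows,cols Grid dimensions; spot coordinates are the integer grid
#'   positions in section units (`x = col`, `y = row`).
#' @param niche_center Numeric length-2 `(x, y)` center of the niche;
#'   default the grid center. Must lie within the grid's bounding box.
#' @param niche_radius Niche radius in coordinate units; must be > 0.
#' @param anchor Anchor gene symbol.
#' @param anchor_strength Log2 fold elevation of the anchor inside the
#'   niche.
#' @param partners Data frame with columns `gene`, `strength` (log2 fold
#'   elevation inside the niche, `>= 0`).
#' @param n_background_genes Number of spatially exchangeable genes.
#' @param base_mean Baseline NB mean per spot.
#' @param dispersion NB dispersion (1/size); `0` gives Poisson noise.
#' @param noise `"nb"` for count noise, `"none"` for a noise-free section
#'   whose expression equals the mean surface exactly (useful to verify
#'   that a strongly elevated gene's high region recovers the niche).
#' @param seed Integer RNG seed.
#' @return A validated `spatial_config` list.
#' @seealso [generate_spatial_section()]
#' @export
spatial_config <- function(rows = 20L,
                           cols = 20L,
                           niche_center = NULL,
                           niche_radius = max(rows, cols) / 4,
                           anchor = "CCNE1",
                           anchor_strength = 3,
                           partners = NULL,
                           n_background_genes = 50L,
                           base_mean = 2,
                           dispersion = 0.4,
                           noise = c("nb", "none"),
                           seed = 1L) {
  noise <- match.arg(noise)
  check_count(rows, "rows")
  check_count(cols, "cols")
  if (rows < 1 || cols < 1) stop_config("grid must have >= 1 row and column.")
  if (is.null(niche_center)) niche_center <- c((1 + cols) / 2, (1 + rows) / 2)
  if (length(niche_center) != 2 || !is.numeric(niche_center)) {
    stop_config("`niche_center` must be numeric (x, y).")
  }
  if (niche_center[1] < 1 || niche_center[1] > cols ||
      niche_center[2] < 1 || niche_center[2] > rows) {
    stop_config("`niche_center` must lie within the grid's bounding box.")
  }
  if (!is.numeric(niche_radius) || niche_radius <= 0) {
    stop_config("`niche_radius` must be > 0.")
  }
  if (!is.null(partners)) {
    partners <- as_tibble(partners)
    if (!all(c("gene", "strength") %in% names(partners))) {
      stop_config("`partners` needs columns gene, strength.")
    }
    if (any(partners$strength < 0)) {
      stop_config("partner `strength` must be >= 0.")
    }
    if (anchor %in% partners$gene) {
      stop_config("the anchor cannot be its own partner.")
    }
  }
  if (dispersion < 0) stop_config("`dispersion` must be >= 0.")
  structure(
    list(rows = as.integer(rows), cols = as.integer(cols),
         niche_center = niche_center, niche_radius = niche_radius,
         anchor = anchor, anchor_strength = anchor_strength,
         partners = partners,
         n_background_genes = as.integer(n_background_genes),
         base_mean = base_mean, dispersion = dispersion, noise = noise,
         seed = as.integer(seed)),
    class = "spatial_config"
  )
}

#' Generate a synthetic spatial section
#'
#' Spots sit on the integer grid. Spots whose Euclidean distance to the
#' niche center is at most the radius form the niche; anchor and partner
#' genes have their NB mean multiplied by `2^strength` there. Each gene
#' draws from its own deterministic sub-stream, so adding a partner leaves
#' the background genes' counts untouched.
#'
#' @param config A [spatial_config()].
#' @param section_id Section identifier; default `"section1"`.
#' @return A [spatial_section()] whose `coords` carry `row`, `col`,
#'   `x`, `y` and the ground-truth `in_niche` flag.
#' @export
generate_spatial_section <- function(config, section_id = "section1") {
  if (!inherits(config, "spatial_config")) {
    stop_config("`config` must be created by spatial_config().")
  }
  grid <- tidyr::expand_grid(row = seq_len(config$rows),
                             col = seq_len(config$cols))
  coords <- tibble(
    spot_id = sprintf("spot_%04d", seq_len(nrow(grid))),
    row = grid$row, col = grid$col,
    x = as.numeric(grid$col), y = as.numeric(grid$row)
  )
  in_niche <- sqrt((coords$x - config$niche_center[1])^2 +
                   (coords$y - config$niche_center[2])^2) <=
    config$niche_radius
  coords$in_niche <- in_niche
  partners <- config$partners
  genes <- c(config$anchor,
             if (!is.null(partners)) partners$gene,
             if (config$n_background_genes > 0) {
               sprintf("BG%04d", seq_len(config$n_background_genes))
             })
  strength <- stats::setNames(rep(0, length(genes)), genes)
  strength[config$anchor] <- config$anchor_strength
  if (!is.null(partners)) strength[partners$gene] <- partners$strength
  n_spots <- nrow(coords)
  expr <- matrix(0, nrow = length(genes), ncol = n_spots,
                 dimnames = list(genes, coords$spot_id))
  for (g in genes) {
    mu <- rep(config$base_mean, n_spots)
    mu[in_niche] <- mu[in_niche] * 2^strength[g]
    expr[g, ] <- if (config$noise == "none") {
      mu
    } else {
      with_seed(
        substream_seed(config$seed, paste(section_id, g, sep = "|")),
        rnb(n_spots, mu, config$dispersion)
      )
    }
  }
  spatial_section(section_id, expr, coords)
}
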