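# Spatial colocalization framework: high-expression region masks,
# nearest-neighbor Euclidean distance statistics, expression-permutation
# nulls with an empirical p (+1/(B+1) convention), Mann-Whitney secondary
# tests, Spearman colocalization, and the genome-wide consistency screen.

#' High-expression region of a gene within a section
#'
#' The region is the top `top_fraction` of spots by the gene's expression:
#' threshold = the `(1 - top_fraction)` percentile over all spots (linear
#' interpolation, type 7), members = spots with expression at or above the
#' threshold. When the threshold equals the gene's minimum the mask would
#' cover every spot and the gene is marked skipped
#' (`"uninformative-distribution"`) rather than tested.
#'
#' @param section A [spatial_section()] with at least 4 spots.
#' @param gene Gene symbol; must be present.
#' @param top_fraction Fraction of spots forming the region (default 0.25).
#' @return A `region_mask` list: `gene`, `section_id`, `spots` (member
#'   ids), `threshold`, `skipped`, `reason`.
#' @export
high_region_mask <- function(section, gene, top_fraction = 0.25) {
  if (!inherits(section, "spatial_section")) {
    stop_input("`section` must be a spatial_section.")
  }
  if (ncol(section$expr) < 4) {
    stop_input("proximity analysis needs at least 4 spots.")
  }
  if (!gene %in% rownames(section$expr)) {
    stop_input(sprintf("gene '%s' absent from section '%s'.",
                       gene, section$section_id))
  }
  if (top_fraction <= 0 || top_fraction >= 1) {
    stop_config("`top_fraction` must be in (0, 1).")
  }
  v <- section$expr[gene, ]
  threshold <- percentile(v, 1 - top_fraction)
  skipped <- threshold == min(v)
  structure(
    list(
      gene = gene, section_id = section$section_id,
      spots = if (skipped) character(0) else names(v)[v >= threshold],
      threshold = threshold, skipped = skipped,
      reason = if (skipped) "uninformative-distribution" else NA_character_
    ),
    class = "region_mask"
  )
}

# nearest-neighbor distances from each row of xy_a to the rows of xy_b
nn_dist_vec <- function(xy_a, xy_b) {
  vapply(seq_len(nrow(xy_a)), function(i) {
    sqrt(min((xy_b[, 1] - xy_a[i, 1])^2 + (xy_b[, 2] - xy_a[i, 2])^2))
  }, numeric(1))
}

mask_xy <- function(mask, coords) {
  idx <- match(mask$spots, coords$spot_id)
  cbind(coords$x[idx], coords$y[idx])
}

#' Nearest-neighbor distance statistic between two region masks
#'
#' For each spot of `mask_a`, the Euclidean distance to the nearest spot
#' of `mask_b`; the statistic `d_obs` is their arithmetic mean. A spot in
#' both masks contributes 0. Directional: swap the masks for the other
#' direction.
#'
#' @param mask_a,mask_b [high_region_mask()] results from the same
#'   section; both nonempty.
#' @param coords Coordinate table with `spot_id`, `x`, `y` (e.g. the
#'   section's `coords`).
#' @return List with `distances` (named per `mask_a` spot) and `d_obs`.
#' @export
nn_distance <- function(mask_a, mask_b, coords) {
  if (!identical(mask_a$section_id, mask_b$section_id)) {
    stop_input("masks come from different sections.")
  }
  if (length(mask_a$spots) == 0 || length(mask_b$spots) == 0) {
    stop_input("both masks must be nonempty.")
  }
  d <- nn_dist_vec(mask_xy(mask_a, coords), mask_xy(mask_b, coords))
  names(d) <- mask_a$spots
  list(distances = d, d_obs = mean(d))
}

#' Spearman colocalization of two genes across spots
#'
#' Rank correlation (average ranks for ties) of the two genes' expression
#' over all spots of a section. Zero variance in either gene yields an
#' undefined-correlation result (`rho = NA`, flagged), never a silent 0.
#'
#' @param section A [spatial_section()] with at least 3 spots.
#' @param gene_a,gene_b Gene symbols.
#' @return One-row tibble: `gene_a`, `gene_b`, `section_id`, `rho`,
#'   `defined`.
#' @export
spearman_coloc <- function(section, gene_a, gene_b) {
  if (ncol(section$expr) < 3) stop_input("need at least 3 spots.")
  for (g in c(gene_a, gene_b)) {
    if (!g %in% rownames(section$expr)) {
      stop_input(sprintf("gene '%s' absent from the section.", g))
    }
  }
  a <- section$expr[gene_a, ]
  b <- section$expr[gene_b, ]
  defined <- stats::sd(a) > 0 && stats::sd(b) > 0
  tibble(
    gene_a = gene_a, gene_b = gene_b, section_id = section$section_id,
    rho = if (defined) stats::cor(a, b, method = "spearman") else NA_real_,
    defined = defined
  )
}

# Core null machinery. Permuting a gene's expression values across spots
# preserves the value multiset, hence the top-fraction threshold and the
# mask SIZE m; the null mask is therefore a uniform random m-subset of
# spots, and the null statistic is the mean of the precomputed
# nearest-anchor distances over that subset (compiled kernel).
perm_null_stats <- function(d_min, m, B, seed) {
  with_seed(seed, .null_mean_nn(d_min, m, B))
}

perm_null_pool <- function(d_min, m, B, seed, cap = 10000L) {
  draws <- max(1L, min(as.integer(B), as.integer(ceiling(cap / m))))
  pool <- with_seed(substream_seed(seed, "mwu_pool"),
                    .null_pool_nn(d_min, m, draws))
  if (length(pool) > cap) pool <- pool[seq_len(cap)]
  pool
}

# exhaustive null over all n! value permutations, collapsed to the
# C(n, m) distinct masks (each mask arises from m! (n-m)! permutations)
perm_null_exhaustive <- function(d_min, m) {
  n <- length(d_min)
  subsets <- utils::combn(n, m)
  d <- apply(subsets, 2, function(s) mean(d_min[s]))
  weight <- factorial(m) * factorial(n - m)
  list(d = d, weight = weight, total = factorial(n))
}

empty_proximity_row <- function(gene, section_id, n_spots, reason) {
  tibble(
    gene = gene, section_id = section_id, n_spots = n_spots,
    m_high = 0L, d_obs = NA_real_, null_mean = NA_real_,
    null_sd = NA_real_, p_empirical = NA_real_, p_mwu = NA_real_,
    skipped = TRUE, reason = reason
  )
}

#' Permutation-null proximity test for one gene against the anchor
#'
#' The anchor's high region stays fixed. The observed statistic `d_obs`
#' is the mean nearest-anchor distance over the test gene's high spots.
#' For each of `B` iterations the test gene's expression values are
#' permuted across spots (preserving the overall expression distribution),
#' the high region recomputed and the null statistic recorded; the
#' empirical p is `(1 + #\{D_b <= d_obs\}) / (1 + B)`, never 0. A
#' secondary one-sided Mann-Whitney p compares observed per-spot distances
#' with pooled null distances (capped at `mwu_cap` values, deterministic).
#' Genes (or anchors) with uninformative expression propagate a skipped
#' flag instead of a p-value.
#'
#' @param section A [spatial_section()].
#' @param anchor Anchor gene symbol.
#' @param gene Test gene symbol.
#' @param top_fraction High-region fraction (default 0.25).
#' @param B Number of permutations (default 1000).
#' @param seed Integer seed; the test is deterministic given it.
#' @param exhaustive Enumerate all value permutations instead of Monte
#'   Carlo (only for small sections; `B` is ignored).
#' @param null_mode `"expression"` (default: permute the test gene's
#'   values, anchor mask fixed) or `"coordinates"` (permute the spot
#'   coordinates jointly, both masks fixed) — see the methods vignette for
#'   why expression permutation is the default.
#' @param mwu_cap Cap on pooled null distances entering the Mann-Whitney
#'   test.
#' @return One-row tibble (`gene`, `section_id`, `n_spots`, `m_high`,
#'   `d_obs`, `null_mean`, `null_sd`, `p_empirical`, `p_mwu`, `skipped`,
#'   `reason`) with the null statistics in `attr(, "null")`.
#' @export
permutation_null <- function(section, anchor, gene, top_fraction = 0.25,
                             B = 1000L, seed = 1L, exhaustive = FALSE,
                             null_mode = c("expression", "coordinates"),
                             mwu_cap = 10000L) {
  null_mode <- match.arg(null_mode)
  if (B < 1) stop_config("`B` must be >= 1.")
  anchor_mask <- high_region_mask(section, anchor, top_fraction)
  if (anchor_mask$skipped) {
    return(empty_proximity_row(gene, section$section_id, ncol(section$expr),
                               "anchor-uninformative"))
  }
  test_mask <- high_region_mask(section, gene, top_fraction)
  n <- ncol(section$expr)
  if (test_mask$skipped) {
    return(empty_proximity_row(gene, section$section_id, n,
                               test_mask$reason))
  }
  coords <- section$coords
  xy_anchor <- mask_xy(anchor_mask, coords)
  d_min <- nn_dist_vec(cbind(coords$x, coords$y), xy_anchor)
  member_idx <- match(test_mask$spots, coords$spot_id)
  obs <- d_min[member_idx]
  d_obs <- mean(obs)
  m <- length(member_idx)
  eps <- 1e-9
  if (null_mode == "coordinates") {
    xy <- cbind(coords$x, coords$y)
    nulls <- with_seed(seed, {
      vapply(seq_len(B), function(b) {
        perm <- sample.int(n)
        mean(nn_dist_vec(xy[perm[member_idx], , drop = FALSE],
                         xy[perm[match(anchor_mask$spots, coords$spot_id)], ,
                            drop = FALSE]))
      }, numeric(1))
    })
    count <- sum(nulls <= d_obs + eps)
    b_eff <- B
  } else if (exhaustive) {
    ex <- perm_null_exhaustive(d_min, m)
    nulls <- ex$d
    count <- sum(nulls <= d_obs + eps) * ex$weight
    b_eff <- ex$total
  } else {
    nulls <- perm_null_stats(d_min, m, B, seed)
    count <- sum(nulls <= d_obs + eps)
    b_eff <- B
  }
  p_emp <- (1 + count) / (1 + b_eff)
  pooled <- if (null_mode == "coordinates") nulls else {
    # per-spot null distances: d_min over the null masks; re-draw
    # deterministically from a shifted sub-stream to keep p_emp's stream
    # untouched, then cap
    if (exhaustive) {
      as.numeric(apply(utils::combn(n, m), 2, function(s) d_min[s]))
    } else {
      perm_null_pool(d_min, m, B, seed, cap = mwu_cap)
    }
  }
  p_mwu <- mwu_test(obs, pooled)
  out <- tibble(
    gene = gene, section_id = section$section_id, n_spots = n,
    m_high = m, d_obs = d_obs, null_mean = mean(nulls),
    null_sd = stats::sd(nulls), p_empirical = p_emp, p_mwu = p_mwu,
    skipped = FALSE, reason = NA_character_
  )
  attr(out, "null") <- nulls
  attr(out, "observed_distances") <- obs
  out
}

#' Genome-wide consistent-proximity screen
#'
#' Runs [permutation_null()] for every non-anchor gene with an informative
#' expression distribution, in every section; adjusts the empirical
#' p-values by Benjamini-Hochberg within each section; and flags a gene
#' *consistent* when it was testable in every section and its adjusted q
#' is at or below `alpha` in all of them. Consistent genes are ranked by
#' mean `d_obs` ascending (ties broken lexicographically by gene). Each
#' (section, gene) pair draws from its own deterministic sub-stream, so
#' results do not depend on iteration order.
#'
#' @param sections A [spatial_section()] or list of them.
#' @param anchor Anchor gene symbol.
#' @param B Number of permutations per gene.
#' @param alpha Significance level on the within-section BH q.
#' @param top_fraction High-region fraction.
#' @param seed Integer seed.
#' @param null_mode Passed to [permutation_null()].
#' @return An object of class `spatial_screen`; `tidy()` returns the
#'   per-gene summary, `glance()` the screen-level counts; the per-section
#'   detail sits in `$per_section`.
#' @export
genome_screen <- function(sections, anchor = "CCNE1", B = 1000L,
                          alpha = 0.05, top_fraction = 0.25, seed = 1L,
                          null_mode = c("expression", "coordinates")) {
  null_mode <- match.arg(null_mode)
  if (inherits(sections, "spatial_section")) sections <- list(sections)
  if (length(sections) == 0) stop_input("need at least one section.")
  per_section <- purrr::map(sections, function(section) {
    genes <- setdiff(rownames(section$expr), anchor)
    anchor_mask <- high_region_mask(section, anchor, top_fraction)
    if (anchor_mask$skipped) {
      rlang::warn(sprintf(
        "section '%s': anchor distribution uninformative; all genes skipped.",
        section$section_id
      ))
      return(dplyr::bind_rows(purrr::map(genes, function(g) {
        empty_proximity_row(g, section$section_id, ncol(section$expr),
                            "anchor-uninformative")
      })) |> dplyr::mutate(q = NA_real_))
    }
    coords <- section$coords
    d_min <- nn_dist_vec(cbind(coords$x, coords$y),
                         mask_xy(anchor_mask, coords))
    n <- ncol(section$expr)
    rows <- purrr::map(genes, function(g) {
      gene_seed <- substream_seed(seed, paste(section$section_id, g,
                                              sep = "|"))
      if (null_mode == "coordinates") {
        return(permutation_null(section, anchor, g, top_fraction, B,
                                gene_seed, null_mode = "coordinates"))
      }
      mask <- high_region_mask(section, g, top_fraction)
      if (mask$skipped) {
        return(empty_proximity_row(g, section$section_id, n, mask$reason))
      }
      member_idx <- match(mask$spots, coords$spot_id)
      obs <- d_min[member_idx]
      d_obs <- mean(obs)
      m <- length(member_idx)
      nulls <- perm_null_stats(d_min, m, B, gene_seed)
      pool <- perm_null_pool(d_min, m, B, gene_seed)
      tibble(
        gene = g, section_id = section$section_id, n_spots = n,
        m_high = m, d_obs = d_obs, null_mean = mean(nulls),
        null_sd = stats::sd(nulls),
        p_empirical = (1 + sum(nulls <= d_obs + 1e-9)) / (1 + B),
        p_mwu = mwu_test(obs, pool),
        skipped = FALSE, reason = NA_character_
      )
    })
    tab <- dplyr::bind_rows(rows)
    tab$q <- NA_real_
    tested <- !tab$skipped
    if (any(tested)) tab$q[tested] <- bh_adjust(tab$p_empirical[tested])
    tab
  })
  detail <- dplyr::bind_rows(per_section)
  genes_summary <- detail |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      n_sections = dplyr::n(),
      n_testable = sum(!.data$skipped),
      mean_d_obs = mean(.data$d_obs[!.data$skipped]),
      max_q = if (all(!.data$skipped)) max(.data$q) else NA_real_,
      consistent = all(!.data$skipped) & all(.data$q <= alpha),
      .groups = "drop"
    ) |>
    dplyr::mutate(consistent = tidyr::replace_na(.data$consistent, FALSE))
  ranked <- genes_summary |>
    dplyr::filter(.data$consistent) |>
    dplyr::arrange(.data$mean_d_obs, .data$gene) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::select("gene", "rank")
  genes_summary <- dplyr::left_join(genes_summary, ranked, by = "gene") |>
    dplyr::arrange(.data$rank, .data$mean_d_obs, .data$gene)
  if (!any(genes_summary$n_testable > 0)) {
    rlang::warn("no testable genes in any section.")
  }
  structure(
    list(genes = genes_summary, per_section = detail, anchor = anchor,
         alpha = alpha, B = as.integer(B), top_fraction = top_fraction,
         null_mode = null_mode, seed = as.integer(seed)),
    class = "spatial_screen"
  )
}

#' @export
print.spatial_screen <- function(x, ...) {
  cat(sprintf(
    "<spatial_screen> anchor %s, %d gene(s) across %d section(s), B = %d\n",
    x$anchor, nrow(x$genes), dplyr::n_distinct(x$per_section$section_id),
    x$B
  ))
  cat(sprintf("consistent genes (q <= %g in every section): %d\n",
              x$alpha, sum(x$genes$consistent)))
  print(head(x$genes, 10), ...)
  invisible(x)
}

#' @export
tidy.spatial_screen <- function(x, ...) x$genes

#' @export
glance.spatial_screen <- function(x, ...) {
  tibble(
    n_genes = nrow(x$genes),
    n_testable = sum(x$genes$n_testable > 0),
    n_consistent = sum(x$genes$consistent),
    n_sections = dplyr::n_distinct(x$per_section$section_id),
    B = x$B, alpha = x$alpha, null_mode = x$null_mode
  )
}
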