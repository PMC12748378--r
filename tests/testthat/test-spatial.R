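# High-region masks, NN distances, permutation nulls, Spearman
# colocalization, geometric invariances, and the consistency screen.

square_section <- function(expr) {
  n <- ncol(expr)
  side <- ceiling(sqrt(n))
  grid <- expand.grid(x = seq_len(side), y = seq_len(side))[seq_len(n), ]
  spatial_section("sq", expr, data.frame(
    spot_id = colnames(expr), x = grid$x, y = grid$y
  ))
}

test_that("high-region masks follow the interpolated percentile rule", {
  expr <- rbind(G = c(1, 2, 3, 4))
  colnames(expr) <- paste0("t", 1:4)
  sec <- spatial_section("m", expr,
                         data.frame(spot_id = paste0("t", 1:4), x = 1:4,
                                    y = 0))
  m25 <- high_region_mask(sec, "G", 0.25)
  expect_equal(m25$threshold, 3.25)
  expect_equal(m25$spots, "t4")
  m50 <- high_region_mask(sec, "G", 0.5)
  expect_setequal(m50$spots, c("t3", "t4"))

  flat <- spatial_section("m", rbind(G = rep(2, 4)) |>
                            `colnames<-`(paste0("t", 1:4)),
                          data.frame(spot_id = paste0("t", 1:4), x = 1:4,
                                     y = 0))
  mf <- high_region_mask(flat, "G")
  expect_true(mf$skipped)
  expect_equal(mf$reason, "uninformative-distribution")

  expect_error(high_region_mask(sec, "ABSENT"),
               class = "ampcontext_input_error")
})

test_that("nearest-neighbor distances match brute force", {
  coords <- tibble::tibble(spot_id = paste0("s", 1:4),
                           x = c(0, 1, 0, 10), y = c(0, 0, 1, 10))
  mk <- function(spots) structure(list(gene = "g", section_id = "z",
                                       spots = spots, skipped = FALSE),
                                  class = "region_mask")
  # identity
  same <- nn_distance(mk(c("s1", "s2")), mk(c("s1", "s2")), coords)
  expect_equal(same$d_obs, 0)
  # 3-4-5 triangle
  coords2 <- tibble::tibble(spot_id = c("a", "b"), x = c(0, 3), y = c(0, 4))
  mk2 <- function(spots) structure(list(gene = "g", section_id = "z",
                                        spots = spots, skipped = FALSE),
                                   class = "region_mask")
  expect_equal(nn_distance(mk2("a"), mk2("b"), coords2)$d_obs, 5)
  # two-by-two brute force
  coords3 <- tibble::tibble(spot_id = c("p", "q", "r", "s"),
                            x = c(0, 1, 0, 5), y = c(0, 0, 1, 5))
  res <- nn_distance(mk(c("p", "q")), mk(c("r", "s")), coords3)
  expect_equal(unname(res$distances), c(1, sqrt(2)))
  expect_equal(res$d_obs, (1 + sqrt(2)) / 2)
  # cross-section masks are rejected
  other <- structure(list(gene = "g", section_id = "other",
                          spots = "s1", skipped = FALSE),
                     class = "region_mask")
  expect_error(nn_distance(mk("s1"), other, coords),
               class = "ampcontext_input_error")
})

test_that("one-sided Mann-Whitney matches its worked examples", {
  expect_equal(mwu_test(c(1, 2, 3), c(4, 5, 6)), 1 / 20)
  expect_equal(mwu_test(c(4, 5, 6), c(1, 2, 3)), 1)
  expect_gte(mwu_test(c(1, 2, 2, 5), c(1, 2, 2, 5)), 0.5)
  expect_error(mwu_test(numeric(0), 1), class = "ampcontext_input_error")
})

test_that("Spearman colocalization handles ties and degeneracy", {
  expr <- rbind(A = c(1, 2, 3, 4), B = c(2, 4, 6, 9),
                C = c(4, 3, 2, 1), D = c(1, 2, 2, 3), E = c(1, 3, 2, 4),
                F = rep(5, 4))
  colnames(expr) <- paste0("s", 1:4)
  sec <- spatial_section("t", expr, data.frame(
    spot_id = paste0("s", 1:4), x = 1:4, y = 1
  ))
  expect_equal(spearman_coloc(sec, "A", "B")$rho, 1)
  expect_equal(spearman_coloc(sec, "A", "C")$rho, -1)
  # hand-ranked oracle with average ranks
  r1 <- oracle_ranks(c(1, 2, 2, 3))
  r2 <- oracle_ranks(c(1, 3, 2, 4))
  expect_equal(spearman_coloc(sec, "D", "E")$rho,
               sum((r1 - mean(r1)) * (r2 - mean(r2))) /
                 sqrt(sum((r1 - mean(r1))^2) * sum((r2 - mean(r2))^2)))
  flat <- spearman_coloc(sec, "A", "F")
  expect_false(flat$defined)
  expect_true(is.na(flat$rho))
})

test_that("the 4-spot worked example gives the exhaustive p of 19/25", {
  sec <- tiny_section()
  res <- permutation_null(sec, "CCNE1", "TG", top_fraction = 0.25,
                          exhaustive = TRUE)
  expect_equal(res$d_obs, 1)
  expect_equal(res$p_empirical, 19 / 25)
})

test_that("empirical p respects its bounds and the +1 convention", {
  sec <- null_section(n_genes = 3, rows = 6, cols = 6, seed = 2)
  res <- permutation_null(sec, "CCNE1", "BG0001", B = 50, seed = 3)
  nulls <- attr(res, "null")
  expect_equal(res$p_empirical,
               (1 + sum(nulls <= res$d_obs + 1e-9)) / 51)
  expect_gte(res$p_empirical, 1 / 51)
  expect_lte(res$p_empirical, 1)
  expect_equal(length(nulls), 50)
})

test_that("permutation results are deterministic given the seed", {
  sec <- null_section(n_genes = 5, rows = 8, cols = 8, seed = 4)
  a <- permutation_null(sec, "CCNE1", "BG0002", B = 100, seed = 9)
  b <- permutation_null(sec, "CCNE1", "BG0002", B = 100, seed = 9)
  expect_identical(a, b)
  c <- permutation_null(sec, "CCNE1", "BG0002", B = 100, seed = 10)
  expect_false(identical(attr(a, "null"), attr(c, "null")))
})

test_that("value permutation preserves threshold and mask size", {
  # the fast null path relies on this multiset invariance
  set.seed(6)
  v <- rnbinom(40, mu = 3, size = 2)
  thr <- quantile(v, 0.75, type = 7, names = FALSE)
  m <- sum(v >= thr)
  for (i in 1:20) {
    vp <- sample(v)
    expect_equal(quantile(vp, 0.75, type = 7, names = FALSE), thr)
    expect_equal(sum(vp >= thr), m)
  }
})

test_that("statistics are invariant under rigid motions and scale", {
  sec <- null_section(n_genes = 4, rows = 7, cols = 7, seed = 5)
  transform_coords <- function(sec, f) {
    xy <- f(cbind(sec$coords$x, sec$coords$y))
    spatial_section(sec$section_id, sec$expr,
                    dplyr::mutate(sec$coords, x = xy[, 1], y = xy[, 2]))
  }
  base <- permutation_null(sec, "CCNE1", "BG0001", B = 80, seed = 7)
  # translation + rotation by 30 degrees
  th <- pi / 6
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  moved <- transform_coords(sec, function(xy) xy %*% rot + 100)
  res_m <- permutation_null(moved, "CCNE1", "BG0001", B = 80, seed = 7)
  expect_equal(res_m$d_obs, base$d_obs)
  expect_equal(res_m$p_empirical, base$p_empirical)
  expect_equal(spearman_coloc(moved, "CCNE1", "BG0001")$rho,
               spearman_coloc(sec, "CCNE1", "BG0001")$rho)
  # scaling by c multiplies distances by c, p unchanged
  scaled <- transform_coords(sec, function(xy) xy * 3.5)
  res_s <- permutation_null(scaled, "CCNE1", "BG0001", B = 80, seed = 7)
  expect_equal(res_s$d_obs, 3.5 * base$d_obs)
  expect_equal(res_s$p_empirical, base$p_empirical)
})

test_that("the screen finds a planted partner and excludes the anchor", {
  cfg <- spatial_config(rows = 15, cols = 15,
                        partners = data.frame(gene = "P1", strength = 3),
                        n_background_genes = 30, seed = 12)
  sec <- generate_spatial_section(cfg)
  scr <- genome_screen(sec, B = 999, seed = 12)
  expect_false("CCNE1" %in% scr$genes$gene)
  summary <- tidy(scr)
  expect_true(summary$consistent[summary$gene == "P1"])
  expect_equal(summary$gene[which(summary$rank == 1)], "P1")
  expect_s3_class(autoplot(scr), "ggplot")
})

test_that("an exchangeable section yields (almost) no consistent genes", {
  sec <- null_section(n_genes = 30, rows = 12, cols = 12, seed = 20)
  scr <- genome_screen(sec, B = 499, seed = 20)
  expect_lte(sum(tidy(scr)$consistent), 1)
})

test_that("skipped genes propagate and never count as consistent", {
  sec <- null_section(n_genes = 3, rows = 6, cols = 6, seed = 30)
  sec$expr["BG0002", ] <- 5 # constant: uninformative
  scr <- genome_screen(sec, B = 99, seed = 30)
  row <- dplyr::filter(scr$per_section, gene == "BG0002")
  expect_true(row$skipped)
  expect_equal(row$reason, "uninformative-distribution")
  expect_false(tidy(scr)$consistent[tidy(scr)$gene == "BG0002"])
})
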