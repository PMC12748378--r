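# QC, normalization, quartile group assignment, rank-sum DE, BH.

make_cm <- function(counts, ...) {
  meta <- tibble::tibble(cell_id = colnames(counts), ...)
  cell_matrix(counts, meta)
}

test_that("QC bounds are closed exactly where stated", {
  counts <- matrix(1L, nrow = 10000, ncol = 5,
                   dimnames = list(sprintf("g%05d", 1:10000), paste0("c", 1:5)))
  counts[50:10000, 1] <- 0L   # 49 detected -> removed
  counts[51:10000, 2] <- 0L   # 50 detected -> kept
  counts[9001:10000, 3] <- 0L # 9000 detected -> kept
  counts[9002:10000, 4] <- 0L # 9001 detected -> removed
  counts[101:10000, 5] <- 0L  # within bounds; tests the mito boundary
  cm <- make_cm(counts, mito_frac = c(0, 0, 0, 0, 0.15))
  kept <- suppressMessages(qc_filter(cm))
  expect_setequal(kept$cells$cell_id, c("c2", "c3", "c5"))

  # mito exactly 0.15 is retained; strictly above is removed
  cm2 <- make_cm(matrix(1L, 100, 2, dimnames = list(paste0("g", 1:100),
                                                    c("a", "b"))),
                 mito_frac = c(0.15, 0.1500001))
  expect_equal(suppressMessages(qc_filter(cm2))$cells$cell_id, "a")

  # idempotent
  once <- suppressMessages(qc_filter(cm))
  twice <- suppressMessages(qc_filter(once))
  expect_identical(as.matrix(once$counts), as.matrix(twice$counts))
})

test_that("log-normalization matches the stated transform", {
  counts <- matrix(c(100L, 0L), nrow = 2,
                   dimnames = list(c("g1", "g2"), "c1"))
  nm <- normalize_log(make_cm(counts))
  expect_equal(as.numeric(nm$counts[, "c1"]), c(log1p(10000), 0))

  # scale invariance: doubling a cell's counts leaves it unchanged
  set.seed(1)
  counts <- matrix(rpois(60, 5), nrow = 10,
                   dimnames = list(paste0("g", 1:10), paste0("c", 1:6)))
  counts[1, ] <- counts[1, ] + 1L # no zero-total cells
  nm1 <- normalize_log(make_cm(counts))
  nm2 <- normalize_log(make_cm(counts * 2L))
  expect_equal(as.matrix(nm1$counts), as.matrix(nm2$counts))

  # an all-zero gene stays all-zero
  counts[10, ] <- 0L
  expect_true(all(normalize_log(make_cm(counts))$counts[10, ] == 0))

  # zero-total cells are an error naming the cell
  counts0 <- counts; counts0[, 3] <- 0L
  expect_error(normalize_log(make_cm(counts0)), "c3",
               class = "ampcontext_input_error")
})

test_that("quartile assignment follows the closed type-7 convention", {
  # 8 epithelial cells with anchor values 1..8:
  # q25 = 2.75, q75 = 6.25 -> high = {7, 8}, low = {1, 2}
  counts <- rbind(CCNE1 = 1:8, OTHER = rep(5L, 8))
  colnames(counts) <- paste0("c", 1:8)
  cm <- make_cm(counts, sample = "s1", cell_type = "epithelial")
  ga <- assign_groups(cm, scaling = "lognorm")
  thr <- attr(ga, "thresholds")
  expect_equal(thr$q_low, 2.75)
  expect_equal(thr$q_high, 6.25)
  expect_setequal(ga$cell_id[ga$label == "high"], c("c7", "c8"))
  expect_setequal(ga$cell_id[ga$label == "low"], c("c1", "c2"))
  expect_setequal(ga$cell_id[ga$label == "excluded"],
                  paste0("c", 3:6))

  # the default z-score scaling is monotone, so membership is identical
  gz <- assign_groups(cm, scaling = "zscore")
  expect_equal(ga$label, gz$label)
})

test_that("degenerate and non-epithelial cells are excluded", {
  counts <- rbind(CCNE1 = rep(3L, 6), OTHER = 1:6)
  colnames(counts) <- paste0("c", 1:6)
  cm <- make_cm(counts, sample = "s1", cell_type = "epithelial")
  expect_warning(ga <- assign_groups(cm, scaling = "lognorm"),
                 "degenerate")
  expect_true(all(ga$label == "excluded"))

  counts2 <- rbind(CCNE1 = c(1L, 2L, 3L, 4L, 100L), OTHER = rep(1L, 5))
  colnames(counts2) <- paste0("c", 1:5)
  cm2 <- make_cm(counts2, sample = "s1",
                 cell_type = c(rep("epithelial", 4), "stromal"))
  ga2 <- assign_groups(cm2, scaling = "lognorm")
  expect_equal(ga2$label[ga2$cell_id == "c5"], "excluded")

  # < 4 epithelial cells in a sample: skipped with a warning
  cm3 <- make_cm(counts2[, 1:3], sample = "s1", cell_type = "epithelial")
  expect_warning(ga3 <- assign_groups(cm3, scaling = "lognorm"), "skipped")
  expect_true(all(ga3$label == "excluded"))
})

test_that("high/low groups take about a quarter of cells each", {
  set.seed(7)
  for (i in 1:5) {
    n <- sample(40:120, 1)
    counts <- rbind(CCNE1 = rpois(n, 20), OTHER = rpois(n, 5))
    colnames(counts) <- paste0("c", seq_len(n))
    cm <- make_cm(counts, sample = "s1", cell_type = "epithelial")
    ga <- assign_groups(cm, scaling = "lognorm")
    # within tie-induced slack of n/4
    expect_lt(abs(sum(ga$label == "high") - n / 4), n / 8 + 2)
    expect_lt(abs(sum(ga$label == "low") - n / 4), n / 8 + 2)
    # no high cell sits below its sample's q75
    thr <- attr(ga, "thresholds")
    expect_true(all(ga$scaled_value[ga$label == "high"] >= thr$q_high))
    expect_true(all(ga$scaled_value[ga$label == "low"] <= thr$q_low))
  }
})

test_that("identical groups give zero fold change and p = 1", {
  counts <- cbind(matrix(c(5L, 3L, 8L, 1L), 4), matrix(c(5L, 3L, 8L, 1L), 4))
  rownames(counts) <- paste0("g", 1:4)
  colnames(counts) <- paste0("c", 1:2)
  cm <- cell_matrix(counts, tibble::tibble(cell_id = colnames(counts)))
  assignment <- tibble::tibble(cell_id = c("c1", "c2"),
                               label = c("high", "low"))
  de <- differential_expression(cm, assignment, min_cells = 1)
  expect_true(all(de$avg_log2FC == 0))
  expect_true(all(de$p_value == 1))
})

test_that("a planted strong fold change passes; a moderate one does not", {
  fx <- labeled_groups(n_per_group = 200, log2fc = 3, seed = 2)
  nm <- normalize_log(fx$matrix)
  de <- differential_expression(nm, fx$assignment)
  shifted <- dplyr::filter(de, gene == "SHIFTED")
  expect_true(shifted$pass)
  expect_gt(shifted$avg_log2FC, 2)

  # a clearly significant but sub-threshold fold change fails the flag
  fx2 <- labeled_groups(n_per_group = 200, log2fc = 1.2, seed = 3)
  de2 <- differential_expression(normalize_log(fx2$matrix), fx2$assignment)
  shifted2 <- dplyr::filter(de2, gene == "SHIFTED")
  expect_lt(shifted2$p_adjusted, 0.05)
  expect_false(shifted2$pass)
})

test_that("empty groups are a grouping error", {
  fx <- labeled_groups(n_per_group = 5, seed = 1)
  bad <- dplyr::mutate(fx$assignment, label = "high")
  expect_error(differential_expression(fx$matrix, bad),
               class = "ampcontext_input_error")
})

test_that("rank-sum p matches enumeration exactly at small n, closely above", {
  # at the sizes where the implementation enumerates, it must equal an
  # independently coded enumeration oracle
  set.seed(13)
  for (i in 1:30) {
    nx <- sample(4:10, 1)
    ny <- sample(4:10, 1)
    x <- sample(1:6, nx, replace = TRUE) # heavy ties on purpose
    y <- sample(1:6, ny, replace = TRUE)
    p_less <- ampcontext:::ranksum_p(x, y, "less", exact_max = 10L)
    expect_equal(p_less, oracle_mwu_less(x, y))
  }
  # where the tie-corrected normal approximation takes over, it tracks a
  # one-off enumeration to within 0.02
  set.seed(14)
  for (i in 1:3) {
    x <- sample(1:8, 11, replace = TRUE)
    y <- sample(1:8, 11, replace = TRUE)
    p_norm <- ampcontext:::ranksum_p(x, y, "less", exact_max = 10L)
    p_enum <- ampcontext:::ranksum_p(x, y, "less", exact_max = 11L)
    expect_lt(abs(p_norm - p_enum), 0.02)
  }
})

test_that("BH adjustment follows the step-up definition", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(5)
  for (i in 1:20) {
    p <- runif(sample(1:10, 1))
    expect_equal(bh_adjust(p), oracle_bh(p))
    expect_true(all(bh_adjust(p) >= p)) # monotone inflation
  }
  expect_error(bh_adjust(c(0.5, 1.2)), class = "ampcontext_input_error")
})
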