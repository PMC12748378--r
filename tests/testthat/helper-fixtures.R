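# Fixtures and independent oracles shared across the suite. Every oracle
# here is written from the defining formula, independent of the package's
# own code paths.

# the 4-spot worked example: anchor high at the origin, test gene high
# one unit away, a far-off spot at (10, 10)
tiny_section <- function() {
  expr <- rbind(CCNE1 = c(4, 1, 1, 1), TG = c(1, 4, 1, 1))
  colnames(expr) <- paste0("s", 1:4)
  spatial_section(
    "tiny", expr,
    data.frame(spot_id = paste0("s", 1:4),
               x = c(0, 1, 0, 10), y = c(0, 0, 1, 10))
  )
}

# a section whose genes are all spatially exchangeable (no niche effect
# on any gene, anchor included)
null_section <- function(n_genes = 50, rows = 20, cols = 20, seed = 1,
                         id = "null") {
  cfg <- spatial_config(
    rows = rows, cols = cols, anchor_strength = 0,
    n_background_genes = n_genes, seed = seed
  )
  generate_spatial_section(cfg, section_id = id)
}

# cell matrix with direct high/low labels (bypassing anchor quartiles)
# and one gene shifted by a known log2 fold change
labeled_groups <- function(n_per_group = 200, base_mean = 20, log2fc = 3,
                           seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_group
  counts <- rbind(
    SHIFTED = rnbinom(n, mu = rep(c(base_mean * 2^log2fc, base_mean),
                                  each = n_per_group), size = 10),
    FLAT1 = rnbinom(n, mu = 30, size = 10),
    FLAT2 = rnbinom(n, mu = 5, size = 10),
    LIB = rnbinom(n, mu = 500, size = 10) # stabilises library sizes
  )
  colnames(counts) <- sprintf("c%03d", seq_len(n))
  cm <- cell_matrix(counts, data.frame(cell_id = colnames(counts)))
  assignment <- tibble::tibble(
    cell_id = colnames(counts),
    label = rep(c("high", "low"), each = n_per_group)
  )
  list(matrix = cm, assignment = assignment)
}

# --- independent oracles -------------------------------------------------

# average ranks computed by explicit sort-and-share, no call to rank()
oracle_ranks <- function(v) {
  r <- numeric(length(v))
  for (i in seq_along(v)) {
    r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
  }
  r
}

# exact one-sided rank-sum p for "a smaller", by enumeration of every
# C(n, na) assignment of the pooled values
oracle_mwu_less <- function(a, b) {
  pooled <- c(a, b)
  r <- oracle_ranks(pooled)
  na <- length(a)
  w_obs <- sum(r[seq_len(na)])
  subsets <- combn(length(pooled), na)
  sums <- apply(subsets, 2, function(s) sum(r[s]))
  mean(sums <= w_obs + 1e-9)
}

# step-up BH from the definition: q_(i) = min_{j >= i} p_(j) * m / j
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    cands <- vapply(i:m, function(j) p[o[j]] * m / j, numeric(1))
    q_sorted[i] <- min(1, min(cands))
  }
  out <- numeric(m)
  out[o] <- q_sorted
  out
}

# chi-square homogeneity statistic from the definition
oracle_chisq_stat <- function(mat) {
  e <- outer(rowSums(mat), colSums(mat)) / sum(mat)
  sum((mat - e)^2 / e)
}

# hypergeometric upper tail by exhaustive enumeration of query draws
oracle_hyper_tail <- function(k, K, n, N) {
  draws <- combn(N, n)
  in_set <- seq_len(K) # first K elements form the set
  mean(apply(draws, 2, function(d) sum(d %in% in_set) >= k))
}

# central binomial interval at the given coverage
binom_interval <- function(n, p, coverage = 0.99) {
  a <- (1 - coverage) / 2
  c(qbinom(a, n, p), qbinom(1 - a, n, p))
}
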