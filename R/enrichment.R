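# Database-agnostic overrepresentation analysis: hypergeometric upper-tail
# tests of a query gene list against user-supplied gene sets over a
# declared universe. No GO/KEGG release is bundled; any GMT works.

#' Gene set collection
#'
#' Named gene sets over a declared universe. The default universe is the
#' union of set members (the background is the analyst's choice and is
#' recorded on the object so every report can state it); set members
#' falling outside an explicit universe are dropped at construction.
#'
#' @param sets Named list of character vectors.
#' @param universe Optional explicit gene universe.
#' @return A `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, universe = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop_input("all gene sets must be named.")
  }
  if (anyDuplicated(names(sets))) stop_input("set names must be unique.")
  sets <- purrr::map(sets, function(s) unique(as.character(s)))
  universe_declared <- !is.null(universe)
  if (is.null(universe)) {
    universe <- sort(unique(unlist(sets, use.names = FALSE)))
  } else {
    universe <- unique(as.character(universe))
    sets <- purrr::map(sets, function(s) intersect(s, universe))
  }
  structure(
    list(sets = sets, universe = universe,
         universe_declared = universe_declared),
    class = "gene_set_collection"
  )
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf(
    "<gene_set_collection> %d set(s) over a universe of %d gene(s) (%s)\n",
    length(x$sets), length(x$universe),
    if (x$universe_declared) "declared" else "union of members"
  ))
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for the overlap `X` between a query of size `n` and a set
#' of size `K` drawn from a universe of size `N`, computed in log space
#' via the stable hypergeometric tail.
#'
#' @param k Observed overlap.
#' @param K Set size.
#' @param n Query size.
#' @param N Universe size.
#' @return Upper-tail probability in `(0, 1]`.
#' @export
#' @examples
#' hypergeom_tail(3, 5, 3, 10) # 10/120
hypergeom_tail <- function(k, K, n, N) {
  check_count(k, "k"); check_count(K, "K")
  check_count(n, "n"); check_count(N, "N")
  if (k > min(K, n) || K > N || n > N) {
    stop_input("need 0 <= k <= min(K, n) <= N.")
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Overrepresentation analysis of a query gene list
#'
#' One hypergeometric upper-tail test per set against the collection's
#' universe, Benjamini-Hochberg adjustment across all sets, significance
#' at adjusted p below `alpha`. The query is deduplicated and intersected
#' with the universe first; an empty intersected query is an error that
#' reports how many query genes fell outside the universe. The full table
#' is always returned — any "top 10 terms" truncation belongs to display
#' layers, not to the stored result.
#'
#' @param query Character vector of gene symbols.
#' @param collection A [gene_set_collection()].
#' @param alpha Significance threshold on the adjusted p (default 0.05).
#' @return Tibble sorted by `q` then `p` then set name: `set`, `k`
#'   (overlap), `K` (set size), `n` (query size in universe), `N`
#'   (universe size), `p`, `q`, `significant`.
#' @export
ora <- function(query, collection, alpha = 0.05) {
  if (!inherits(collection, "gene_set_collection")) {
    stop_input("`collection` must be a gene_set_collection.")
  }
  query <- unique(as.character(query))
  inside <- intersect(query, collection$universe)
  n_outside <- length(query) - length(inside)
  if (length(inside) == 0) {
    stop_input(sprintf(
      "query is empty after intersecting with the universe (%d gene(s) outside).",
      n_outside
    ))
  }
  if (n_outside > 0) {
    rlang::inform(sprintf(
      "ora: %d query gene(s) outside the universe were dropped.", n_outside
    ))
  }
  N <- length(collection$universe)
  n <- length(inside)
  rows <- purrr::imap(collection$sets, function(members, name) {
    K <- length(members)
    k <- length(intersect(inside, members))
    tibble(set = name, k = k, K = K, n = n, N = N,
           p = hypergeom_tail(k, K, n, N))
  })
  dplyr::bind_rows(rows) |>
    dplyr::mutate(q = bh_adjust(.data$p),
                  significant = .data$q < alpha) |>
    dplyr::arrange(.data$q, .data$p, .data$set)
}
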