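# Amplification calling, stratified rate estimation and co-alteration
# profiling from GISTIC-style per-gene call tables.

#' Call high-level amplification from a GISTIC-style copy-number value
#'
#' A gene is amplified when its discretized call is at or above +2
#' (high-level amplification); gains (+1), neutral (0) and deletions
#' (-1, -2) are not.
#'
#' @param call Integer vector of copy-number calls (-2..+2 convention).
#' @param cutoff Amplification cutoff, default `2`.
#' @return Logical vector.
#' @export
#' @examples
#' call_amplified(c(-2, 0, 1, 2))
call_amplified <- function(call, cutoff = 2L) {
  if (!is.numeric(call) || anyNA(call) || any(call != floor(call))) {
    stop_input("copy-number calls must be integers.")
  }
  call >= cutoff
}

#' Amplification rate for one stratum
#'
#' Exact percentage `100 * k / n` plus a 2-decimal presentation value
#' (round-half-to-even), matching how cohort studies print rates.
#'
#' @param k Amplified count.
#' @param n Stratum size; must be positive (a zero denominator is an
#'   error, never a silent 0).
#' @param stratum Optional stratum label.
#' @return One-row tibble: `stratum`, `k`, `n`, `rate_percent`,
#'   `rate_percent_2dp`.
#' @export
#' @examples
#' amplification_rate(122, 795, "uterine carcinosarcoma")
amplification_rate <- function(k, n, stratum = NA_character_) {
  check_count(k, "k")
  check_count(n, "n")
  if (n == 0) stop_input("undefined rate: stratum size n is 0.")
  if (k > n) stop_input("`k` cannot exceed `n`.")
  rate <- 100 * k / n
  tibble(
    stratum = as.character(stratum), k = as.integer(k), n = as.integer(n),
    rate_percent = rate, rate_percent_2dp = round2(rate)
  )
}

#' Stratified amplification rates with a between-stratum test
#'
#' Computes one amplification rate per stratum and a global test of rate
#' homogeneity on the strata x (amplified, not) contingency table:
#' chi-square without continuity correction, substituting Fisher's exact
#' test for 2x2 tables with any expected cell below 5 (for larger sparse
#' tables the chi-square is kept and a small-cell warning is issued).
#' Patients with a missing anchor call are excluded from numerator and
#' denominator, with the exclusion count reported.
#'
#' @param table Alteration table (see [generate_cohort()]).
#' @param anchor Anchor gene symbol; its call column is `cn_<anchor>`.
#' @param stratum_key Column (or columns) defining strata, e.g. `"site"`,
#'   `c("site", "histology")`, or `"sample_type"` for the
#'   primary-vs-metastatic comparison.
#' @param cutoff Amplification cutoff.
#' @return An object of class `amp_rate_test`; `tidy()` returns the
#'   per-stratum rates, `glance()` the test summary.
#' @export
stratified_rates <- function(table, anchor = "CCNE1", stratum_key = "site",
                             cutoff = 2L) {
  col <- paste0("cn_", anchor)
  if (!col %in% names(table)) {
    stop_input(sprintf("no call column `%s` in the table.", col))
  }
  missing_call <- is.na(table[[col]])
  n_excluded <- sum(missing_call)
  if (n_excluded > 0) {
    rlang::inform(sprintf(
      "excluding %d patient(s) with missing %s call.", n_excluded, anchor
    ))
  }
  tab <- table[!missing_call, , drop = FALSE]
  if (nrow(tab) == 0) stop_input("no patients with a non-missing call.")
  rates <- tab |>
    dplyr::mutate(.amp = call_amplified(.data[[col]], cutoff)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(stratum_key))) |>
    dplyr::summarise(k = sum(.amp), n = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(
      stratum = do.call(paste, c(dplyr::across(dplyr::all_of(stratum_key)),
                                 sep = "/")),
      rate_percent = 100 * .data$k / .data$n,
      rate_percent_2dp = round2(.data$rate_percent)
    ) |>
    dplyr::select(dplyr::all_of(stratum_key), "stratum", "k", "n",
                  "rate_percent", "rate_percent_2dp") |>
    dplyr::arrange(.data$stratum)
  if (nrow(rates) < 2) {
    test <- tibble(method = "not applicable (single stratum)",
                   statistic = NA_real_, df = NA_real_, p_value = NA_real_)
  } else {
    m <- cbind(amplified = rates$k, not_amplified = rates$n - rates$k)
    expected <- outer(rowSums(m), colSums(m)) / sum(m)
    small <- any(expected < 5)
    if (small && nrow(m) == 2) {
      ft <- stats::fisher.test(m)
      test <- tibble(method = "Fisher's exact test",
                     statistic = NA_real_, df = NA_real_,
                     p_value = ft$p.value)
    } else {
      if (small) {
        rlang::warn("expected cell count < 5; chi-square may be inaccurate.")
      }
      ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
      test <- tibble(method = "chi-square test of homogeneity",
                     statistic = unname(ct$statistic),
                     df = unname(ct$parameter),
                     p_value = ct$p.value)
    }
  }
  structure(
    list(rates = rates, test = test, anchor = anchor,
         stratum_key = stratum_key, n_excluded = n_excluded),
    class = "amp_rate_test"
  )
}

#' @export
print.amp_rate_test <- function(x, ...) {
  cat(sprintf("Amplification rates of %s by %s\n", x$anchor,
              paste(x$stratum_key, collapse = " x ")))
  print(x$rates, ...)
  cat(sprintf("%s: p = %.4g\n", x$test$method, x$test$p_value))
  invisible(x)
}

#' @export
tidy.amp_rate_test <- function(x, ...) x$rates

#' @export
glance.amp_rate_test <- function(x, ...) {
  dplyr::mutate(x$test, n_strata = nrow(x$rates),
                n_excluded = x$n_excluded)
}

#' Co-alteration frequencies among anchor-amplified cases
#'
#' Within the anchor-amplified subset, the frequency of co-amplification
#' (call at or above the cutoff) for every other `cn_` gene and of
#' pathogenic mutation for every `mut_` gene, sorted by descending
#' frequency with lexicographic tie-break. The anchor itself is excluded.
#'
#' @inheritParams stratified_rates
#' @return Tibble: `gene`, `event_class` (`"co-amplified"`/`"mutated"`),
#'   `count`, `denominator`, `frequency_percent`.
#' @export
coalteration_frequencies <- function(table, anchor = "CCNE1", cutoff = 2L) {
  col <- paste0("cn_", anchor)
  if (!col %in% names(table)) {
    stop_input(sprintf("no call column `%s` in the table.", col))
  }
  amp <- table[!is.na(table[[col]]) &
                 call_amplified(tidyr::replace_na(table[[col]], 0L), cutoff), ,
               drop = FALSE]
  if (nrow(amp) == 0) stop_input("no anchor-amplified cases in the table.")
  denom <- nrow(amp)
  cn_genes <- setdiff(sub("^cn_", "", grep("^cn_", names(table), value = TRUE)),
                      anchor)
  mut_genes <- sub("^mut_", "", grep("^mut_", names(table), value = TRUE))
  rows <- dplyr::bind_rows(
    purrr::map(cn_genes, function(g) {
      k <- sum(call_amplified(amp[[paste0("cn_", g)]], cutoff), na.rm = TRUE)
      tibble(gene = g, event_class = "co-amplified", count = k)
    }),
    purrr::map(mut_genes, function(g) {
      k <- sum(amp[[paste0("mut_", g)]], na.rm = TRUE)
      tibble(gene = g, event_class = "mutated", count = k)
    })
  )
  if (nrow(rows) == 0) {
    return(tibble(gene = character(0), event_class = character(0),
                  count = integer(0), denominator = integer(0),
                  frequency_percent = numeric(0)))
  }
  rows |>
    dplyr::mutate(denominator = denom,
                  frequency_percent = 100 * .data$count / denom,
                  frequency_percent_2dp = round2(.data$frequency_percent)) |>
    dplyr::arrange(dplyr::desc(.data$frequency_percent), .data$gene)
}
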