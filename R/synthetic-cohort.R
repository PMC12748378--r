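#' Configuration for a synthetic alteration cohort
#'
#' Describes a multi-stratum tumor cohort with known, planted amplification
#' structure: each stratum (tumor site x histology) has a fixed size and a
#' fixed per-patient probability that the anchor gene carries a high-level
#' amplification call (+2). Conditional co-mutation and co-amplification
#' probabilities plant co-alteration signal among anchor-amplified cases.
#'
#' The default strata reproduce the sizes and amplification rates of a
#' 12,845-patient gynecologic pan-site cohort (cervical, endometrial and
#' ovarian carcinomas with their histologic subtypes); the default
#' co-mutation block plants TP53/PIK3CA/PIK3R1 enrichment among amplified
#' cases. Conditional probabilities for non-amplified cases are stand-ins
#' (real cohorts publish only the amplified-case frequencies); see the
#' methods vignette.
#'
#' @param strata Data frame with columns `site`, `histology`, `n`
#'   (patients) and `p_amp` (anchor amplification probability in `[0, 1]`).
#' @param co_mutation Data frame with columns `gene`, `p_given_amp`,
#'   `p_given_not`: probability of a pathogenic mutation conditional on
#'   anchor amplification status.
#' @param co_amplification Optional data frame with the same columns as
#'   `co_mutation`, planting co-amplification (+2 calls) in other genes.
#' @param primary_fraction Fraction of samples labeled `"primary"` (the
#'   rest are `"metastatic"`).
#' @param anchor Anchor gene symbol; default `"CCNE1"`.
#' @param seed Integer RNG seed.
#' @return A `cohort_config` list, validated.
#' @seealso [generate_cohort()]
#' @export
#' @examples
#' cfg <- cohort_config(strata = data.frame(
#'   site = "ovary", histology = "HGSOC", n = 100, p_amp = 0.1
#' ))
#' cohort <- generate_cohort(cfg)
cohort_config <- function(strata = default_cohort_strata(),
                          co_mutation = default_co_mutation(),
                          co_amplification = NULL,
                          primary_fraction = 0.625,
                          anchor = "CCNE1",
                          seed = 1L) {
  strata <- as_tibble(strata)
  needed <- c("site", "histology", "n", "p_amp")
  if (!all(needed %in% names(strata))) {
    stop_config("`strata` needs columns site, histology, n, p_amp.")
  }
  check_count(strata$n, "strata$n")
  check_prob(strata$p_amp, "strata$p_amp")
  labels <- paste(strata$site, strata$histology, sep = "|")
  if (anyDuplicated(labels)) {
    stop_config("stratum (site, histology) labels must be unique.")
  }
  check_prob(primary_fraction, "primary_fraction")
  validate_conditional <- function(tab, what) {
    if (is.null(tab)) return(NULL)
    tab <- as_tibble(tab)
    if (!all(c("gene", "p_given_amp", "p_given_not") %in% names(tab))) {
      stop_config(sprintf(
        "`%s` needs columns gene, p_given_amp, p_given_not.", what
      ))
    }
    check_prob(tab$p_given_amp, paste0(what, "$p_given_amp"))
    check_prob(tab$p_given_not, paste0(what, "$p_given_not"))
    if (anyDuplicated(tab$gene)) {
      stop_config(sprintf("duplicate gene in `%s`.", what))
    }
    tab
  }
  structure(
    list(
      strata = strata,
      co_mutation = validate_conditional(co_mutation, "co_mutation"),
      co_amplification = validate_conditional(co_amplification,
                                              "co_amplification"),
      primary_fraction = primary_fraction,
      anchor = anchor,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' Default cohort strata
#'
#' Stratum sizes and anchor-amplification probabilities calibrated to the
#' printed per-subtype rates of a large gynecologic cohort (e.g. uterine
#' carcinosarcoma 122/795, ovarian high-grade serous 463/4703). The
#' low-grade serous stratum size is inferred from the site totals.
#'
#' @return Tibble with columns `site`, `histology`, `n`, `p_amp`.
#' @export
default_cohort_strata <- function() {
  tibble(
    site = c(rep("cervix", 3), rep("uterus", 4), rep("ovary", 6)),
    histology = c(
      "squamous", "adenocarcinoma", "adenosquamous",
      "endometrioid", "serous", "clear_cell", "carcinosarcoma",
      "HGSOC", "CCOC", "ENOC", "MOC", "carcinosarcoma", "LGSOC"
    ),
    n = c(434L, 331L, 51L, 3377L, 1204L, 198L, 795L,
          4703L, 509L, 369L, 187L, 281L, 406L),
    p_amp = c(3 / 434, 3 / 331, 0, 19 / 3377, 133 / 1204, 8 / 198,
              122 / 795, 463 / 4703, 13 / 509, 5 / 369, 1 / 187,
              35 / 281, 0)
  )
}

#' @rdname default_cohort_strata
#' @export
default_co_mutation <- function() {
  # amplified-case frequencies follow the pooled printed values; the
  # non-amplified conditionals are stand-ins chosen well below them
  tibble(
    gene = c("TP53", "PIK3CA", "PIK3R1"),
    p_given_amp = c(0.7146, 0.1429, 0.0584),
    p_given_not = c(0.35, 0.10, 0.03)
  )
}

#' Generate a synthetic cohort alteration table
#'
#' Draws one row per patient. The anchor gene's GISTIC-style call is +2
#' with the stratum's configured probability and 0 otherwise; mutation
#' flags (and optional co-amplifications) are drawn from conditional
#' probabilities given anchor amplification status. Each stratum uses a
#' deterministic sub-stream of the global seed, so adding a stratum does
#' not perturb the others.
#'
#' @param config A [cohort_config()].
#' @return A tibble with columns `patient_id`, `site`, `histology`,
#'   `sample_type`, one `cn_<gene>` integer call column per gene and one
#'   `mut_<gene>` logical column per co-mutation gene.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    stop_config("`config` must be created by cohort_config().")
  }
  strata <- config$strata
  rows <- purrr::pmap(
    strata,
    function(site, histology, n, p_amp) {
      n <- as.integer(n)
      label <- paste(site, histology, sep = "|")
      with_seed(substream_seed(config$seed, label), {
        amp <- if (n > 0) stats::rbinom(n, 1L, p_amp) == 1L else logical(0)
        out <- tibble(
          patient_id = sprintf("%s_%s_%04d", site, histology, seq_len(n)),
          site = rep(site, n),
          histology = rep(histology, n),
          sample_type = ifelse(
            stats::runif(n) < config$primary_fraction, "primary", "metastatic"
          )
        )
        out[[paste0("cn_", config$anchor)]] <- ifelse(amp, 2L, 0L)
        if (!is.null(config$co_amplification)) {
          for (i in seq_len(nrow(config$co_amplification))) {
            g <- config$co_amplification$gene[i]
            p <- ifelse(amp, config$co_amplification$p_given_amp[i],
                        config$co_amplification$p_given_not[i])
            out[[paste0("cn_", g)]] <-
              ifelse(stats::runif(n) < p, 2L, 0L)
          }
        }
        if (!is.null(config$co_mutation)) {
          for (i in seq_len(nrow(config$co_mutation))) {
            g <- config$co_mutation$gene[i]
            p <- ifelse(amp, config$co_mutation$p_given_amp[i],
                        config$co_mutation$p_given_not[i])
            out[[paste0("mut_", g)]] <- stats::runif(n) < p
          }
        }
        out
      })
    }
  )
  dplyr::bind_rows(rows)
}
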