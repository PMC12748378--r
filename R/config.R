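#' Pipeline configuration and fixed analysis constants
#'
#' Central home for the analysis constants used across the pipeline:
#' the GISTIC call cutoff for high-level amplification (+2), the closed
#' quartile bounds for marker-high/low cell stratification (0.25 / 0.75),
#' the differential-expression thresholds (|avg_log2FC| > 2, adjusted
#' p < 0.05), the spatial high-region top fraction (0.25), the number of
#' permutations for the spatial null (1000) and the global significance
#' level (0.05). Override only with reason; downstream functions take
#' these as defaults.
#'
#' @param anchor Anchor gene symbol.
#' @param amp_call_cutoff Integer call at or above which a gene is
#'   amplified.
#' @param quartile_low,quartile_high Closed percentile bounds for the
#'   low/high expression groups.
#' @param deg_log2fc Absolute avg_log2FC threshold for a DEG pass flag.
#' @param deg_alpha Adjusted-p threshold for a DEG pass flag.
#' @param top_fraction Fraction of spots forming a spatial high region.
#' @param permutations Number of null permutations (B >= 1).
#' @param alpha Global significance level.
#' @param seed Integer seed.
#' @param output_dir Where result tables are written, when requested.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(anchor = "CCNE1",
                            amp_call_cutoff = 2L,
                            quartile_low = 0.25,
                            quartile_high = 0.75,
                            deg_log2fc = 2,
                            deg_alpha = 0.05,
                            top_fraction = 0.25,
                            permutations = 1000L,
                            alpha = 0.05,
                            seed = 1L,
                            output_dir = NULL) {
  check_prob(quartile_low, "quartile_low")
  check_prob(quartile_high, "quartile_high")
  if (quartile_low >= quartile_high) {
    stop_config("`quartile_low` must be below `quartile_high`.")
  }
  if (top_fraction <= 0 || top_fraction >= 1) {
    stop_config("`top_fraction` must be in (0, 1).")
  }
  if (permutations < 1) stop_config("`permutations` must be >= 1.")
  check_prob(alpha, "alpha")
  check_prob(deg_alpha, "deg_alpha")
  structure(
    list(anchor = anchor, amp_call_cutoff = as.integer(amp_call_cutoff),
         quartile_low = quartile_low, quartile_high = quartile_high,
         deg_log2fc = deg_log2fc, deg_alpha = deg_alpha,
         top_fraction = top_fraction,
         permutations = as.integer(permutations), alpha = alpha,
         seed = as.integer(seed), output_dir = output_dir),
    class = "pipeline_config"
  )
}
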