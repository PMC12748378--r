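# ampcontext

Amplification-context profiling for an anchor oncogene — by default
**CCNE1** (cyclin E1, 19q12) — across three data modalities of gynecologic
tumor studies:

1. **Cohort copy-number tables** (GISTIC-style per-gene calls from panels
   such as AACR GENIE extracts): stratified amplification rates with
   between-stratum tests, and co-alteration frequencies among
   anchor-amplified cases.
2. **Single-cell RNA-seq counts**: QC, log-normalization, per-sample
   quartile stratification of epithelial cells into anchor-high /
   anchor-low groups, and Wilcoxon rank-sum differential expression.
3. **Spatial transcriptomics sections**: high-expression region masks,
   nearest-neighbor Euclidean proximity to anchor-high regions,
   expression-permutation null distributions, and a genome-wide screen
   for genes consistently colocalized with the anchor.

A database-agnostic overrepresentation stage (hypergeometric tests on
user-supplied GMT gene sets) closes the loop from differential genes to
pathways, and synthetic-data generators with planted ground truth make
every stage testable end to end without any external download.

## The statistics at the core

**Amplification calling and rates.** A gene is amplified when its
discretized copy-number call satisfies `call ≥ +2`. For a stratum with
`k` amplified of `n` patients the rate is `100·k/n` (exact, plus a
2-decimal round-half-to-even presentation value). Between-stratum
homogeneity is tested by the chi-square test on the strata × {amplified,
not} table (Fisher's exact test for sparse 2×2 tables).

**Quartile stratification.** Within each sample's epithelial cells, the
anchor's log-normalized expression is z-scored; cells at or above the
75th percentile (type-7 linear interpolation) are *high*, at or below the
25th are *low*, intermediates are excluded. Differential expression uses
a two-sided rank-sum test per gene with BH correction, and
`avg_log2FC = log2((mean_high + 1)/(mean_low + 1))` on de-logged
normalized expression; a gene *passes* at `|avg_log2FC| > 2` and adjusted
`p < 0.05`.

**Spatial proximity.** For a section with spot coordinates, a gene's high
region is the top 25% of spots by expression. The proximity statistic is

```
D_obs = mean over test-high spots of the Euclidean distance
        to the nearest anchor-high spot
```

The null permutes the test gene's expression values across spots
(preserving the expression distribution) with the anchor region held
fixed; the empirical p is `(1 + #{D_b ≤ D_obs}) / (1 + B)`, with a
one-sided Mann–Whitney comparison of observed vs pooled null distances
as a secondary statistic. The genome-wide screen adjusts empirical
p-values by BH within each section and flags genes *consistent* when
`q ≤ α` in every section, ranking them by mean `D_obs`.

**Overrepresentation.** For a query of `n` genes in a universe of `N`,
overlap `k` with a set of size `K` is scored by the hypergeometric upper
tail `P(X ≥ k)`, BH-adjusted across sets.

## Worked example

```r
library(ampcontext)

# a 12,845-patient synthetic cohort calibrated to published
# per-histology amplification rates
cohort <- generate_cohort(cohort_config(seed = 1))
stratified_rates(cohort, anchor = "CCNE1", stratum_key = "site")
#> Amplification rates of CCNE1 by site
#> # A tibble: 3 × 6
#>   site   stratum     k     n rate_percent rate_percent_2dp
#>   <chr>  <chr>   <int> <int>        <dbl>            <dbl>
#> 1 cervix cervix      5   816        0.613             0.61
#> 2 ovary  ovary     483  6455        7.48              7.48
#> 3 uterus uterus    268  5574        4.81              4.81
#> chi-square test of homogeneity: p = 1.304e-18

# a spatial section with one gene planted to colocalize with the anchor
cfg <- spatial_config(rows = 15, cols = 15,
                      partners = data.frame(gene = "ARHGAP1", strength = 3),
                      n_background_genes = 30, seed = 1)
section <- generate_spatial_section(cfg)
genome_screen(section, anchor = "CCNE1", B = 999, seed = 1)
#> <spatial_screen> anchor CCNE1, 31 gene(s) across 1 section(s), B = 999
#> consistent genes (q <= 0.05 in every section): 1
#> # A tibble: 10 × 7
#>    gene    n_sections n_testable mean_d_obs max_q consistent  rank
#>    <chr>        <int>      <int>      <dbl> <dbl> <lgl>      <int>
#>  1 ARHGAP1          1          1      0.563 0.031 TRUE           1
#>  2 BG0006           1          1      1.05  0.682 FALSE         NA
#>  # ...
```

The cohort rates recover the stratum-level probabilities the generator
was configured with (per-site rates are weighted averages of the
subtype strata); the screen flags the planted partner — and only it —
as consistently proximal to the CCNE1-high region, ranked first by mean
nearest-neighbor distance.

Each result type has a plot: `autoplot()` on rate and screen objects,
`plot_deg_volcano()` for differential expression, `plot_spatial_gene()`
for section maps; `tidy()`/`glance()` return tibbles for downstream use.

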