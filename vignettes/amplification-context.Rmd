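---
title: "Methods: profiling the context of an anchor-gene amplification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: profiling the context of an anchor-gene amplification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampcontext)
```

`ampcontext` implements a three-modality analysis of what surrounds a
high-level amplification of an anchor oncogene (CCNE1 by default) in
gynecologic tumors: cohort-level amplification and co-alteration rates,
single-cell quartile stratification with rank-sum differential
expression, and a spatial colocalization screen with permutation nulls.
This vignette is the package's own account of the statistical choices
involved — what is modeled, which knobs exist, and which conventions were
fixed where more than one defensible option existed.

## Cohort model

The cohort stage treats each patient as one row carrying a discretized
per-gene copy-number call in `{-2, …, +2}` and per-gene pathogenic
mutation flags. A call of `+2` or more is a high-level amplification;
everything below is not. Stratum rates are plain binomial proportions
`100·k/n`, reported exactly and with 2-decimal round-half-to-even
presentation (the convention that reproduces every published rate this
package ships as calibration defaults, e.g. `463/4703 → 9.84`).

Rate homogeneity across strata is tested with the chi-square test on the
strata × {amplified, not} contingency table, without continuity
correction. For 2×2 tables with any expected cell below 5, Fisher's exact
test is substituted; larger sparse tables keep the chi-square with a
warning, because exact tests on r×2 tables grow combinatorially and the
cohort sizes this stage targets rarely need them. Patients missing the
anchor call are dropped from numerator and denominator, and the count of
exclusions is reported — a silent zero would bias rates downward.

The primary-versus-metastatic comparison is the same machinery with
`stratum_key = "sample_type"`; no separate code path exists.

## Single-cell stratification

Cells pass QC when the detected-gene count lies in `[50, 9000]`
(inclusive) and the mitochondrial fraction is at most 0.15 — only cells
*strictly* above 15% are removed. Normalization is counts per 10,000
with `log(1+x)`. Cells with zero totals are an error by design: they
indicate an upstream filtering bug, not data to be silently dropped.

Group assignment works within each sample's epithelial cells:
the anchor's log-normalized expression is z-scored within the sample
("scaled" expression), and cells at or above the 75th percentile are
`high`, at or below the 25th `low`, intermediates `excluded`. Both
bounds are closed. Percentiles use linear interpolation (R's default
type 7), so the 8-cell example with values 1…8 gives `q25 = 2.75`,
`q75 = 6.25`, high = top two cells, low = bottom two. Samples with fewer
than four epithelial cells, or with a degenerate (constant) anchor
distribution, are skipped with a warning rather than force-assigned.
Scaling is configurable (`"zscore"` or raw `"lognorm"`): z-scoring makes
quartiles comparable across samples with different capture depth, which
is why it is the default; the quartile memberships are identical under
any monotone scaling within a sample, so the choice only matters if
thresholds are compared across samples. A global (cross-sample) quartile
mode exists as an option but is not the default.

Differential expression between high and low cells uses a two-sided
Wilcoxon rank-sum test per gene. `avg_log2FC` is computed as
`log2((mean_high + 1) / (mean_low + 1))` where the means are taken on
de-logged normalized expression (`expm1` of the log values, i.e. counts
per 10k). Taking means of the *log* values instead would put a log
inside a log: a planted 8-fold expression shift then measures ~0.3 and
the conventional `|avg_log2FC| > 2` pass threshold becomes unreachable
by construction. The pseudocount of 1 in numerator and denominator
bounds fold changes when a group mean is near zero. A gene is tested
only if detected in at least 3 cells across both groups (the rank test
is degenerate below that), and passes when `|avg_log2FC| > 2` and the
BH-adjusted p is below 0.05. The fold-change threshold is unusually
strict for scRNA-seq practice; it is exposed as a parameter
(`log2fc_threshold`) rather than hard-coded.

### Exact versus approximate rank-sum p-values

When both groups have at most 10 observations the rank-sum p comes from
exhaustive enumeration of all `C(n, n₁)` assignments of the pooled
(average-rank) values, which remains valid under ties. Larger groups use
the tie-corrected normal approximation without continuity correction.
The switchover exists because no normal approximation is uniformly
accurate at such sizes: under heavy ties at `n ≤ 10` its error can reach
the same order as the p-value itself, while at the first sizes where the
approximation is actually used (11 per group and above) the test suite
verifies agreement with one-off enumeration to within 0.02. The
one-sided Mann–Whitney variant used by the spatial module enumerates up
to 8 per group for the same reason.

## Spatial colocalization

A gene's *high region* in a section is the top 25% of spots by
expression: threshold at the 75th percentile (type 7), membership with a
closed bound. If the threshold equals the gene's minimum the mask would
be the whole section, so the gene is marked *skipped* with reason
`uninformative-distribution` — assigning such genes `p = 1` instead
would quietly dilute BH correction with meaningless tests. This skip
naturally catches genes expressed in fewer than 25% of spots whose
75th percentile is zero.

The proximity statistic is the mean, over the test gene's high spots, of
the Euclidean distance to the nearest anchor-high spot. It is
directional by choice: "how close are this gene's hotspots to the
anchor's region" is the question the screen asks, and the directional
mean responds monotonically to planted colocalization. A symmetric
variant (max of both directions) can be built from two `nn_distance()`
calls. Spot `x, y` positions are authoritative; array row/col indices
are carried for reporting only.

### The null model

The null permutes the **test gene's expression values across spots**,
keeping the anchor mask fixed. The literal alternative — permuting
coordinates jointly for all genes — preserves the spot-level coupling
between genes, so a gene expressed in exactly the anchor's spots could
never be rejected against it; that mode is retained behind
`null_mode = "coordinates"` for comparison but is not the default.
Because a value permutation preserves the value multiset, the
75th-percentile threshold and hence the mask *size* are invariant; the
null mask is exactly a uniform random subset of spots of the observed
mask's size. The implementation exploits this: per-spot
nearest-anchor distances are computed once, and each null draw samples a
subset and averages (a compiled kernel; a unit test pins the
multiset-invariance argument). The empirical p uses the
`(1 + #{D_b ≤ D_obs}) / (1 + B)` convention so it is never zero and is
uniformly distributed on its attainable grid under the null. A one-sided
Mann–Whitney test of observed per-spot distances against pooled null
distances is reported as a secondary column; the pooled null is capped
at 10,000 values (a deterministic subsample) since ranking half a
million distances per gene changes nothing statistically.

### The consistency screen and the choice of B

`genome_screen()` runs the permutation test for every informative
non-anchor gene in every section, BH-adjusts empirical p-values within
each section, and flags a gene consistent when it was testable in
*every* section and `q ≤ α` in all of them; consistent genes are ranked
by mean `D_obs`. Each (section, gene) pair derives its RNG sub-stream by
a stable hash, so results are independent of iteration order and of
which other genes are present.

`B` deserves care: with `m` testable genes, the smallest attainable
empirical p is `1/(B+1)`, and a lone true positive needs
`m/(B+1) ≤ α` to survive BH. Screening ~200 genes at `α = 0.05`
therefore needs `B ≥ 4000`; the package's planted-recovery checks use
`B = 4999`. A screen run with the conventional `B = 1000` cannot
single out one gene among hundreds — if it appears to, the discovery is
being carried by co-significant company, not by its own p-value floor.

## Overrepresentation

The ORA stage is deliberately database-free: it consumes any GMT file.
The hypergeometric upper tail `P(X ≥ k)` is computed via the stable
log-space tail, BH-adjusted across all sets of the collection.
The default universe is the union of set members, because no background
was declared by the analyses this stage generalizes; the choice is
recorded on the collection object and callers can declare an explicit
universe, which also clips set members. Only overrepresentation is
tested (one-sided); "top 10 terms" is treated as a display concern and
never truncates stored results.

## What the generators emulate — and what they do not

The synthetic cohort reproduces stratum sizes and per-stratum
amplification probabilities of a 12,845-patient gynecologic cohort
(13 site × histology strata), a 62.5% primary-sample fraction, and
conditional co-mutation probabilities among amplified cases. The
conditional probabilities for *non-amplified* cases are stand-ins —
published analyses report only amplified-case frequencies — and are
chosen well below the amplified-case values so that planted enrichment
is detectable. Panel heterogeneity, missing-call patterns, and
within-stratum correlation are not modeled.

The cell and spatial generators use negative-binomial counts
(per-gene mean, shared dispersion; `dispersion = 0` degrades to
Poisson, `noise = "none"` gives the exact mean surface). NB is the
standard overdispersion convention for counts, and the downstream tests
are rank-based, so only ordinal structure matters. Planted effects act
multiplicatively on the mean (`2^strength`), keeping log2 effects
interpretable. Cells: a fixed epithelial fraction per sample, with the
first `high_subpop_fraction` of epithelial cells carrying the anchor
shift and the planted DEGs; mitochondrial fractions are Beta-distributed
metadata, deliberately independent of the counts. Spatial: spots on an
integer grid with a circular niche; anchor and partner genes are
elevated inside it, background genes are exchangeable. Real tissue has
correlated gene programs, segmentation artifacts, spatially varying
capture efficiency, and non-circular niches; passing tests on these
generators shows the *statistics* behave as designed (calibration,
recovery, invariances), not that any biological conclusion transfers.

One geometric consequence worth knowing: a planted partner's high region
can equal the niche only if the niche covers at least the top fraction
of spots. Default geometry (radius = max-dimension/4 on a square grid,
~20% of spots) sits near that boundary on purpose — with count noise the
mask mixes niche and background spots, which is the realistic regime for
the screen; the noise-free identity check uses a larger radius.

Every generator call takes one seed and derives per-stratum / per-sample
/ per-(section, gene) sub-streams by stable hashing, so adding a unit
never perturbs the data of existing units.

## Problem sizes used by the test suite

The statistical checks run at sizes chosen to give the assertions real
power while keeping a laptop test run comfortable: calibration on
20 exchangeable 400-spot sections of 50 genes at `B = 200` (the
rejection fraction at 0.05 is checked against the exact binomial 99%
envelope); planted-partner recovery over 20 seeds of 400-spot sections
with 200 background genes at `B = 4999` (≥ 90% recovery required, and
the no-signal arm must be clean in ≥ 18 of 20); Monte-Carlo-versus-
exhaustive agreement at `B = 10,000` on sections of ≤ 6 spots; and a
500-gene global-null differential expression run with 200 cells per
group, which must produce zero pass flags and a near-uniform raw p
distribution.

## Known limitations

- Mutation flags are taken as given; no variant-level pathogenicity
  classification is performed.
- The spatial stage accepts already-normalized expression and does not
  implement variance-stabilizing normalization; a log-CPM fallback via
  `normalize_log()` is available for raw counts.
- Batch integration, clustering, embedding, cell-type annotation,
  ligand–receptor inference, immune deconvolution and tumor mutational
  burden are out of scope; epithelial labels arrive as metadata.
- The empirical p's resolution is `1/(B+1)`; multi-hundred-gene screens
  need `B` in the thousands (see above), which is the main runtime cost.
- With heavy ties in small groups, rank-based p-values are discrete;
  exact enumeration keeps them valid but they remain conservative.
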