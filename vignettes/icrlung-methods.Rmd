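---
title: "Methods: immune-class assignment and benefit association in icrlung"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: immune-class assignment and benefit association in icrlung}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icrlung)
```

## The problem

Anti-PD1/PDL1 checkpoint inhibitors benefit only a minority of advanced
non-small cell lung cancer (NSCLC) patients, and PDL1 immunohistochemistry is
an imperfect selector. A candidate transcriptomic biomarker is the
Immunologic Constant of Rejection (ICR): a 20-gene panel covering Th1
signaling (*IFNG*, *TBX21*, *CD8A/B*, *IL12B*, *STAT1*, *IRF1*), Th1
chemoattraction (*CXCL9*, *CXCL10*, *CCL5*), cytotoxic effector function
(*GNLY*, *PRF1*, *GZMA/B/H*) and counter-regulatory checkpoints (*CD274*,
*PDCD1*, *IDO1*, *CTLA4*, *FOXP3*). Tumors are partitioned into four classes
ICR1 (immune-cold) through ICR4 (immune-hot), and the collapsed contrast
ICR2-4 vs ICR1 is tested for association with Durable Clinical Benefit
(DCB: stable disease or objective response under RECIST 1.1 maintained at
least six months from the start of checkpoint inhibition) and, separately,
with disease-free survival in patients never exposed to checkpoint
inhibitors.

`icrlung` implements that full analysis chain — nCounter-style count
normalization, per-cohort harmonization, the consensus-clustering
classifier, companion-signature scoring, association statistics and
survival analysis — plus a synthetic multi-cohort generator so every stage
is testable without patient data.

## Expression processing

**nCounter-style normalization** (`subtract_background()`,
`normalize_geomean()`, `to_log2()`): per sample, the background is the
geometric mean of the eight negative-control probes and is subtracted from
endogenous counts; counts are then rescaled so each sample's geometric mean
over the 46 reference probes (40 housekeeping + 6 positive controls) equals
the cohort average of those geometric means; finally values move to
log2(count + 1). Three numerical choices the upstream convention leaves
open are fixed here and configurable:

* post-subtraction floor = 1 count (keeps log2 finite; 0 supported),
* zero negative-control counts: the geometric mean is computed on
  counts + 1 and 1 is subtracted, avoiding collapse of the background
  estimate to zero,
* log2 offset = 1.

Exact scale-equivariance (multiplying one sample's raw counts by a constant
leaves its normalized values unchanged) holds for the fixed-reference
variant of `normalize_geomean()`; under the default "mean of per-sample
geometric means" reference the common target moves too, shifting all
samples by a shared constant. The tests assert the fixed-reference form.

**Harmonization** (`quantile_normalize()`, `standardize_gene()`): each
cohort is quantile-normalized separately; tied values receive the mean of
the quantile values of their tied ranks (the convention matches
`limma::normalizeQuantiles(ties = TRUE)`, against which it is tested). PDL1
(*CD274*) is z-scored within cohort (n−1 denominator) before pooling.
Nothing else crosses cohort boundaries as expression: classification,
scoring and binarization all run per cohort, and only labels and scores are
pooled (`pool_datasets()` enforces schema identity and unique patient IDs).
Duplicate probes collapse to gene symbols by mean.

## The consensus-clustering classifier

`consensus_cluster()` re-implements resampling-based consensus clustering:
5000 repetitions by default, each drawing 80% of samples without
replacement (`pItem = 0.8`), inner agglomerative clustering with the
Ward.D2 criterion cut at k = 4, co-clustering and co-sampling counts
accumulated per sample pair, and final labels from complete-linkage
("outer") clustering of 1 − consensus. Decisions where the upstream
description is silent:

* **Inner distance**: Euclidean on the 20-gene sample vectors (the metric
  under which the Ward criterion is defined); 1 − Pearson available via
  `inner_distance = "pearson"`. The choice is recorded in the result's
  config.
* **Ward semantics**: Ward.D2, i.e. the Lance–Williams update applied with
  the D2 convention to unsquared input distances. A brute-force test
  verifies the inner merges against exhaustive minimization of the
  within-cluster sum-of-squares increase at n ≤ 8 — the ward.D/ward.D2
  distinction silently changes clusters, so it is pinned by test.
* **Resampling**: items only (no gene resampling); one random stream seeded
  from the config drives all repetitions; subsets are drawn by index on the
  *sorted* sample-ID order, making results invariant to input column order.
* **Never co-sampled pairs** (conceivable only at very low repetition
  counts): consensus entry 0.5 (maximally uncertain), count retained.
* **No gene scaling** before clustering (after quantile normalization);
  configurable upstream of the call.

Cluster naming: the per-sample ICR score is the mean of the 20 panel genes'
log2 values, and clusters are renamed ICR1..ICR4 in ascending order of
within-cluster mean score (`assign_icr_labels()`). This ordering rule is an
assumption — the published figure orders classes along increasing score but
states no rule. Ties break by cluster size, then lowest original index,
with a message. k is fixed at 4 by design; `k = 2` runs produce the same
report schema.

## Companion signatures

`score_panel()` computes unweighted metagene means for every set in the
shipped GMT database: 28 immune cell-subset metagenes (Bindea-style),
IFN-α/IFN-γ/TNF-α and TP53 pathway-activation scores, the antigen
processing and presentation machinery score (APM), the 18-gene T
cell-inflamed signature (TIS) and the 12-chemokine tertiary lymphoid
structure signature (TLS). **The cell-subset and pathway member lists are
curated surrogates** reconstructed from public descriptions of the cited
signatures — the source study reprints none of them — and are deliberately
user-replaceable (any GMT passes through `read_gmt()`). TIS is unweighted
by default; a weights file upgrades it to the published weighted form.
The cytolytic activity score is the log2 geometric mean of *GZMA* and
*PRF1*. The Th1/Th2 ratio is the difference of the two metagenes in log2
domain.

Binarization of the comparator predictors (TIS, TLS, standardized PDL1)
uses the first within-cohort quintile: scores ≤ the 20th percentile are
"low", the rest "high"; ties at the cut all go low. Whether the source
study cut quintiles per cohort or on the pooled population is unstated;
per-cohort is the default here (consistent with every other per-cohort
step), and pooled cuts are available by passing a single cohort label.
All-equal scores make the cut meaningless and are refused rather than
forced.

## Association statistics

* `odds_ratio_wald()`: OR with Wald CI; Haldane–Anscombe +0.5 on zero
  cells, flagged. Wald (not profile) intervals are a validated choice: on
  the published counts they reproduce both printed intervals (1.64–19.51
  and 0.35–29.01) exactly at printed rounding.
* `fisher_exact()`: true exact enumeration for 2 × k tables under the
  multivariate hypergeometric with probability-mass ordering for the
  two-sided p (the common convention; twice-one-sided differs and is not
  used). Degenerate margins give p = 1, flagged. The 2 × 2 case is tested
  exhaustively against a closed-form hypergeometric oracle for all tables
  with n ≤ 40. Note: on the reconstructed four-class DCB table the printed
  "exact" p of 2.67E-02 is reproduced by Pearson's chi-square, while
  genuine enumeration gives 0.0154 — the tests document both.
* `logistic_fit()`: IRLS from zero slopes with the intercept at the logit
  of the mean outcome; convergence at max |score| < 1e-8 or 25 iterations;
  Wald SEs from the inverse observed information; separation is flagged,
  never silent. On a saturated single-binary-predictor model it reproduces
  `odds_ratio_wald()` to 6 significant figures, and it is tested against
  `glm()` on multivariate designs. The univariate screen enters variables
  into the multivariate model at p < 0.05 (configurable).
* `homogeneity_test()`: Cochran's Q on per-cohort log-ORs with
  inverse-variance weights (the fixed-effects homogeneity statistic; the
  alternative Breslow–Day test is not implemented), +0.5 correction per
  table with zero cells.
* `anova_oneway()`: classical F decomposition for class-wise score
  comparisons.
* No multiple-testing correction is applied anywhere (matching the source
  analysis); all p-values are nominal.

## Survival

`km_estimate()` is the product-limit estimator with Greenwood variance; the
CI is computed on log S with symmetric normal quantiles and truncated to
[0, 1] (the source does not state its CI method; this matches
`survfit(conf.type = "log")`, against which it is tested). Deaths precede
censorings at tied times. `logrank_test()` uses the (g−1)-dimensional
observed-minus-expected score vector with its hypergeometric covariance.
The published TCGA numbers (67% 5-year DFS, log-rank p = 0.782) require
external TCGA data and are out of scope; the survival module's contract is
the null-behavior property: class-independent synthetic survival yields
non-significant log-rank results at the nominal rate.

## The synthetic world

`sim_config()` defaults state the emulated study: five cohorts of
44/30/30/28/30 patients (162 total), class probabilities
(0.22, 0.30, 0.22, 0.26) matching the published class proportions, DCB
probability 0.09 in ICR1 and 0.35 in ICR2-4 (matching 3/35 and 44/127),
and exponential disease-free survival (rate 0.012 events/month, about a
58-month median, uniform censoring over 10 years) independent of class —
encoding the published null prognostic result as a testable property.

Expression: the 20 panel genes have gene-specific baselines (4.5–8.3 log2
units) plus `separation` per class step — 1.5 log2 units by default (the
"strong separation" preset, chosen so the classifier recovers planted
classes with ARI ≥ 0.9 at n = 162 through the full per-cohort pipeline;
~0.5 gives a "weak" stress preset). Residual noise is Gaussian on the log2
scale, SD 0.7. Companion genes from the signature database load on the same
0–3 class continuum with +0.8 log2 per step (TP53-activation genes −0.8,
so the TP53 score falls along the continuum as published; Th2 genes +0.2,
making the Th1/Th2 ratio rise). Filler genes are neutral. Gene baselines
are deterministic in gene index — stable across cohorts and spread over a
wide dynamic range, without which per-cohort quantile normalization
(rank-based) would crush the class signal into a narrow reference
distribution; this was the one generator calibration required by the
recoverability design target. Cohort batch effects are a scalar location
shift (SD 0.5) and a log-normal noise-scale factor (SD 0.15). DCB is
Bernoulli given class and otherwise independent of expression — the
minimal structure consistent with the published class-wise benefit rates.
Per-cohort class proportions are homogeneous (per-cohort breakdowns were
never published). Seeding: one root seed, per-cohort streams at a fixed
offset, so any cohort regenerates independently and bit-identically.

What a green test does **not** establish: the generator has Gaussian log2
noise, scalar batch effects and class-conditionally independent genes — no
count overdispersion beyond Poisson in the raw-count fixture, no
gene–gene correlation beyond the planted continuum, no missing clinical
data, no cohort-specific class mix, no tumor-purity gradient. Recovery and
calibration results transfer to real cohorts only insofar as real class
structure is at least as separable.

## Scaled-down test budgets

The published classifier ran 5000 repetitions; the recovery checks in the
test suite use 500 (acceptance) and 30–150 (unit) repetitions — at these
sample sizes the consensus matrix is already essentially crisp, and the
degenerate single-repetition case is tested exactly. Type-I-error checks
use 2000 null simulations (±0.01 band), the null-survival property 400
seeds, and the mixture-odds-ratio concentration check 120 seeds of n = 600
clinical tables; each scaled count is stated in the test it governs. A
single-cohort n = 60 unit test asserts ARI ≥ 0.7 only — class-boundary
noise at that size is real — while the n = 162 design-point check asserts
the full ARI ≥ 0.9.

## Known limitations

* The signature member lists are surrogates; scores are faithful to the
  *construction* (unweighted metagene means) but not gene-for-gene to the
  cited originals.
* Fisher enumeration is exponential in k; intended for 2 × k tables with
  the margins arising here (≤ ~1e5 candidate tables).
* No Firth penalization: quasi-separated designs are flagged, not rescued.
* No cross-cohort expression batch correction (deliberate — labels, not
  expression, are pooled), no Cox modeling, no competing risks, no
  automatic selection of k.
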