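# icrlung

Immune-classification and treatment-benefit analysis for non-small cell
lung cancer (NSCLC) expression cohorts.

## What it does, and for whom

Only a minority of advanced NSCLC patients benefit from anti-PD1/PDL1
checkpoint inhibitors, and better predictive biomarkers than PDL1
immunohistochemistry are needed. One candidate is the Immunologic Constant
of Rejection (ICR): a 20-gene panel of Th1/cytotoxic immune activation
(*CCL5, CD274, CD8A, CD8B, CTLA4, CXCL9, CXCL10, FOXP3, GNLY, GZMA, GZMB,
GZMH, IDO1, IFNG, IL12B, IRF1, PDCD1, PRF1, STAT1, TBX21*) that partitions
tumors into four classes, ICR1 (immune-cold) to ICR4 (immune-hot).

`icrlung` is for computational biologists who want that analysis chain as
tested, reusable components:

* **Classifier** — resampling-based consensus clustering on the 20-gene
  panel (default 5000 repetitions, 80% item resampling, Ward.D2 inner /
  complete outer linkage, k = 4), classes named ICR1..ICR4 by ascending
  mean panel score, plus the collapsed ICR1 vs ICR2-4 contrast.
* **Expression processing** — nCounter-style raw-count normalization
  (negative-control background subtraction, reference-probe geometric-mean
  scaling, log2), per-cohort quantile normalization, within-cohort gene
  standardization, label-level pooling.
* **Signatures** — metagene scores for immune cell subsets and pathway
  activation (GMT-driven, user-replaceable), cytolytic activity
  (log2 geometric mean of *GZMA*/*PRF1*), TIS, TLS, standardized PDL1, and
  first-quintile low/high binarization.
* **Statistics** — contingency tables, Wald odds ratios, exact Fisher
  enumeration for 2 × k tables, IRLS logistic regression with univariate →
  multivariate screening, one-way ANOVA, Cochran's Q cross-cohort
  homogeneity, Kaplan–Meier with Greenwood CIs, log-rank tests. Key
  quantities: OR = (a·d)/(b·c) with CI exp(ln OR ± 1.96·√(1/a+1/b+1/c+1/d));
  S(t) = ∏(1 − d_i/n_i); Q = Σ w_i (θ̂_i − θ̄)².
* **Synthetic cohorts** — a generator planting a 4-class immune continuum
  across five batched cohorts (n = 162 by default) with class-dependent
  durable clinical benefit (DCB) and class-independent survival, so every
  stage is testable without patient data.

## Worked example

```r
library(icrlung)
run <- run_full_analysis(sim_config(seed = 1),
                         consensus_config(repetitions = 500, seed = 1))
print(run)
```

```
<icr_run> n = 162 patients, 5 cohorts
  ICR classes: ICR1=34, ICR2=49, ICR3=35, ICR4=44
  DCB: 27% overall; OR (ICR2-4 vs ICR1) = 3.29 [1.08, 9.96]
  log-rank (DFS, ICR1 vs ICR2-4): chisq = 0.145, p = 0.703
```

The simulated cohort lands near the published design point (22/30/22/26%
class mix, 29% overall DCB): here 34 of 162 patients are ICR1, benefit is
enriched in ICR2-4 (odds ratio 3.29, 95% CI 1.08–9.96 — one draw from a
sampling distribution centered near the planted mixture OR of 5.4), the
five cohorts are mutually homogeneous (`run$summary$dcb$homogeneity_p` =
0.957), and disease-free survival shows no class effect (p = 0.703), as
planted. `run$univariate` and `run$multivariate` hold the forest-plot-ready
logistic results; `run_full_analysis(..., out_dir = "out")` writes the
CSV/JSON report bundle.

Checking the published contingency tables directly:

```r
reproduce_printed_tables()
#>                 check computed expected pass
#> 1           pooled OR     5.65     5.65 TRUE
#> 2       pooled CI low     1.64     1.64 TRUE
#> 3      pooled CI high    19.51    19.51 TRUE
#> ...                                  all TRUE
```

## Command line

```sh
Rscript inst/cli/icr.R simulate  --seed 1 --out sim/
Rscript inst/cli/icr.R classify  --expr sim/cohort01_expression.tsv \
    --k 4 --reps 5000 --pitem 0.8 --seed 1 --out labels.csv
Rscript inst/cli/icr.R run-all   --seed 1 --reps 500 --out out/
Rscript inst/cli/icr.R check-paper
```

## Documentation

`vignettes/icrlung-methods.Rmd` describes the model and every numerical
convention (tie rules, floors, seeds), what the synthetic generator does
and does not emulate, and known limitations. The signature gene lists under
`inst/extdata/signatures.gmt` are curated surrogates and deliberately
user-replaceable.
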