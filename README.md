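# mvmrmr

Multi-view minimum-redundancy maximum-relevance (MRMR) feature selection
for multi-omics classification.

## What problem this solves

Multi-omics studies measure several feature matrices ("views" — e.g.
gene-level copy number, methylation, expression) on the same patients and
ask whether a binary clinical outcome (such as long- vs. short-term
survival) can be predicted from them jointly. With tens of thousands of
features and a few hundred samples, feature selection is the decisive
step — and the two obvious recipes both have failure modes: selecting per
view and concatenating ignores redundancy *across* views; concatenating
first and selecting once ignores that views differ in task relevance.

`mvmrmr` is for method developers and analysts who want a tested,
reproducible implementation of greedy MRMR selection and its multi-view
extension, plus the scaffolding (gated two-stage filter pipelines, a
ground-truthed synthetic generator, a repeated-CV benchmark harness) to
evaluate selection strategies end to end.

## The method

Single-view MRMR selects the most relevant feature first, then greedily
adds

```
argmax_{j in candidates}  f(x_j, y)  -  (1 / |S|^2) * sum_{l in S} g(x_j, x_l)
```

with relevance `f` (chi-squared, two-group F, binned mutual information,
or their min-max-normalized average `cfm`) and redundancy
`g = |Pearson r|`. The exponent on `|S|` is configurable (2 by default,
1 for the classical mean-penalty form).

The multi-view extension `mrmr_mv_select()` allocates selection steps to
views by sampling a schedule from a view-importance distribution
`P = (p_1 ... p_v)`, starts from the globally most relevant feature across
all views, and — crucially — computes the redundancy penalty against the
features already selected from **every** view. A view-2 copy of a selected
view-1 feature is penalized like an in-view duplicate, so the algorithm
keeps complementary signal and discards cross-view redundancy.

Around the selectors, the package provides a two-stage gated filter
framework (view-specific Stage-I filters with enable gates, e.g. an
L1-embedded ranking filter; a single- or multi-view Stage-II selector),
delimited-table I/O with the standard preprocessing (missing-feature
removal, unit-interval rescaling, variance filtering, 3-year survival
labeling), a synthetic multi-view generator with planted relevant,
redundant and complementary features, and a repeated stratified-CV harness
comparing single-view, concatenation (`SV_C`), per-view-union (`SV_S`),
multi-view (`MV`) and prediction-averaging `Ensemble` strategies by AUC.

## Worked example

```r
library(mvmrmr)

# two 200-feature views, 3 planted relevant features each (complementary
# signal), effect size 0.8, 300 samples
g <- generate_multiview(synthetic_spec(n_relevant = 3, effect_size = 0.8),
                        seed = 101)

pipe <- two_stage_pipeline(
  stage1 = filter_spec("all_filter"),
  stage2 = filter_spec("mrmr_mv", list(k = 6, f = "f_stat")))
fitted <- fit_pipeline(pipe, g$dataset, seed = 1)
fitted$fitted_state$selected
#> $view1
#> [1] "rel01" "rel02" "rel03"
#> $view2
#> [1] "rel02" "rel01" "rel03"

recovery_score(fitted$fitted_state$selection, g$truth)
#> $precision
#> [1] 1
#> $recall
#> [1] 1

suite <- strategy_suite(g$dataset, k_grid = 6, learners = "l1",
                        protocol = cv_protocol(n_folds = 3, n_repeats = 1,
                                               seed = 1))
suite$summary
#>   strategy learner k  mean_auc
#> 1 Ensemble      l1 6 0.8396278
#> 2       MV      l1 6 0.8594691
#> 3     SV_C      l1 6 0.8409962
#> 4     SV_S      l1 6 0.8285441
#> 5 SV_view1      l1 6 0.7769568
#> 6 SV_view2      l1 6 0.7324849
```

The multi-view selector recovers all six planted features (perfect
precision and recall against the generator's ground truth), and under
shared CV splits the `MV` model (AUC 0.86) beats the best single-view
model (0.78) — each view carries only half the signal, so integration
helps by construction.

A command-line front end is installed with the package
(`system.file("cli", "mvmrmr", package = "mvmrmr")`) with subcommands
`select`, `simulate` and `evaluate`, each driven by a YAML config file.

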