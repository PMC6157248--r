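---
title: "Multi-view MRMR feature selection: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-view MRMR feature selection: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(mvmrmr)
```

## The problem

Multi-omics studies measure several feature matrices — "views" such as
gene-level copy number, DNA methylation and expression — on the same
patients, and ask whether a clinical outcome (here: a binary label such as
long- versus short-term survival) can be predicted from them jointly. Two
obstacles dominate: extreme dimensionality (tens of thousands of features
against a few hundred samples) and heterogeneity (the views differ in scale,
noise and per-task usefulness). Feature selection is therefore the pivotal
step, and naive recipes have known failure modes: selecting per view and
concatenating ignores redundancy *across* views; concatenating first and
selecting once ignores that views differ in relevance for the task.

`mvmrmr` implements the greedy minimum-redundancy maximum-relevance (MRMR)
criterion and its multi-view extension, embeds both in a gated two-stage
filter framework, and ships a synthetic multi-view generator plus a
repeated cross-validation harness so that every claim about the algorithms
can be tested end to end without any external data.

## The selection criterion

Given a relevance function $f(x_j, y) \ge 0$ and a redundancy function
$g(x_i, x_j) \in [0, 1]$ (here $|{\rm Pearson}\ r|$), single-view selection
starts from the feature with maximal relevance and then greedily adds

$$\mathrm{argmax}_{j \in \Omega_S}\;\Big( f(x_j, y) \;-\;
  \frac{1}{|S|^2} \sum_{l \in S} g(x_j, x_l) \Big),$$

where $S$ is the already-selected set and $\Omega_S$ the remaining
candidates. Two remarks on this exact form:

* **The divisor is $|S|^2$.** The classical criterion divides the
  redundancy sum by $|S|$ (a mean); the form implemented here by default
  uses the squared size, which down-weights redundancy faster as the
  selection grows. Because the classical variant is the natural comparison,
  the exponent is a parameter (`exponent = 2` by default, `1` for the mean
  form); both are covered by the arithmetic tests.
* **Scales matter.** The penalty lives on the $[0,1]$ correlation scale.
  A raw two-group F statistic at $m = 300$ samples and one standardized
  unit of class separation is on the order of 75, so with `f = "f_stat"`
  the penalty is a small perturbation and the greedy trace is close to a
  relevance ranking. With bounded relevance functions — mutual information
  (at most $\ln 2$ nats for a binary outcome) or the normalized consensus
  `cfm` — the penalty has real teeth. This is visible in the package's own
  tests: the planted-copy suppression property is demonstrated under
  `f = "mutual_information"`.

### Relevance functions

Four relevance functions ship, selected by name:

* `chi2` — the one-feature chi-squared statistic for nonnegative data:
  per-class sums of the feature are compared against the totals expected
  under independence from the label. It requires nonnegative input and the
  operation validates rather than silently shifting; the standard
  preprocessing (unit-interval rescaling) guarantees this.
* `f_stat` — the one-way ANOVA F statistic between the two classes.
  A perfectly separated feature (zero within-class variance) scores `Inf`,
  which behaves correctly under argmax; a constant feature scores 0.
* `mutual_information` — a deterministic plug-in estimate: the feature is
  discretized into `bins` (default 10) equal-width bins over its observed
  range and the discrete MI with the label is computed in nats. The
  estimator is intentionally deterministic — the greedy trace is then
  exactly reproducible — and the bin count is the only tuning knob. No
  nearest-neighbour estimator is provided; for $[0,1]$-rescaled data with a
  few hundred samples, 10 equal-width bins is the conventional plug-in
  choice.
* `cfm` — the consensus of the three: each component statistic is min-max
  normalized to $[0,1]$ *across the candidate pool* and the three
  normalized scores are averaged with equal weights. Raw averaging would
  let F statistics (unbounded) dominate MI (bounded); min-max over the
  pool is the simplest normalization making them commensurable. The pool
  is fixed at the start of a greedy run (all candidate features in scope;
  for multi-view runs, the union over views so that scores are comparable
  between views). A per-step renormalization over shrinking candidate sets
  would also be defensible; the fixed pool keeps selection caching exactly
  transparent and the greedy prefix property trivially intact.

Zero-variance features score 0 under every relevance function, and
`abs_pearson` of a constant vector with anything is defined as 0 ("no
signal, no redundancy") rather than `NaN`, so degenerate columns can never
be selected ahead of informative ones nor poison the penalty.

## Multi-view selection

`mrmr_mv_select()` extends the criterion to $v$ views with a
view-importance distribution $P = (p_1, \dots, p_v)$:

1. A schedule $C$ of $k - 1$ view indices is drawn with replacement from
   $P$ (reproducible from one integer seed; selection given the schedule is
   fully deterministic).
2. The first selected feature is the globally most relevant one across
   *all* views — deliberately not drawn from $P$. Note the consequence:
   even $P = (1, 0)$ can contribute its first feature from view 2. The
   schedule only governs steps $2 \dots k$.
3. At step $t$, the candidate set is restricted to view $C[t]$, but the
   redundancy penalty sums $g$ against the features already selected from
   *every* view, divided by $|S_{\rm all}|^e$. This cross-view penalty is
   the point of the method: a view-2 copy of an already-selected view-1
   feature is penalized with $g = 1$ exactly as an in-view duplicate would
   be, so the algorithm retains complementary features and discards
   cross-view redundancy.
4. If the scheduled view has run out of candidates, that step's view is
   redrawn from $P$ restricted (and renormalized) to views with remaining
   candidates. This guarantees $\sum_i |S^i| = k$ whenever the dataset has
   at least $k$ features, while staying as close to $P$ as possible. The
   redraws use a seed-derived stream, so runs remain reproducible.

Ties at any argmax go to the lowest view index, then the lowest feature
index — an arbitrary but fixed rule chosen for reproducibility.

With $v = 1$ the algorithm reduces exactly to `mrmr_select()`; this is a
tested invariant, not an accident of implementation.

## The two-stage framework

`two_stage_pipeline()` composes selection out of gated parts, mirroring how
multi-omics pipelines are assembled in practice:

* **Stage I** holds one view-specific filter per view, each with an enable
  gate. A disabled filter passes *no* data downstream — implemented as view
  deletion, not zero-filling, and tested as a law ("disabling a view is
  equivalent to deleting it"). `all_filter` passes everything; the
  `embedded_l1` filter ranks features by the absolute coefficients of an
  L1-penalized logistic model (glmnet) at a fixed regularization strength
  and truncates to `top_n`, nonzero coefficients first. When the penalty
  zeroes out (almost) everything, ranking falls back to coefficient
  magnitude over all features — the contract is "ranked truncation", not
  "support of the lasso".
* **Stage II** is a single filter: a single-view kind applied to the
  *concatenation* of the surviving views, or the multi-view selector
  applied to them as such. Concatenation prefixes feature names with their
  view name, since different omics sources routinely share gene symbols.
* **Train vs. test mode.** Fitting learns per-view selected feature
  *names*; applying a fitted pipeline is a pure name-keyed column
  projection (permuted columns project identically; a missing selected
  feature is an error). Transforming twice equals transforming once.

Single-view baselines arise by gating: enable only view $i$ and use a
single-view Stage II. The benchmark strategies are built exactly this way.

## Preprocessing

`preprocess_view()` applies, in order: drop features with any missing
value; rescale to $[0,1]$; remove features with population variance below
0.02. Choices worth stating:

* **Rescaling axis.** The default rescales each *feature* to $[0,1]$.
  A per-sample option (`axis = "per_sample"`) exists for protocols that
  normalize sample profiles instead; per-feature is the default because
  the chi-squared relevance needs per-feature nonnegativity and because
  min-max feature scaling is the standard reading for this preprocessing
  step. Constant slices map to all zeros (not `NaN`), so the variance
  filter removes them cleanly.
* **Variance threshold.** Variance is the population variance (divide by
  $m$), the boundary is kept (strictly-below is removed), and the 0.02
  default is calibrated to unit-interval data — on raw scales it would be
  meaningless, which is why the filter runs after rescaling.
* **Survival labeling.** `label_survival()` encodes the 3-year rule:
  survival $\ge$ 3 years is long-term (1); under 3 years is short-term (0)
  only for deceased subjects; subjects censored alive before 3 years are
  uninformative and excluded via the returned mask.

## The synthetic generator

`generate_multiview()` produces labeled multi-view data with known ground
truth: per-view blocks of relevant features (class-conditional Gaussians
with a controlled standardized mean shift), within-view noisy copies and
cross-view copies of relevant features (correlation controlled exactly via
$\sigma_{\rm noise} = \sigma\sqrt{1/\rho^2 - 1}$), bulk independent noise,
and a Bernoulli outcome at a controlled balance; every feature is finally
rescaled to $[0,1]$. The Gaussian signal model is chosen for analytic
control: effect sizes translate into expected relevance orderings and AUC
ceilings in closed form.

Defaults describe the reference test bed used throughout the package's
tests: $m = 300$ samples, two views of 200 features with 10 relevant
features each, class balance 0.59 (a typical long-term-survivor fraction
under 3-year labeling), effect size 1.0. Two deliberate variants appear in
the acceptance tests:

* *Complementary benchmark*: 3 relevant features per view at effect 0.8.
  Each view alone is informative but well below the AUC ceiling, so
  integrating views must help by construction. (At the defaults a single
  view already reaches AUC $\approx$ 0.99 and no integration gain can be
  observed — a ceiling artifact, not a property of the method.)
* *Sensitivity benchmark*: two 12-feature views, $k$ growing to the full
  feature budget, where the saturation mechanism behind the "larger
  selections are less sensitive to $P$" trend operates (see below).

What the generator does **not** emulate: real CNA/methylation marginal
distributions, linkage-like correlation blocks, batch effects, or
censoring-time structure. Passing tests on this test bed demonstrates the
algorithms' contracts and comparative behavior, not clinical performance
on any particular cohort.

`recovery_score()` evaluates a selection against the ground truth with
redundancy-aware matching: a selected copy counts as recovering its
original, but an original plus its own copy still count once.

## Evaluation protocol

`repeated_cv()` runs stratified $k$-fold cross-validation (defaults: 5
folds, 10 repetitions) with feature selection *inside* every training
fold; the tests include a leak check in which corrupting held-out labels
(with the split held fixed) provably never changes the fitted selections.
Fold seeds derive as `seed + repeat`, so all strategies compared under one
protocol share identical splits — comparisons are paired. AUC is the
Mann–Whitney rank statistic with midrank tie handling, tested to 1e-12
against the explicit pairwise definition.

`strategy_suite()` benchmarks, under shared splits: per-view models
(`SV_<view>`, MRMR restricted to one view), `SV_C` (MRMR on the
concatenation), `SV_S` (MRMR per view, $k$ features *per view*, then the
union — the natural reading of "selection applied separately to each
view"; note this gives `SV_S` up to $vk$ features), `MV`
(`mrmr_mv_select`), and `Ensemble` (unweighted prediction averaging of the
best per-view model and the MV model). Learners are plug-in contracts
(`fit`/`predict_prob`); shipped defaults are L1-logistic (glmnet), plain
logistic, probability random forest (500 trees, via ranger) and gradient
boosting (500 rounds, via xgboost) — replaceable plumbing, not part of the
method.

`p_sensitivity()` quantifies how much the MV model cares about the view
sampling distribution: for each $k$ it evaluates $P = (p_1, 1 - p_1)$ over
$p_1 \in \{0, 0.1, \dots, 1\}$ and reports the **percent relative range**
$100\,(\max - \min)/\mathrm{mean}$ of the resulting mean AUCs. (The
percent relative range is the standard relative-spread statistic; adding a
constant to all AUCs strictly decreases it.) On the saturating benchmark
the seed-averaged statistic is non-increasing in $k$ — once $k$ approaches
the feature budget, every $P$ selects essentially the same features and
the sensitivity collapses to exactly zero at $k = $ budget. With $k$ far
below the budget the statistic need not be monotone; the qualitative
flattening is a saturation phenomenon.

## Worked example

```{r example, eval = FALSE}
g <- generate_multiview(synthetic_spec(n_relevant = 3, effect_size = 0.8),
                        seed = 101)
pipe <- two_stage_pipeline(
  stage1 = filter_spec("all_filter"),
  stage2 = filter_spec("mrmr_mv", list(k = 6, f = "f_stat")))
fitted <- fit_pipeline(pipe, g$dataset, seed = 1)
selected_names <- fitted$fitted_state$selected
recovery_score(fitted$fitted_state$selection, g$truth)

suite <- strategy_suite(g$dataset, k_grid = 6, learners = "l1",
                        protocol = cv_protocol(n_folds = 3, n_repeats = 1,
                                               seed = 1))
suite$summary
```

## Numerical and design choices, collected

* Redundancy divisor exponent: 2 by default, 1 as the classical variant.
* Ties: lowest view index, then lowest feature index, at every argmax.
* Selection proceeds even when all candidate scores are negative; the only
  stopping rule is $k$.
* The first multi-view pick ignores $P$; exhausted scheduled views are
  redrawn from $P$ restricted to non-empty views.
* `abs_pearson` on zero-variance input is 0; constant features have zero
  relevance; perfectly separated features have infinite F (pinned to the
  top of the `cfm` normalization).
* MI uses deterministic equal-width binning (default 10 bins) in nats.
* `cfm` normalizes over the candidate pool fixed at the start of the run.
* Caching (precomputed relevance, incrementally accumulated redundancy
  sums) is exactly transparent: cache on/off yields identical selections,
  enforced by tests.
* Stratified folds assign each class's shuffled samples round-robin, so
  per-fold class counts differ by at most one.
* Test and acceptance problem sizes (views of 12–200 features, 20 seeds
  per stochastic property, 3-fold single-repeat CV inside seed loops) were
  chosen so the full suite exercises every property at comfortable
  statistical margins while staying quick to run.

## Known limitations

* The greedy criterion is a heuristic; the exact subset search is
  exponential and exists here only as a brute-force test oracle at tiny
  sizes.
* With unbounded relevance (raw F or chi-squared on large samples) the
  redundancy penalty is comparatively negligible; use MI or `cfm` when
  redundancy suppression is the goal.
* $P$ is an input, not learned; no backward elimination or swap refinement
  of the greedy solution is attempted.
* Binary outcomes only; survival is handled by thresholding, not by
  time-to-event modeling.
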