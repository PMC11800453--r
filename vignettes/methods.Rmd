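---
title: "Methods: sex-stratified Angle-GMLVQ classification of emotion-processing profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sex-stratified Angle-GMLVQ classification of emotion-processing profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

Youth with conduct disorder (CD) show, on average, altered emotion
processing: weaker recognition of facial expressions, poorer learning from
reward and punishment, and reduced inhibitory control under emotional
interference. Group-mean comparisons on single variables, however, say
little about whether these alterations are *useful markers at the
individual level*, and the literature suggests the profile of deficits may
differ between girls and boys. `cdlvq` implements an individual-level,
multivariate answer: a prototype classifier trained separately per sex on
20 covariate-adjusted error scores from three tasks (Emotion Hexagon,
Passive Avoidance Learning, Emotional Go/Nogo), evaluated over repeated
holdout resampling, with per-feature relevance learning that yields a
stability-style feature ranking, and a non-parametric comparison of the two
sex-specific models.

Because the clinical cohort this design targets is not publicly
deposited, the package ships a synthetic cohort generator that reproduces
the *statistical conditions* of such a study; every stage of the pipeline
is therefore testable end to end. All shipped data are synthetic and
labelled as such.

# The classifier

## Angular dissimilarity with a learned relevance transform

Each subject is a vector $x \in \mathbb{R}^{20}$ of covariate-adjusted
z-scores. The classifier holds one prototype $w_c$ per class and a square
transform $\Omega \in \mathbb{R}^{20\times 20}$, and measures

$$
d(x, w) \;=\; \frac{1 - \cos\theta}{2},
\qquad
\cos\theta = \frac{\langle \Omega x,\, \Omega w\rangle}
                  {\lVert\Omega x\rVert\,\lVert\Omega w\rVert},
$$

which depends only on the *directions* of the transformed vectors:
$d(\alpha x, \beta w) = d(x, w)$ for $\alpha, \beta > 0$. The classifier is
therefore sensitive to the *pattern* of performance across features — e.g.
"poor on punishment cues but normal on expressions" — rather than to overall
error level. The relevance matrix $\Lambda = \Omega^\top\Omega$ is kept at
unit trace, and its normalized diagonal
$r_j = \Lambda_{jj} / \operatorname{tr}\Lambda$ gives nonnegative
per-feature relevance scores summing to 1, comparable across fits.

## Cost and optimizer

Training minimizes the classical GLVQ relative-distance cost

$$
E(W, \Omega) = \sum_i \mu_i, \qquad
\mu_i = \frac{d^{+}_i - d^{-}_i}{d^{+}_i + d^{-}_i} \in [-1, 1],
$$

with $d^{+}$ the dissimilarity to the nearest same-class prototype and
$d^{-}$ to the nearest other-class prototype; sample $i$ is classified
correctly exactly when $\mu_i < 0$. The published description of the
angle-based variant leaves the cost activation, the optimizer and the rank
of $\Omega$ open; this package fixes the canonical choices — identity
activation, square full-rank $\Omega$, full-batch gradient descent with
backtracking step halving — and exposes each as a `gmlvq_control()` knob:

* `prototypes_per_class = 1` — a single prototype per class; the angular
  geometry on z-scored data rarely benefits from more, and the target
  analysis is binary.
* `max_iter = 500`, `tol = 1e-7` — iteration cap and the threshold on the
  per-step cost decrease. The cost is scale-invariant in $\Omega$, so the
  unit-trace renormalization applied after every update (which stabilizes
  the subspace learning) never changes the cost.
* `eta_prototype = 0.5`, `eta_relevance = 0.1` — base step sizes; the
  relevance transform learns more slowly than the prototypes, the usual
  arrangement in matrix-relevance LVQ. Backtracking (up to `max_halvings`
  halvings per step) accepts only non-increasing costs, so the training
  history is monotone by construction and the step size needs no manual
  schedule.
* `init_jitter = 0.05` — prototypes start at the class means plus seeded
  Gaussian jitter. The jitter is essential rather than cosmetic: on
  z-scored data with weak separation the class means sit near the origin,
  where directions are ill-defined. The same jitter draw is used for both
  classes' prototype slots, which makes the fit invariant (to numerical
  tolerance) under relabeling of the classes.

Vectors whose transformed norm falls below $10^{-12}$ are treated as
degenerate: training refuses them, and prediction falls back to the
unweighted angle for the affected rows with a warning. Ties in the
nearest-prototype decision go to the lower-indexed prototype.

The cost/gradient kernel and the descent loop are implemented in compiled
code (RcppArmadillo) for speed; a plain-R reference implementation of the
same computation is retained in the package internals and the test suite
asserts agreement to near machine precision, alongside a
numerical-differentiation check of the analytic gradients.

# Preprocessing

Covariates cannot be entered into a prototype classifier, so each feature
is residualized before classification: ordinary least squares of the raw
score on age, IQ, SES (continuous) and site (dummy-coded, first site as
reference), fitted on the pooled cases + controls of one sex stratum, with
residuals divided by their SD. Choices worth making explicit:

* **Pooled fitting.** The regression uses cases and controls together.
  Fitting on controls only would re-introduce group information through
  the back door; pooled fitting is the conservative reading when
  case-control covariate differences are the motivation for adjusting.
* **Fitted once per stratum, before resampling.** The adjustment is not
  re-estimated inside each training fold. This mirrors an
  adjust-then-classify order of operations and is a mild optimism source
  (the test half of every split contributed to the residualization); it is
  deliberate and documented rather than hidden.
* **Within-sex residualization.** All downstream models are sex-specific,
  so the adjustment is fitted within each sex stratum.
* **No imputation.** Missing covariates are an error naming the subjects;
  the analysis contract is complete cases.
* The group label never enters the regression.

# Holdout resampling, metrics and retention

Each sex's model is evaluated over `n_resamplings = 500` independent
stratified holdout splits with `test_fraction = 0.2` (per class, rounded,
so test-set class proportions stay within one subject of the stratum's).
The exact holdout geometry of the original analysis is not public; these
values are package defaults, not a reconstruction, and both are
configurable. Per repetition the engine records:

* the five test-set metrics — wACC $=(\mathrm{TPR}+\mathrm{TNR})/2$, PPV,
  NPV, TPR, TNR — with CD as the positive class. A metric with a zero
  denominator is recorded as missing, excluded from summaries and counted,
  never coerced to 0;
* the normalized relevance vector;
* the in-sample (training) wACC and the retention flag
  `in_sample_wacc >= 0.5`. Retention uses training data only, so no test
  information leaks into the choice of which relevance profiles to keep.

`summarize_model()` reports each metric's mean with a t-based 95% CI over
all repetitions (the retention rule gates only relevance aggregation and
the ranking, not the performance summary), an exact two-sided binomial
test of the count of repetitions with test wACC above 0.5, and Cohen's
*g* as that proportion minus 0.5. The proportion-of-repetitions reading of
*g* is the one consistent with reporting large effects alongside mean
accuracies near 0.59 — applying *g* to the mean accuracy itself would give
≈0.09 and could never reach conventional "large" benchmarks.

A deterministic child-seed scheme (`child_seed(master, r)`) makes every
repetition individually reproducible; the same scheme fans the global seed
out to the simulation, the per-stratum runs and the exemplar fits inside
`run_full_analysis()`.

# Feature ranking and model comparison

`rank_features()` computes, per feature, the percentage of resamplings in
which the feature ranked among the `top_k = 5` relevances of a classifier
reaching test wACC ≥ 0.6. Two readings of the denominator are defensible;
the default divides by all *retained* repetitions, so a low percentage
reflects both the rarity of sufficiently accurate classifiers and the
rarity of top-5 membership (`denominator = "qualifying"` switches to the
alternative). Relevance ties break deterministically by schema order.

`compare_models()` applies two-sided Mann-Whitney U tests to the
per-repetition metric distributions of the two sexes, with effect size
$r = |Z|/\sqrt{n_1+n_2}$. Repetitions are treated as exchangeable draws;
because holdout resamples overlap, they are not independent and the
comparison is anti-conservative — p-values should be read as descriptive
of the resampling distributions, not as subject-level inference.

# The synthetic cohort generator

`simulate_cohort()` draws subject-level records that reproduce the study
conditions the pipeline assumes:

* **Stratum sizes** default to 317/479 females and 225/231 males
  (CD/control), the composition of the large multi-site cohort this design
  targets.
* **Correlation structure.** Latent profiles follow
  $z_j = \sqrt{s}\,G + \sqrt{v}\,F_{d(j)} + \sqrt{u}\,\epsilon_j$ with a
  shared factor, one factor per emotion domain and unique noise, all
  standard normal, so correlations are $s+v$ within and $s$ between
  domains. The defaults $(s, v, u) = (0.12, 0.25, 0.63)$ follow in closed
  form from the target correlations 0.37 (within) and 0.12 (between).
* **Covariates and confounding.** Age uniform on 9–18 years; IQ normal
  (100, 15) truncated at 70; SES standard normal; 7 sites, uniform.
  CD strata are shifted by −6 IQ points (−0.4 SD) and −0.4 SD SES, and
  per-feature covariate effects (defaults −0.8 %/year of age, −0.08 %/IQ
  point, −1 %/SES SD, site offsets spread over ±1.5%) plant the
  confounding that residualization must remove — so the adjustment stage
  is consequential and testable.
* **Deficit heterogeneity.** Only a subset of CD youth is assumed to show
  emotion dysfunction: a fraction `deficit_prevalence = 0.5` of CD
  subjects carries the sex-specific deficit pattern (a two-component
  mixture). The female pattern loads most heavily on happiness-recognition
  errors, the male pattern on fear-recognition errors, each with secondary
  loadings across all three domains. Magnitudes were fixed by a one-time
  calibration of the full pipeline's mean test wACC — grid search over the
  pattern scale, averaged over five cohort seeds at 100 resamplings — to
  ≈0.59 (female) and ≈0.56 (male), the intended moderate, clinically
  sub-threshold accuracy regime. The residual cohort-to-cohort SD of that
  mean is ≈0.03: a single simulated cohort can legitimately support mean
  accuracies a few points away from the calibration target.
* **Percent mapping.** Latent values map to error percentages as
  $30 + 11 z$, clipped to $[0, 100]$; at the defaults well under 1% of
  scores touch the bounds, and any affine choice is equivalent downstream
  because features are z-scored. (A steeper map such as $25 + 12z$ clips
  ≈2% of scores once covariate variance is added, which is why the gentler
  default was chosen.)
* The 20-feature battery is fixed as 6 recognition + 8 learning + 6
  regulation scores — the unique decomposition consistent with the three
  task descriptions: six Hexagon expressions, omission and avoidance
  errors at four incentive magnitudes, six go/nogo block pairings.

What the generator does **not** emulate: trial-level task data, comorbidity
structure, non-Gaussian score distributions (real error percentages are
often skewed and zero-inflated), site-by-covariate interactions, and any
dependence of the deficit pattern on age or severity. Passing tests on
synthetic cohorts therefore demonstrate that the *pipeline* behaves as
specified under the assumed statistical conditions — not that the
substantive clinical findings would replicate on real data.

# Numerical and design notes

* Problem sizes in the test suite are the package's own choices: full-size
  strata with 500 repetitions for the calibration and null checks; smaller
  cohorts (≈150 subjects, 200 repetitions) for the repeated null-run
  check; 100,000 subjects for the correlation recovery; 10,000 random
  pairs for the dissimilarity oracle.
* Exact binomial and exact Mann-Whitney enumerations are used where sample
  sizes permit (U test: both n < 20 and no ties); otherwise the
  tie-corrected normal approximation supplies both the p-value and the
  $Z$ behind the effect size $r$.
* Back-calculation of published PPV/NPV values from TPR/TNR is
  inconsistent with a single common test-set prevalence across the two sex
  models, so no attempt is made to reconstruct the original test-set
  composition; the package's own stratified-prevalence defaults determine
  PPV/NPV, which is why its PPV/NPV need not match published ones even
  when wACC does.
* With a strong planted signal and `top_k = 5`, surplus top-5 slots lock
  onto whichever noise features happen to correlate with the signal in the
  one fixed cohort; single noise features can therefore show high ranking
  percentages. This is a property of resampling one dataset, not a defect
  of the ranking.

# Known limitations

* The adjustment-before-resampling order (above) leaks a small amount of
  distributional information into test folds.
* Mann-Whitney comparisons across overlapping resamples are
  anti-conservative. The binomial chance test shares the problem in a
  stronger form: all repetitions are drawn from one finite cohort, and a
  null cohort's own chance group-feature association shifts its entire
  resampling distribution slightly off 0.5 (SD of the per-cohort mean
  test wACC is about `1/sqrt(n)`-scale, ~0.014 at full stratum size).
  Over hundreds of correlated repetitions the binomial test reliably
  detects that cohort-level offset, so on truly null data it rejects far
  more often than its nominal level. Significance of the chance test
  should be read as "this cohort's resampling distribution is not
  centered at 0.5", not as subject-level evidence against chance.
* The angle dissimilarity is undefined at the origin; degenerate rows are
  handled explicitly but a cohort with many near-zero profiles would merit
  a different dissimilarity.
* Single-prototype-per-class models cannot represent multimodal class
  structure; `prototypes_per_class` raises this, at the cost of a
  non-convex fit that is more initialization-sensitive.
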