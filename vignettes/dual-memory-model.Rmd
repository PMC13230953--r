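---
title: "The dual-memory model of the testing effect: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The dual-memory model of the testing effect: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualmem)
```

## The model

A cued-recall test trial with feedback is assumed to do two things that a
restudy trial does not: it strengthens the memory formed at initial study
(study memory) *and* lays down a separate memory of the retrieval episode
(test memory), giving tested items two retrieval routes on the final test.
With three simplifying assumptions — (1) study-memory strength is
identically distributed in the restudy and test conditions, (2) study and
test memory strengths are identically distributed, and (3) the two
strengths are stochastically independent — the probability of recalling a
tested item is the inclusive-or of two routes that each succeed with the
restudy probability:

$$P_T = P_R + P_R - P_R^2 = 2 P_R - P_R^2, \qquad
  TE = P_T - P_R = P_R - P_R^2 .$$

The same equations are applied to subject-level proportions correct
(`predict_pt()`, `predict_te()`). The TE prediction is quadratic:
0 at $P_R \in \{0, 1\}$ and maximal (0.25) at $P_R = 0.5$. This is why a
raw accuracy interaction between training task and any factor that shifts
$P_R$ is uninterpretable — equal testing efficacy can produce unequal TEs
and vice versa — and why the package evaluates efficacy against the model
instead.

### Correlated strengths

When cue and target are strongly related semantically, study and test
memories plausibly share representational features, making their strengths
positively correlated rather than independent. The extension
(`pt_correlated()`) models the two strengths as standard bivariate normal
with correlation $\rho \in [0, 1]$ and scores recall if either exceeds the
threshold $z = \Phi^{-1}(1 - P_R)$ that individually reproduces $P_R$:

$$P_T(\rho) = 1 - \Phi_2(z, z; \rho) = 2 P_R - P(S > z, T > z; \rho).$$

This Gaussian-copula choice is the minimal law that (i) preserves
identical marginals for the two routes, (ii) reproduces $2P_R - P_R^2$
exactly at $\rho = 0$, (iii) collapses to the single-route limit $P_R$ at
$\rho = 1$, and (iv) has one interpretable parameter. Because the
supplement of the source framework specifies only "correlated strengths",
other copulas are conceivable; a different law could shift a fitted
$\rho$ slightly, which is why the package treats $\rho$ as a model-defined
scale parameter, not a direct estimate of a physical correlation.

Near independence the extension is practically indistinguishable from the
parameter-free model: the maximum TE difference over the whole $P_R$ range
between $\rho = 0$ and $\rho = 0.1$ is 0.0159 (attained at $P_R = 0.5$),
which is why good independent-model fits to weakly related materials do
not rule out small positive correlations.

### Numerics

The upper-orthant probability is evaluated through Plackett's identity,

$$P(S > z, T > z; \rho) = \bar\Phi(z)^2 +
  \frac{1}{2\pi} \int_0^{\arcsin \rho} e^{-z^2/(1 + \sin\theta)}\, d\theta,$$

where the $\sin\theta$ substitution removes the
$1/\sqrt{1 - r^2}$ singularity of the naive correlation integral. The
integrand is then smooth on the full $\rho$ range and 32 Gauss–Legendre
nodes are converged to well below $10^{-8}$ (checked against 2000 nodes
and against independent 2-D quadrature of the bivariate density in the
test suite). Probabilities exactly 0 or 1 short-circuit before the
$\Phi^{-1}$ call. A Monte-Carlo route (`pt_correlated_mc()`) exists purely
for validation and for readers who prefer simulation; every analysis path
uses the closed form.

## Estimating the strength correlation

`fit_rho()` matches means: it finds $\rho$ minimising
$\bigl|\,\tfrac1N \sum_i P_T(\rho; \mathrm{PC}_{R,i}) - \overline{\mathrm{PC}_T}\,\bigr|$,
with each participant's own restudy accuracy feeding the prediction (means
are taken across participants, not pooled trials). The mean prediction is
continuous and strictly decreasing in $\rho$, so the minimiser is unique;
bisection runs to a tolerance of $10^{-3}$ on $\rho$ and the estimate is
the best point actually evaluated, which makes the reported objective the
minimum of the search trace by construction. If the observed mean already
exceeds the independence prediction the estimate is pinned at $\rho = 0$
(boundary flagged); below the single-route prediction it pins at
$\rho = 1$. Restudy accuracies that are all 0 or 1 leave $\rho$
unidentified and raise an error.

Two properties of this estimator are worth knowing:

* **Quantisation floor.** With $N$ participants and $k$ items the observed
  mean moves in steps of $1/(Nk)$, so an interior fit matches the mean to
  within about $1/(2Nk)$.
* **Small-sample bias.** Proportions carry binomial noise with variance
  $p(1-p)/k$, and the prediction is concave in $P_R$, so by Jensen's
  inequality the mean prediction computed from noisy $\mathrm{PC}_R$ is
  slightly low, and the fitted $\rho$ slightly lower than the generating
  value — about $-0.03$ at $k = 40$ items for cohorts generated at
  $\rho = 0.334$ (median recovered $\approx 0.30$ over 200 replicates in
  the test suite). This is a property of mean-matching on finite trials,
  shared by any analysis that plugs observed proportions into the
  prediction; it disappears as $k$ grows.

`efficacy_reduction()` expresses the shortfall of the observed mean TE
relative to the independence prediction, $(TE_{pred} - TE_{obs}) /
TE_{pred}$; positive values mean testing under-delivered.

## Cumulative-distribution matching

`cumulative_curve()` sorts $\mathrm{PC}_R$ and $\mathrm{PC}_T$
*independently* from smallest to largest, places both on the quantile axis
$k/N$ ($k = 1..N$, maximum at 1 — the convention that makes $N$ "equally
spaced values scaled from zero to one" concrete), and applies the model
transform to the sorted $\mathrm{PC}_R$ at each quantile. Ties (common,
since proportions are multiples of $1/k$) are broken by a stable sort on
(value, participant id), making curves invariant to input order.
`deviation_metrics()` reports the mean signed (observed − predicted), mean
absolute and maximum absolute deviations; a clearly negative mean signed
deviation is the distribution-wide signature of reduced testing efficacy,
as opposed to a ceiling artefact confined to high performers.
`interpolate_curve()` puts groups of unequal size on a common 101-point
grid for matched-quantile comparison; `range_fraction()` quantifies how
much of a group's restudy distribution lies in the high-TE band
(closed interval by default, with the open-interval count also reported by
the pipeline, since verbal "between about 0.4 and 0.6" statements do not
fix endpoints).

One subtlety: even when the data are generated under independence, the
finite-item mean signed deviation is not exactly centred at zero but at
$+E[p(1-p)]/k$ (the same Jensen effect as above, now pushing the
*prediction* down). At $k = 40$ that is about $+0.005$. The test suite's
null-centering check therefore runs at $k = 200$ items, where the offset
is negligible against sampling noise; at 40 items the offset is real and
would be misread as a (tiny) spurious efficacy *increase*, never as the
Scenario-2 decrease.

## The synthetic cohort generator

`cohort_config()` / `generate_cohort()` emulate the reference design the
analysis assumes: two relatedness groups of 118 (low) and 113 (high)
participants, training task within participants, 40 items per condition,
one final cued-recall trial per item scored 0/1. Per-participant baseline
abilities are beta-distributed with group means 0.47 (high) and 0.30
(low); both training conditions share the participant's single ability
(study-memory equivalence), restudy items are Bernoulli in it, and test
items are scored from correlated bivariate-normal strength pairs at the
group's $\rho$ (defaults: 0.334 high, 0 low), so expected test accuracy is
exactly `pt_correlated(ability, rho)`.

Free choices, made once:

* **Concentration 3** for the beta ability law. The reference
  distributions span the full $[0,1]$ range of restudy accuracy;
  concentration 3 reproduces that spread while holding the stated group
  means. No empirical ability variance is available to estimate it, so it
  is a documented default, not an estimate (and `Inf` gives degenerate
  abilities for calibration tests).
* **Low-group mean 0.30**, below the high group as in the reference data.
* **Items exchangeable** by default; an additive item effect on the latent
  scale (`item_sd`) exists for sensitivity analyses but is off, since
  item-level modelling is out of scope.

What the generator does *not* emulate: spelling-based scoring of typed
responses, training-phase dynamics (feedback timing, forward testing
effects), retention-interval forgetting, or item random effects in the
default configuration. Passing tests on synthetic cohorts therefore
validate the *analysis chain* under the model's own assumptions — they
show the estimator and statistics recover what was put in, not that the
model is true of any real population.

## Inference chain

`mixed_anova_2x2()` wraps the classical one-within × one-between
decomposition (`stats::aov` with an `Error(participant/measure)` stratum),
returning F, degrees of freedom, p and partial $\eta^2$ per effect, for
both the Training Task × Relatedness ANOVA on observed accuracy and the
Data Type × Relatedness ANOVA on observed vs predicted test accuracy.
Unequal group sizes use the standard sequential mixed-design
decomposition. Effects with numerically zero sums of squares report
F = 0, p = 1 rather than 0/0. `t_test_bf()` runs two-sided t tests (paired
tests are identically the one-sample t on differences) and attaches the
default JZS Bayes factor at Cauchy prior scale 0.707, computed from the
one-dimensional g-mixture integral; zero-variance inputs raise an error
rather than returning an infinite t, since proportion data can pin at
floor or ceiling. `raftery_label()` bins the directional Bayes factor
(left-closed: $[1,3)$ weak, $[3,20)$ positive, $[20,150)$ strong,
$\ge 150$ very strong). ANOVA-level Bayes factors are deliberately out of
scope — the default mixed-model BF needs multidimensional integration over
random-effect priors — and reports say so.

## Pipeline, determinism and problem sizes

`run_pipeline()` chains the stages (read/simulate → summarise → fit →
curves → statistics → report) and serialises a JSON report whose layout is
described by the schema shipped in `inst/schema/`. All randomness flows
from explicit seeds; a configuration plus seed reproduces the report
byte-for-byte apart from the timestamp, and seeded routines restore the
caller's RNG state.

Simulation-based checks in the test suite use these sizes, chosen to make
Monte-Carlo error small relative to the tolerances they support: 200
replicate cohorts of 113 participants × 40 items for parameter recovery
and for the overprediction signature, $10^5$ draws for closed-form vs
Monte-Carlo agreement on a 5 × 5 $(p, \rho)$ grid at 3 standard errors,
2000 replicates for the 0.05-level calibration of the ANOVA interaction
and paired t under the null, and 60 replicates for the generator-implied
efficacy-reduction and range-fraction medians.

## Known limitations

* $\rho$ is restricted to $[0, 1]$; negatively correlated routes are
  outside the model space.
* The Gaussian copula is a reconstruction of "correlated strengths";
  alternative dependence structures would fit the same means with slightly
  different $\rho$ values and distribution shapes.
* Mean-matching inherits the small finite-trial bias described above;
  analyses at substantially fewer than 40 items per condition should
  expect a larger downward shift in fitted $\rho$.
* The bootstrap-style `simulate()` method resamples observed restudy
  accuracies as abilities; it mixes binomial noise into the ability law
  and is meant for qualitative checks, not for sharp coverage claims.
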