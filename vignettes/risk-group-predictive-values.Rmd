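---
title: "Risk-group predictive values: model, intervals and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Risk-group predictive values: model, intervals and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvtrial)
```

## The statistical model

A diagnostic trial examines `N = n1 + n0` subjects, `n1` diseased and `n0`
non-diseased according to an error-free gold standard, each by the same
`M` diagnostic modalities (or reader-by-method combinations, flattened
into `M` slots). The per-subject result vector follows a multivariate
Bernoulli distribution with success probabilities `se` (diseased group)
and `sp` (non-diseased group); subjects are independent replications.
Sensitivities and specificities are estimated by the usual proportions,
and — because the modalities share subjects — the estimators are
correlated within each disease group:

\[
\widehat{\operatorname{Cov}}(\hat{se}^{(l)}, \hat{se}^{(r)}) =
\frac{\hat P_{lr} - \hat{se}^{(l)}\hat{se}^{(r)}}{n_1},
\]

with \(\hat P_{lr}\) the proportion of diseased subjects positive on both
modalities (specificity analogous from joint negatives). The diseased and
non-diseased blocks are independent, so sensitivity and specificity
estimators have zero cross-covariance.

Each risk group `g` carries a pre-test probability of disease
\(\pi_g\), estimated in a *prior* study as \(\hat\pi_g = k_g / m_g\) with
binomial variance \(\hat\pi_g(1-\hat\pi_g)/m_g\). Predictive values follow
from Bayes' theorem,

\[
p_+ = \frac{se\,\pi}{se\,\pi + (1-sp)(1-\pi)}, \qquad
p_- = \frac{sp\,(1-\pi)}{sp\,(1-\pi) + (1-se)\,\pi},
\]

and their estimators inherit an asymptotically normal distribution by the
multivariate delta method. Writing \(g_m = \nabla f_\pm(se^{(m)},
sp^{(m)}, \pi_g)\), the covariance of the predictive-value estimators
assembles from the three independent sources:

\[
\widehat{\operatorname{Cov}}(\hat p^{(l)}, \hat p^{(r)}) =
g_l^{se} g_r^{se} \widehat{\operatorname{Cov}}(\hat{se}^{(l)},\hat{se}^{(r)})
+ g_l^{sp} g_r^{sp} \widehat{\operatorname{Cov}}(\hat{sp}^{(l)},\hat{sp}^{(r)})
+ g_l^{\pi} g_r^{\pi} \widehat{\operatorname{Var}}(\hat\pi_g).
\]

The prevalence estimate is *shared* across modalities, so its contribution
is fully correlated between them (a rank-one term). All covariances in
this package are on the finite-sample scale (the covariance of the
estimator itself); the asymptotic theory's \(\sqrt{N}\)-normalised
covariance equals `N` times ours, and every statistic below is
algebraically identical under the substitution, which spares the API from
carrying `N` and the group-size ratios around.

Key assumptions, and what they mean in practice:

- the gold standard is error-free;
- every subject undergoes all `M` tests (missing cells are rejected at
  read time rather than imputed, because imputation would distort the
  covariance structure);
- `se`, `sp` and all `pi_g` lie strictly inside (0, 1);
- accuracy is homogeneous across risk groups — the trial's `se`/`sp`
  apply to every group, only the prevalence differs. This is what makes
  external prevalences (and case-control designs) usable, and it is the
  assumption to scrutinise before using the package: if accuracy depends
  on the same factor that defines the risk groups (e.g. BMI for imaging),
  a stratified analysis is needed instead.

## Interval variants and their parameters

Six variants are available in `confidence_interval()`, all two-sided at
`alpha = 0.05` by default (the conventional level, and the one used by
every benchmark in the test suite):

| method | scale | quantile | prevalence variance |
|---|---|---|---|
| `additive-normal` | probability | normal | estimated |
| `additive-t` | probability | t, estimated df | estimated |
| `logistic-normal` | logit | normal | estimated |
| `logistic-t` | logit | t, estimated df | estimated |
| `mercaldo-additive` | probability | normal | fixed at 0 |
| `mercaldo-logistic` | logit | normal | fixed at 0 |

Additive intervals are deliberately **not clipped** to [0, 1]: clipping
would silently change interval lengths and corrupt length comparisons
between methods; the logistic transform is the principled range-preserving
alternative. The logit-scale standard error is
\(sd(\hat p)/(\hat p(1-\hat p))\) by the delta method.

**Degrees of freedom for the t variants.** The variance estimate
\(\hat v = c_{se} + c_{sp} + c_\pi\) (the three gradient-weighted binomial
components) is itself random; matching a scaled chi-square to its first
two moments gives

\[
\nu = \frac{2\hat v^2}{\widehat{\operatorname{Var}}(\hat v)}, \qquad
\widehat{\operatorname{Var}}(\hat v) = \sum_{i \in \{se, sp, \pi\}}
c_i^2\,\frac{(1-2p_i)^2}{p_i(1-p_i)\,n_i},
\]

using the asymptotic variance of each binomial variance estimator
\(\widehat{p(1-p)}/n\). Two limits confirm the construction: when one
component carries all the variance, \(\nu\) collapses to that component's
own effective df; when every underlying proportion is exactly 1/2 the
denominator vanishes while \(\hat v > 0\), \(\nu \to \infty\), and the t
interval recovers the normal one. When the point estimate is 0 or 1 every
component vanishes and \(\nu\) is 0/0 — precisely the case where the t
interval is reported as failed. An alternative Satterthwaite construction
with component dfs \((n_1-1, n_0-1, m_g-1)\) was considered and discarded:
on the worked CAD example it yields \(\nu \approx 161\) and misses the
reference t-interval endpoints, whereas the moment-matching form above
(\(\nu \approx 47\)) reproduces them to three decimals. The logistic-t
variant uses the same \(\nu\) (the natural pairing, since \(\nu\) is a
property of \(\hat v\), not of the link).

**Degenerate estimates.** If \(\hat p \in \{0, 1\}\) the point estimate is
still reported; the plug-in variance collapses to zero, so the additive
interval degenerates to a point, while the logistic and t variants are
undefined and flagged `failed = TRUE` rather than raising an error — in
simulation use, failure is an outcome to count, not an exception.

**Differences and contrasts.** `difference_interval()` and
`contrast_interval()` use the normal quantile on the probability scale
(the defining formula for differences), with variance `c' V c`. The t
approximation is not offered for contrasts: its df construction relies on
the three-source decomposition of a *single* predictive value's variance
and does not carry over cleanly to linear combinations across modalities.

## Testing equality across modalities

`ats_test()` tests \(H_0: T p = 0\) with the centering matrix
\(T = I_M - \frac{1}{M}\mathbf{1}\mathbf{1}'\) (or a user-supplied
symmetric idempotent projection; anything symmetric but not idempotent is
replaced by the projector onto its column space). The ANOVA-type statistic
\(\hat p' T \hat p / \operatorname{tr}(T \hat V)\) is referred to a
\(\chi^2_{\hat f}/\hat f\) distribution with
\(\hat f = [\operatorname{tr}(T\hat V)]^2 / \operatorname{tr}[(T\hat V)^2]\).
For `M = 2` this reduces exactly to the squared standardised difference
with \(\hat f = 1\), so the p-value equals the two-sided normal test of
the difference — one of the package's exact regression tests. A logit-link
variant transforms estimates and covariance before forming the statistic.

The hypothesis concerns one risk group and one side (PPV or NPV) at a
time; p-values are not adjusted across groups or sides, and users running
many groups should apply their own multiplicity control. The test requires
the full cross-modality covariance and therefore refuses accuracy objects
built from published summaries (`summary_accuracy()`), where the joint
proportions are unrecoverable; per-modality intervals remain available for
such input.

## The synthetic-data generator

`generate_trial()` draws correlated binary outcome vectors by thresholding
a latent Gaussian vector: marginal `m` is positive when its latent
coordinate falls below \(\Phi^{-1}(se^{(m)})\) (diseased block; the
non-diseased block uses `sp`). For each pair of marginals the latent
correlation is solved numerically (one-dimensional quadrature of the
bivariate normal orthant probability inside a root finder, cached per
(marginal pair, rho)) so that the *binary* correlation matches the
requested `rho`; requests outside the Fréchet bounds of a pair are
rejected with the admissible range. The Gaussian copula was chosen over an
explicit joint-probability parameterisation because it scales to arbitrary
`M` with one parameter per pair and guarantees valid joint distributions.

What the generator emulates: exchangeable-by-design dependence between
modalities, independent diseased/non-diseased blocks, binomial prevalence
studies (`generate_prevalence_study()`, which redraws boundary outcomes
`k ∈ {0, m}` and records the redraw count). What it does not emulate:
covariate-dependent accuracy, reader drift, clustered or longitudinal
data, imperfect gold standards. Tests passing on generated data therefore
validate the estimators and intervals under the stated sampling model,
not robustness to violations of it.

## The coverage study

`run_coverage_study()` reproduces the interval benchmark: a fully crossed
grid of \(\pi \in \{0.05, 0.25, 0.5\}\), \(se, sp \in \{0.5, 0.75, 0.85,
0.9\}\) (48 combinations), \(n_0 = n_1 \in \{50, 100, 500\}\) and
\(m_g \in \{100, 500, 1000\}\) — 432 cells, 10,000 replicates each by
default. Per replicate, `se`, `sp` and `pi` estimates are drawn directly
from their binomials (the sufficient statistics — subject-level data would
add cost without changing the distribution for `M = 1`), every interval
variant is formed from the same draws, and coverage of the true predictive
value, interval length and failure are recorded. Design notes:

- **`n` and `mg` fully crossed, not paired.** The marginal summary rows
  for `mg = 100` and `n = 50` differ in the benchmark tables, which is
  only possible under a crossed design.
- **Failure accounting.** A replicate fails when \(\hat p \in \{0, 1\}\)
  (or is 0/0). Failed replicates are excluded from the coverage and
  length denominators of the logistic and t variants — an interval that
  does not exist can neither cover nor miss — and tallied in the failure
  rate, which is identical across those variants because the point
  estimator is shared. An analytic check supports this bookkeeping: at
  \(\pi = 0.05, m_g = 100\) the probability of \(\hat\pi = 0\) alone is
  \(0.95^{100} \approx 0.59\%\), and only counting such draws as failures
  (rather than redrawing them) reproduces the benchmark failure rates by
  prevalence stratum.
- **Fixed-prevalence columns** reuse the same \(\hat\pi\) draw but omit
  its variance — evaluating the known-prevalence method in the realistic
  setting where the prevalence was in fact estimated.
- **Seeding.** Each cell derives its seed from the design's base seed and
  its own index, so results are independent of evaluation order and
  reproducible cell-by-cell.
- Marginal summary rows (`summary()`) are exact unweighted means over the
  constituent cells, one parameter held fixed.

Problem sizes in the test suite: the acceptance checks run the full
432-cell design at 10,000 replicates plus a 1,000-replicate scaled-down
pass; the null-rejection check of the ANOVA-type test uses 5,000
three-modality trials with `n1 = n0 = 500`, `mg = 1000`, `rho = 0.3`;
Monte-Carlo covariance oracles use 4,000–10,000 replicates with
3-standard-error bands.

## Known limitations and one data remark

- All inference is asymptotic; for very small groups (`n` below a few
  dozen) even the t variant can undercover, and the failure mechanism
  becomes non-negligible for extreme `se`, `sp` or `pi`.
- One-way modality structure only: factorial reader-by-method designs are
  analysed by flattening cells into modality slots and choosing contrasts
  accordingly; no variance-component modelling of readers is attempted.
- Prevalence must come from the same population the risk groups describe;
  the package cannot detect a mismatched prior study.
- The bundled CAD example: the source publication of the underlying trial
  quotes a PPV of 0.83 and an NPV of 0.91 under the study-prevalence
  convention, while the printed contingency table yields 140/153 ≈ 0.915
  (PPV) and 114/138 ≈ 0.826 (NPV) — the quoted pair appears transposed.
  The package works from the table counts; the discrepancy is noted here
  rather than silently corrected, and none of the bundled benchmarks
  depend on it.
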