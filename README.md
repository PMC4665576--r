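# pvtrial

Predictive values for risk groups in factorial diagnostic trials.

## The problem

Sensitivity (se) and specificity (sp) describe how well a diagnostic test
separates diseased from non-diseased subjects, but they do not answer the
clinical question: *given this patient's positive (or negative) result, how
likely are they to be diseased (or disease-free)?* Those are the positive
and negative predictive values, and they depend on the patient's pre-test
probability of disease — the prevalence `pi` in the patient's risk group —
through Bayes' theorem:

    PPV = se * pi / (se * pi + (1 - sp) * (1 - pi))
    NPV = sp * (1 - pi) / (sp * (1 - pi) + (1 - se) * pi)

`pvtrial` estimates risk-group-specific predictive values for one or
several diagnostic modalities evaluated on the *same* subjects, with the
prevalence of each risk group taken from prior studies as a count ratio
`k/m`. Because `pi` is itself an estimate, its sampling variability is
propagated — together with that of `se` and `sp`, and the cross-modality
correlations induced by the paired design — through the multivariate delta
method into the joint covariance of the predictive-value estimators. On
that basis the package provides:

- **Intervals**: additive (probability-scale) and logistic (logit-scale,
  range-preserving) confidence intervals, each with a normal or a
  t-approximated quantile whose degrees of freedom `nu = 2 v^2 / Var(v)`
  are estimated from the three binomial variance components;
- **Fixed-prevalence variants** (`mercaldo-*`) that treat `pi` as known —
  the classical convention, markedly anti-conservative when `pi` was in
  fact estimated;
- **Tests**: an ANOVA-type statistic (quadratic form with a scaled
  chi-square/Box reference distribution and estimated degrees of freedom)
  for equality of predictive values across modalities or flattened
  reader-by-method cells, plus Wald intervals for differences and
  arbitrary contrasts;
- **Generators** for correlated multi-modality trial data (Gaussian-copula
  thresholded binary outcomes) and prevalence studies;
- A vectorised **coverage simulation engine** benchmarking all six
  interval variants on a 432-cell design (coverage, length, failure rate).

Intended users: biostatisticians analysing diagnostic accuracy studies —
including case-control designs, where the study prevalence is meaningless
and an external prevalence is the only honest option.

## Worked example: CT angiography for coronary artery disease

A multicentre trial evaluated multidetector CT angiography (MDCTA) against
conventional coronary angiography (the gold standard) in 291 patients:
140 true positives, 13 false positives, 24 false negatives, 114 true
negatives. Prevalences of coronary artery disease by presenting symptom
come from a prior literature review: 146/913 (nonanginal chest pain),
963/1,931 (atypical angina), 1,874/2,108 (typical angina).

```r
library(pvtrial)

trial <- read_trial_csv(system.file("extdata", "cad_trial.csv", package = "pvtrial"))
acc <- estimate_accuracy(trial)
acc
#> Diagnostic accuracy (M = 1, n1 = 164, n0 = 127)
#>  modality     se sd(se)     sp sd(sp)
#>     mdcta 0.8537 0.0276 0.8976 0.0269

prev <- prevalence_spec(c("nonanginal", "atypical", "typical"),
                        k = c(146, 963, 1874), m = c(913, 1931, 2108))
pv <- predictive_values(acc, prev, "nonanginal", "PPV")
confidence_interval(pv, "logistic-normal")
#> nonanginal PPV intervals (logistic-normal, alpha = 0.05)
#>  modality          method estimate  lower  upper failed
#>     mdcta logistic-normal   0.6135 0.4785 0.7331  FALSE

pv_table(acc, prev, methods = c("additive-normal", "logistic-normal"))
```

The full report (rounded to 3 decimals) reads, for example:

```
      group side modality          method estimate lower upper
 nonanginal  PPV    mdcta additive-normal    0.614 0.484 0.744
 nonanginal  PPV    mdcta logistic-normal    0.614 0.478 0.733
 nonanginal  NPV    mdcta additive-normal    0.970 0.958 0.982
   atypical  PPV    mdcta additive-normal    0.892 0.842 0.943
   atypical  NPV    mdcta additive-normal    0.860 0.814 0.907
```

Reading: for a patient with nonanginal chest pain, a positive MDCTA raises
the disease probability from 0.16 to 0.61 — far from conclusive — while a
negative result virtually excludes disease (NPV 0.97). For typical angina
the picture reverses: PPV 0.985, but NPV only 0.43. The same accuracy data
support opposite clinical conclusions in different risk groups, which is
exactly why predictive values must be reported per group.

The same analysis from the shell:

```sh
Rscript inst/cli/pvtrial.R pv --data inst/extdata/cad_trial.csv \
  --prev "nonanginal:146/913" --prev "atypical:963/1931" \
  --prev "typical:1874/2108" --methods additive-normal,logistic-normal
```

(`estimate` and `simulate` subcommands cover accuracy-only reports and the
coverage study; `--se/--sp/--n1/--n0` accept published summaries when the
subject-level data are unavailable, in which case cross-modality testing
is refused because the required covariances cannot be recovered.)

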