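# reachgain

Analysis of **rapid visuomotor response gains** in perturbed reaching.
When the visual feedback cursor of a reaching hand is abruptly displaced
("cursor jump"), an involuntary corrective response appears in the lateral
hand force within ~125 ms. This package asks a decision-theoretic question
of that reflex: does its gain track the *value* — reward × probability — of
the potential movement goals?

It is aimed at motor-control and psychophysics researchers who want a
tested, reusable version of this analysis: simulate the block designs of
three value-manipulation experiments, extract windowed response gains from
1 kHz force/acceleration traces, detect response-divergence onsets by ROC
analysis, fit hierarchical Bayesian gain models, and compare them with WAIC
and Bayes factors. Because raw data for this paradigm are typically not
deposited, a synthetic-data generator is a first-class part of the package:
every downstream stage is testable without any download.

## The models

A subject's response gain `G` (mean baseline-subtracted lateral force,
170–220 ms post-jump, positive = correction toward the center target) is
modeled as linear in a condition-level predictor `x`:

    G_{s,c} ~ Normal(alpha_s + beta_s * x_c, sigma)

with four candidate predictors built from the outer/center reward ratio
`R_O/R_C` and cue-probability ratio `P_O/P_C`:

| model          | predictor `x`                                   |
|----------------|--------------------------------------------------|
| probability    | `ln(P_O/P_C)`                                    |
| reward         | `ln(R_O/R_C)`                                    |
| value_neutral  | `ln(R_O P_O / (R_C P_C))`                        |
| value_risk     | `2[(1-w) ln(R_O/R_C) + w ln(P_O/P_C)]`, `w ∈ [0,1]` |

The risk weight `w` mixes the two log-ratios: `w = 0.5` reproduces the
risk-neutral relative value exactly, `w > 0.5` is risk-averse
(probability-dominated), `w < 0.5` risk-seeking (reward-dominated).
Subject-level `alpha_s`, `beta_s` (and `w_s`) are partially pooled under
group-level Gaussians with weak priors (Normal SD 10000 on group means,
half-Cauchy scale 5 on group SDs and the error scale); sampling is MCMC
via JAGS. Models are compared by WAIC (deviance scale) and pairwise Bayes
factors `K = exp(ΔWAIC/2)` with Kass–Raftery evidence labels.

Response-divergence onsets between two trace ensembles use signal
detection: the area under the ROC curve (aROC) at every 1 ms sample, the
series truncated once it exceeds 0.62 for three consecutive samples, a
dog-leg (flat at 0.5, then linear) fitted by exhaustive breakpoint scan,
and the onset taken as the later of the dog-leg breakpoint and the last
local minimum of the aROC curve.

## Worked example

Simulate a 10-subject cohort on the 8-condition value grid (reward and
probability ratios in {0.5, 1, 2}, excluding 1/1) with a risk-averse
generating weight `w = 0.68`, then fit and compare all four models:

```r
library(reachgain)
out <- run_value_pipeline(n_subjects = 10, seed = 1)
out$comparison
#> Gain model comparison (WAIC, deviance scale; K vs best model)
#>          model    waic p_waic k_vs_best       label r_squared
#>     value_risk -126.36 23.687 1.000e+00      (best)    0.9987
#>  value_neutral   72.58 13.044 1.579e+43 very strong    0.8684
#>    probability   84.36 16.049 5.700e+45 very strong    0.8358
#>         reward  192.13  9.537 1.443e+69 very strong    0.1626
```

The risk-sensitive value model wins decisively (lowest WAIC; the Bayes
factors against every alternative are "very strong"), and its group-level
risk weight recovers the generating value:

```r
fit <- out$comparison$fits$value_risk
fit$summary[fit$summary$parameter == "mu.w", ]
#>  parameter  mean     sd ci_2.5 ci_97.5 rhat
#>       mu.w 0.703 0.0549  0.622   0.838    1
```

Across conditions, hit-rate ratios (outer/center) fall as the corrective
gain toward the center grows — the behavioral signature that gain
modulation serves task success:

```r
out$hit_regression
#> $slope      -0.142
#> $p_value     1.5e-05
#> $r_squared   0.964
```

Onset detection on synthetic ensembles (36 trials/group, true divergence
at 150 ms; the estimator is deliberately conservative, so it lands a few
ms late):

```r
set.seed(1)
A <- t(sapply(1:36, function(i) synthesize_trace(0, onset = 150, noise_sd = 0.35)$value))
B <- t(sapply(1:36, function(i) synthesize_trace(1, onset = 150, noise_sd = 0.35)$value))
detect_onset(A, B, seq(-100, 400))
#> onset 164 ms (flat end 158, last local min 164)
```

Published WAIC scores can be compared directly:

```r
k <- waic_bayes_factor(7136, 7129)   # risk-neutral vs risk-sensitive value
round(k); evidence_label(k)
#> 33  "strong"
```

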