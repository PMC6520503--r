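---
title: "Value-sensitive visuomotor gains: models, simulator and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Value-sensitive visuomotor gains: models, simulator and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reachgain)
```

# The scientific problem

When a reaching hand's visual feedback cursor jumps sideways mid-movement,
an involuntary lateral force response appears within about 125 ms — long
before voluntary correction (~320 ms). `reachgain` analyzes whether the
*gain* of that rapid response is set by the expected value of the potential
movement goals: the rewards attached to the center and outer targets and
the probabilities with which each will be cued. The package covers the full
chain: simulating the three block designs that manipulate reward,
probability, or both; turning 1 kHz force/acceleration traces into windowed
response gains; locating response-divergence onsets by ROC analysis; and
fitting and comparing four hierarchical Bayesian models of the gains.

# The gain models

The windowed response gain of subject $s$ in block condition $c$ is

$$G_{s,c} \sim \mathrm{Normal}(\alpha_s + \beta_s x_c,\ \sigma),$$

with condition predictors built from the outer/center reward ratio
$r = R_O/R_C$ and jump-cue probability ratio $p = P_O/P_C$:
$x = \ln p$ (probability model), $x = \ln r$ (reward model),
$x = \ln rp$ (risk-neutral relative value), and the risk-sensitive value

$$x = 2\left[(1-w)\ln r + w \ln p\right], \qquad w \in [0,1].$$

**The factor 2 is a deliberate parameterization choice.** The risk-sensitive
form is a convex mixture of the two log-ratios; without rescaling, fixing
$w = 0.5$ would reproduce the risk-neutral predictor only up to a factor of
two absorbed by the slope. Doubling the mixture makes the reduction *exact*:
at $w = 0.5$ the risk-sensitive model has identical likelihood to the
risk-neutral one for every dataset, so the two models are strictly nested
and $w$ is interpretable on its own scale ($w > 0.5$ risk-averse /
probability-dominated, $w < 0.5$ risk-seeking / reward-dominated).
Swapping the outer and center labels negates every predictor.

## Priors and hierarchy

Group-level means have Normal(0, SD 10000) priors (the group risk-weight
mean additionally truncated to $[0,1]$, under which the weak prior is
effectively uniform); group SDs and the observation scale $\sigma$ have
half-Cauchy(scale 5) priors; a single $\sigma$ is shared across subjects.
Subject intercepts and slopes are Gaussian around the group means; the
subject risk weight is a Gaussian truncated to $[0,1]$ ("bounded
Gaussian"). Posterior sampling is MCMC in JAGS. The default schedule
mirrors the full analysis (adapt 1000, 30000 draws per chain, first 5000
discarded); `sampler_config(reduced = TRUE)` gives adapt 500 / 2000 draws /
500 discarded, which the package's own tests and the acceptance script use
so that a model fit costs about a second — the posterior means of
group-level parameters are stable at that length for the cohort sizes used
here (10 subjects × 8 conditions), though group-*scale* parameters
(`sd.beta`, `sd.w`) can show split-$\hat R$ slightly above 1.01 and the fit
then emits a warning rather than failing.

Four chains are run by default so that split-$\hat R$ is meaningful (each
chain is split in half; $\hat R$ uses the between/within variance of the
half-chains). Point estimates are posterior means — the quantity quoted for
the group risk weight — and the draw with the highest joint log-posterior
is also reported as an approximate MAP. Gains enter the fit
direction-pooled (mean of the left- and right-jump observations per
subject × condition) by default; per-direction fitting is available via
`pool = FALSE`.

# The synthetic-data generator

No raw data are deposited for this paradigm, so the generator defines the
study conditions under which everything is tested:

* **Trial schedules** reproduce the three designs exactly: 102-trial
  reward-manipulation blocks, 112/122-trial probability blocks, and
  136-trial value blocks (18 context + 108 cursor-jump + 10 unperturbed,
  with channel trials to outer targets only in the value design). The
  value grid crosses reward and probability ratios in $\{0.5, 1, 2\}$
  minus the $1/1$ cell — 8 conditions spanning 5 relative values
  $\{0.25, 0.5, 1, 2, 4\}$. Context trials are emitted first in fixed
  order; the rest are shuffled with the supplied seed. The value design's
  context count is fixed at 18 (the design allows 18–20; fixing it keeps
  schedules deterministic) and its context trials are simulated as
  unperturbed center-cued standard reaches. A small historical
  idiosyncrasy of the original value-design execution — one trial per
  block assigned to a wrong condition — is *not* emulated; intended
  probabilities are used.
* **Gains** follow the risk-sensitive linear model with subject-level
  heterogeneity. Defaults: group intercept 1.5 N, slope −0.8 N per
  log-unit (corrections weaken as the outer target's relative value
  rises), group risk weight 0.68 with between-subject SD 0.1, per-trial
  noise SD 0.5 N. A windowed gain observation averages 18 channel trials
  (the value design's count per condition × direction), so its SD is
  $0.5/\sqrt{18} \approx 0.12$ N. The per-trial noise magnitude and the
  intercept/slope scale are assumptions — trial-level noise is not
  published for this paradigm — chosen to give single-trial responses of
  realistic size relative to their variability (individual trials visibly
  noisy, occasionally direction-reversed; condition means well resolved).
* **Traces** are logistic ramps (onset default 125 ms, rise 60 ms),
  exactly zero before onset and rescaled so the 170–220 ms window mean
  equals the target gain *exactly* in the noise-free case, plus white
  Gaussian noise. Real force traces are not white-noise ramps — they have
  autocorrelated physiological noise, overshoot, and voluntary
  components after ~320 ms — so trace-level tests demonstrate pipeline
  correctness, not biological realism.
* **Hits** are Bernoulli with
  $P(\text{hit}) = \mathrm{logistic}(a + b\,g)$, where $g$ is the
  corrective gain toward the *cued* target (the negative of the
  toward-center gain when an outer target is cued). Only a linear trend
  between gains and hit-rate ratios is reported for this paradigm, so a
  logistic link is the minimal monotone choice; $b = 0.5$ per newton
  keeps simulated per-condition hit-rate spreads within roughly ten
  percentage points (the order of the reported high-vs-low-value
  differences), and $a$ is calibrated by root finding so the pooled
  standard-trial hit rate is 73.8%.

# Preprocessing choices

* **Filter**: 4th-order Butterworth at 50 Hz, applied forward–backward
  (zero phase). Only the cutoff is externally specified for this analysis;
  the order and zero-phase realization are the human-movement-analysis
  standard. Finite traces are padded by odd reflection (150 samples per
  end) before `filtfilt` so that edge transients die in the padding: DC
  passes to within $10^{-6}$, 10 Hz is attenuated < 1%, 200 Hz > 95%.
* **Differentiation** of filtered velocity to acceleration: central
  differences with the endpoint value replicated from its neighbor.
* **Baselines**: the per-subject mean unperturbed trace of the matching
  trial type (channel baselines for channel trials, standard for
  standard), subtracted pointwise.
* **Window**: 170–220 ms *inclusive* on both ends — 51 samples at 1 kHz.
* **Sign convention**: rightward-jump traces are negated before pooling,
  so positive always means correction toward the center target.
* **Display latency**: raw time axes aligned to the commanded jump can be
  shifted by the measured display latency (24 ms) with
  `latency_correct()`.

The whole chain is linear (affine once a fixed baseline is subtracted),
and gains extracted from noise-free synthetic traces equal the generating
gains to $10^{-9}$.

# Onset detection choices

The aROC at each sample is the Mann–Whitney statistic normalized to
$[0,1]$; ties count 0.5 (the standard convention — unspecified in the
original description). Truncation: "exceeds 0.62" is read as *strictly*
greater, and the kept series ends at the last pre-run sample. The dog-leg
fixes the flat level at 0.5 and constrains the linear component to be
continuous at the breakpoint (the flat line *is* the 0.5 level); the
breakpoint is found by exhaustive scan over sample times with ties broken
toward the earlier time, and the slope is the conditional least-squares
solution. A plateau flanked by higher values counts as a local minimum at
its last sample; a series with no interior minimum returns its start. If
the series runs below 0.5 on average (groups labelled opposite to the
divergence direction), it is reflected to $1 - \mathrm{aROC}$ before
fitting (`reflect = "auto"`).

Two properties of the procedure are worth knowing. First, it is
*deliberately conservative*: taking the later of the breakpoint and the
last local minimum biases estimates slightly late (in the package's
recovery study — 24 trials/group, plateau separation 1 vs per-sample noise
0.35, 20 replicates — the mean estimate sits ~10–14 ms after the true
150 ms onset, within the documented 15 ms tolerance). Second, the
0.62-for-3-samples truncation criterion sits only ~1.4 null SEs above 0.5
at 24 + 24 trials, so on *white-noise* ensembles a pre-onset false
truncation occurs in a few percent of runs; larger ensembles (36+ per
group, as obtained when pooling directions across blocks) make this rare.
The stricter historical criterion (0.75) is available via the `criterion`
argument.

# Model comparison choices

WAIC uses the variance-based penalty ($p_\mathrm{WAIC}$ = summed posterior
variance of pointwise log-likelihood) on the deviance scale, computed from
the fit's pointwise log-likelihood draws with a stabilized log-mean-exp;
it is cross-checked against an independent reference implementation in the
test suite. Pairwise Bayes factors are taken as
$K = \exp(\Delta\mathrm{WAIC}/2)$ — the deviance-scale analogue of an
evidence ratio — because this mapping reproduces all three published
factor values (33, 7, $>150$) from the published WAIC scores, which the
test suite asserts. Labels follow Kass–Raftery: 1–3 barely worth
mentioning, 3–20 positive, 20–150 strong, >150 very strong ($K < 1$
"negative"). $K$ is reported at full precision and rounded only for
display.

# Problem sizes and degenerate inputs

The test suite and acceptance script run cohorts of 10 subjects × 8
conditions × 2 directions at the reduced sampling schedule — sizes at
which a single fit takes about a second and the full four-model comparison
about four seconds, while group-level posterior means are already stable.
Degenerate inputs are handled explicitly: zero group SDs collapse
subject sampling to the group means; a zero-variance aROC series is
flagged `degenerate` with slope 0; an all-supra-criterion series truncates
to length zero (and the dog-leg then refuses to fit); single-condition or
single-subject gain tables are rejected before sampling; constant
predictors are rejected by the hit-rate regression.

# Known limitations

* The generator produces white observation noise and symmetric left/right
  responses; real data show autocorrelated noise, lateral asymmetries, and
  block-order effects that the package does not emulate. Passing recovery
  tests therefore demonstrates correctness of the estimation machinery
  under the assumed generative structure, not robustness to every
  real-data pathology.
* The risk-sensitive model's $w$ is only identified when conditions with
  $r \neq p$ exist and the slope is non-zero; on reward-only or
  probability-only designs it is not estimable.
* The MCMC engine is JAGS; group-scale parameters mix more slowly than
  they would under a Hamiltonian sampler, which is why the reduced
  schedule occasionally flags $\hat R$ on `sd.*` parameters. Increase
  `draws` (the full schedule comfortably passes $\hat R \le 1.01$) when
  those scales matter.
* Empirical onset times, WAIC values, $R^2$ and hit rates from the
  original experiments depend on the unpublished raw data; the package
  reproduces the *procedures* and the published arithmetic, and verifies
  statistical behavior on synthetic cohorts whose generating parameters
  are documented above.
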