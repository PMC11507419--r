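---
title: "Methods: a three-state panel Markov model for ADL disability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a three-state panel Markov model for ADL disability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adlmsm)
```

## The model

Disability in activities of daily living (ADL) is measured by a 20-item
scale, each item scored in [0, 1], and the total classified into three
ordered states: 1 = no disability (total exactly 20), 2 = mild (total in
[8, 20)), 3 = severe (total in [0, 8)). The classification boundaries are
exact — a total of 8 is mild, and only a perfect 20 counts as no
disability — because the states drive everything downstream; `adl_state()`
implements them and the test suite pins the boundaries.

The state process $S(t)$ is modelled as a time-homogeneous continuous-time
Markov chain on $\{1,2,3\}$ with generator $Q = (q_{rs})$, where for
$r \neq s$

$$ q_{rs} = \lim_{\Delta t \downarrow 0}
   \Pr\big(S(t+\Delta t)=s \mid S(t)=r\big) / \Delta t $$

and $q_{rr} = -\sum_{s \neq r} q_{rs}$, so rows sum to zero. All six
off-diagonal transitions are allowed: there is no absorbing state (cohorts
this model targets exclude deceased participants at ingestion rather than
modelling mortality), and both deterioration and recovery are observed in
practice. The interval transition probability matrix is the matrix
exponential $P(\Delta t) = e^{Q\,\Delta t}$, computed by
scaling-and-squaring with Padé approximation (`Matrix::expm`); the test
suite checks it against an independent truncated power-series oracle to
1e-10 and verifies the Chapman–Kolmogorov property to 1e-8 on random
generators.

Covariates $z$ act proportionally on each intensity,

$$ q_{rs}(z) = q_{rs}^{(0)} \exp(\beta_{rs}^\top z), $$

the intensity-scale analogue of a proportional hazards model; $e^{\beta}$
is a hazard ratio (HR) specific to one transition. Each covariate receives
its own coefficient on each of the six transitions by default;
`covariate_transitions` can restrict that. Time-varying covariates (age)
are evaluated at the start of each observation interval and held constant
across it — the conventional piecewise-constant treatment in panel
multi-state models, and annual assessments provide no finer resolution.

## Likelihood and estimation

Assessments at times $t_0 < t_1 < \dots$ give interval-censored panel
data: transitions between assessments are unobserved. Each consecutive
pair (state $r$ at $t_{j-1}$, state $s$ at $t_j$) contributes
$\log P_{rs}(t_j - t_{j-1};\, z_{j-1})$, and the log-likelihood sums these
over subjects and pairs. Intervals need not be equally spaced; the actual
gap enters the exponential and missing intermediate waves need no
imputation. Pairs sharing an (interval length, covariate pattern)
combination share one matrix exponential; the grouped evaluation is
contractually identical to the naive per-pair sum (tested against a
brute-force oracle on small datasets).

Baseline intensities are parameterised as $\theta_{rs} = \log q_{rs}^{(0)}$,
which enforces positivity without constrained optimisation and makes
normal-theory intervals for $e^{\beta}$ natural. Optimisation is BFGS
(`stats::optim`) from moment-style starting values
$q_{rs}^{\text{init}} = n_{rs} / (n_{r\cdot} \bar{\Delta t})$ floored at
1e-4 (`crude_initial_estimates()`), with relative convergence tolerance
1e-10, an iteration cap of 500, and the gradient max-norm at the optimum
reported as a diagnostic. The covariance matrix is the inverse of the
numerically differenced observed information (`stats::optimHess`); when the
information is singular — typically a transition with essentially no
events — estimates are still returned and the covariance is omitted with a
warning. Wald 95% intervals are $\exp(\hat\beta \pm 1.96\,\widehat{SE})$;
no multiplicity adjustment is applied across the HR table cells, and this
is deliberate: the table is descriptive, and users can apply `p.adjust` to
the `p` column if they need familywise control.

Two estimation questions were genuinely open and resolved as follows.
Age is time-updated at each interval start (the generator also ages its
subjects deterministically between waves); a baseline-age-only analysis
can be had by passing a frozen age column. Confidence intervals are Wald
on the log scale; profile intervals are out of scope.

Numerical edge cases: a probability that underflows to zero for an
observed pair makes `panel_loglik()` return $-\infty$ with an explanatory
attribute (never an exception inside the optimizer, which sees a large
finite penalty instead); intensities are capped at $e^{50}$ per year
during optimisation to keep the exponential finite; tiny negative entries
from the matrix exponential are zapped to 0.

## Synthetic cohorts

Because registry data of this kind are access-restricted, the package
ships a generator (`generate_cohort()`) whose defaults emulate a large
urban cohort of older adults with chronic diseases: 9,091 subjects, four
annual waves, baseline state mix 51.2/26.8/22.0%, age truncated-normal
(mean 77.87, sd 9.22, minimum 60), 41.6% male, 60.1% home-based, 94.9%
with pensions, 51.6% with co-morbidity, education levels 1–5 in
proportions 859/2487/2575/2257/913 of 9,091. The default generating
intensities (q12 = 0.2764, q13 = 0.0003, q21 = 0.4731, q23 = 0.2226,
q31 = 0.0068, q32 = 0.1204 per year) represent annual dynamics typical of
such a cohort. These defaults are fixed study conditions, not tuning
knobs.

Trajectories are simulated exactly (Gillespie): sojourns are exponential
with rate $-q_{rr}$, jump destinations follow the embedded chain, and the
latent path is read at the wave times under the right-continuous
convention — so the generated data carry genuine interval censoring.
Baseline states are drawn independently of covariates by default (only the
margins of the joint baseline table are published for cohorts like this;
an explicit `beta` configuration lets tests create covariate-modulated
dynamics deliberately, and by default `beta = NULL`, i.e. covariates do not
modulate intensities). Wave missingness is independent across waves with
at least two observations always retained; real missingness is likely
correlated within subjects, which the generator does not emulate. Each
subject draws from a deterministically derived sub-stream of the seed, so
enlarging the cohort never reshuffles earlier subjects.

What passing tests on these cohorts shows: the likelihood, optimizer,
standard errors and prevalence machinery are correct under the model. What
it does not show: robustness to misclassified states, informative
missingness, non-Markov dependence or unmodelled heterogeneity in real
registry data.

## Goodness of fit

`expected_prevalence()` propagates every subject's baseline state through
the fitted $P(t)$ (covariate-aware by default; `marginal = TRUE` pools).
The risk set at time $t$ is subjects whose last observation is at or after
$t$ — with no absorbing state there is no other natural attrition rule;
times beyond the study's last observation are propagated for the whole
cohort and flagged as extrapolation.
Observed and expected percentage curves are combined by `gof_report()`,
whose headline number is the maximum absolute percentage-point gap per
state; `plot()` draws the familiar per-state observed-vs-expected curves.
Expected percentages are convex combinations of probability rows, so they
always lie in [0, 100] and sum to 100.

## Problem sizes used in validation

The validation suite exercises cohorts of 5,000 subjects × 4 annual waves
for parameter recovery (20 seeds; the four well-identified intensities
q12, q21, q23, q32 are recovered with median relative error under 10%),
hazard-ratio CI coverage with a generating HR of 4.65 on the sparse 1→3
transition (20 replicates; the Wald CIs there are wide, as the tiny
baseline q13 = 0.0003 provides little information, and coverage is
correspondingly conservative), and prevalence self-consistency (observed
vs expected within 3 percentage points per state per wave). Smaller
cohorts (hundreds of subjects) back the unit tests. q13 itself is
recovered only to order of magnitude at these scales — an intensity of
0.0003/year produces a handful of direct transitions even in 15,000
intervals — and the documentation flags it accordingly.

## Known limitations

Time-homogeneous intensities (no calendar or duration effects); no hidden
states or misclassification; no absorbing state, so mortality-related
attrition must be handled upstream; Wald inference only; the full
six-covariate multivariate fit with continuous age creates one covariate
pattern per subject, which defeats the expm-sharing optimisation and is
correspondingly slower than fits with discrete covariates.
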