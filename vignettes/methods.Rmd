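---
title: "Methods: a continuous-time hidden Markov model for biomarker surveillance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a continuous-time hidden Markov model for biomarker surveillance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(galadhmm)
```

## The surveillance problem

Patients at high risk of hepatocellular carcinoma (HCC) — typically with
cirrhosis — attend screening visits at irregular intervals over several
years. At each visit a scalar serum score (here the GALAD score, a
combination of AFP, AFP-L3, DCP, age and sex, treated by this package as an
opaque biomarker) may be recorded, and standard clinical work-up may or may
not diagnose a tumour. The tumour's *onset* is never observed: diagnosis
lags onset by months to years, so an undiagnosed visit is not evidence of
absence. The package models the onset day directly, which is what makes
prospective per-visit risk scoring possible for patients who, by
construction, have no diagnosis yet.

## Generative model

For patient $i$ at visit $j$ with day offset $t_{ij}$ ($t_{i1}=0$):

* **Scores.** $B_{ij} \mid \mu_{ij},\sigma^2 \sim N(\mu_{ij},\sigma^2)$ with
  $\mu_{ij} = \nu + b_i + C_{ij} S_i \beta (t_{ij}-\tau_i)$ and
  $b_i \sim N(0, \sigma_b^2)$. Missing scores contribute nothing to the
  likelihood (omission, never imputation), at every layer of the package.
* **Latent state.** $C_{ij} = I(\tau_i < t_{ij})$; the two-state chain is
  absorbing, with per-interval transition probability
  $1-e^{-\lambda_i \Delta t}$ and hazard
  $\log \lambda_i = \zeta + \xi b_i$: a patient with a high baseline score
  level is also at higher onset risk. $C$ is defined at visit times only;
  between visits the state is carried by the exact onset day $\tau_i$,
  uniform within its transition interval.
* **Responder mixture.** $S_i \sim \text{Bernoulli}(p_S)$; non-responders
  ($S_i=0$) keep a flat trajectory despite a tumour, which caps the
  sensitivity of any trend-based rule.
* **Diagnosis.** $D_{ij} \mid C_{ij}=1 \sim
  \text{Bernoulli}(1-e^{-\delta (t_{ij}-\tau_i)})$ and
  $P(D_{ij}=1 \mid C_{ij}=0)=0$: no false positives, false negatives
  expected. Likelihood contributions stop at the first positive visit;
  later follow-up is censored, mirroring how surveillance databases are
  cleaned.

### Parameters, units, defaults

| parameter | meaning | units | reference value |
|---|---|---|---|
| `beta`    | post-onset slope (responders)      | score/day | 0.00604 |
| `sigma`   | within-patient score SD            | score     | 0.460 |
| `sigma_b` | between-patient baseline SD        | score     | 1.805 |
| `nu`      | population mean baseline           | score     | -3.218 |
| `zeta`    | log onset hazard at average baseline | log(1/day) | -10.123 |
| `xi`      | hazard coefficient on baseline     | 1/score   | 0.445 |
| `delta`   | diagnosis hazard after onset       | 1/day     | 0.000312 |
| `p_s`     | responder probability              | —         | 0.656 |

`default_parameters()` returns these reference values, posterior means from
fitting the model to a large Japanese hospital surveillance cohort; they are
the simulator's default operating point. Time is measured in days
throughout; "6 months" is 182.5 days and "1 year" 365 days, the conventions
under which `derived_quantities_report()` reproduces the familiar plug-in
numbers (e.g. a 6-month onset probability of 0.0073 at the average
baseline). The three-month value uses 91.25 days; plugging the posterior
means into the closed form gives 0.028, and we make no attempt to force the
rounded published-style 0.029, which plausibly came from averaging the
transformation over posterior draws rather than transforming the mean.

The vague priors in `default_prior_spec()` are uniforms
$\beta \sim U(0,0.1)$, $\sigma, \sigma_b \sim U(0,100)$,
$\delta \sim U(0,0.15)$, $\zeta \sim U(-60,0)$, $\xi \sim U(-1,5)$, a Beta
$(0.5, 0.5)$ on $p_S$, and $\nu \sim N(0, h_\nu)$ where **`h_nu` = 1000 is
a variance** (SD ≈ 31.6), not a precision — a deliberate and documented
choice, since precision-parameterized software makes this an easy trap.

## What the synthetic cohort emulates — and what it does not

`simulate_cohort()` draws visit schedules with gamma-distributed gaps
(default mean 120 days, coefficient of variation 0.4, 5-year follow-up),
yielding roughly 15 visits per patient, with 25% of scores missing and
post-diagnosis visits truncated — matching the structure of the motivating
cohort (about 5% of patients diagnosed over five years). Onset is simulated
in continuous time as an exponential waiting time, which is exactly
consistent with the absorbing-chain transition probabilities at any visit
grid. Two caveats follow:

* Within a transition interval the generative onset day is
  truncated-exponential while the model's prior is uniform; at hazards of
  order $10^{-4}$/day the difference is negligible, but test oracles that
  compare against simulation must simulate from the *model's* latent prior
  (interval by chain probabilities, day uniform within it), which the test
  helpers do.
* The simulator does not emulate covariates (age, sex, aetiology), death as
  a competing risk, or calendar effects. Passing tests therefore certify
  the inference machinery under the model's own assumptions, not the
  clinical performance of the method on real data, whose operating points
  cannot be reproduced from synthetic cohorts.

## Numerical and design choices

* **Impossible states return `-Inf`, never raise.** Density code signals
  contradictions (a diagnosis without a tumour, an onset day outside its
  interval) with `-Inf` so samplers reject gracefully; constructors, by
  contrast, validate eagerly.
* **Tumour present at the very first visit.** The hazard clock starts at
  the first visit, so onset strictly before it carries no prior mass; the
  degenerate convention $\tau = 0$ (point mass, no density contribution)
  exists for data that force it. A record diagnosed at day 0 has zero
  likelihood under the model — `fit_mcmc()` refuses it by name.
* **Marginal-likelihood oracle.** `patient_marginal_loglik()` integrates
  $b$ by *adaptive* Gauss–Hermite quadrature (nodes centred and scaled by
  the Laplace approximation to the conditional posterior of $b$; plain
  Gauss–Hermite converges far too slowly once a few scores pin $b$ down),
  enumerates $S$ and the onset interval, and integrates the onset day by
  Gauss–Legendre. Defaults: 40 and 15 nodes; orders below 3 are refused.
* **Sampler.** The latent path is reparameterized as (onset interval,
  onset day) — equivalent to sampling the monotone path but with far better
  mixing than per-visit flips. Each sweep updates, vectorized across
  patients (valid because patients are conditionally independent given the
  parameters): a joint interval/day proposal restricted to intervals
  compatible with any observed diagnosis, a day refresh, a closed-form
  Gibbs draw of $S$, and a random-walk update of $b$. Parameter blocks use
  random walks on log scales for $\beta, \sigma, \sigma_b, \delta$, a
  joint bivariate walk for the strongly coupled $(\zeta, \xi)$ pair with a
  proposal Cholesky adapted from the chain history, a conjugate Beta-Gibbs
  draw of $p_S$, and — crucial for mixing — a recentering move that shifts
  $\nu$ and all $b_i$ in opposite directions, leaving every score mean
  invariant. Proposal scales follow a Robbins–Monro rule toward 30%
  acceptance during the adaptation phase and are frozen afterwards; this
  is our analogue of the reference implementation's unspecified adaptation
  stage. Initialization: parameters at prior midpoints, latents at "no
  onset" except where a diagnosis forces one (day set mid-interval before
  the first positive visit).
* **Run lengths.** `mcmc_config()` defaults to the training-stage
  2 × 45,000 iterations with 7,500 burn-in; `mcmc_config_fast()`
  (2 × 4,000, 1,000 burn-in, 1,000 adaptation) is the preset used in the
  test suite and is sufficient for cohorts of a few hundred patients.
* **Convergence.** `gelman_rubin()` implements the classic (non
  rank-normalized) potential scale reduction factor; values below 1 from
  finite-sample noise are truncated to 1.
* **Prediction.** Per the method's design, prediction removes the
  diagnosis factor (a prospective patient has none) and the responder
  mixture (a flat-trajectory tumour is indistinguishable from no tumour,
  and letting $S$ compete with $C$ for the same evidence destabilizes the
  probability), and fixes $S = 1$. Informative priors are moment-matched
  from training draws: gammas for $\sigma, \sigma_b$, a normal for $\beta$
  — truncated at 0 when sampling, a guard that matters only in the extreme
  tail — and a trivariate normal for $(\nu, \zeta, \xi)$ whose spread may
  be supplied as a precision matrix (`cov_is_precision = TRUE`, the form in
  which such matrices are conventionally printed; `default_predictive_priors()`
  uses it). Each visit is refit independently on the patient's history
  only — deterministic given the seed, with per-(patient, visit) seeds
  derived so that editing later visits can never alter an earlier
  prediction. An exact mode (`predict_visit_exact()`) integrates the
  latents by the same quadratures and the parameters by prior Monte Carlo;
  it is the test oracle, not the production path.
* **Evaluation.** Sensitivity is per patient (any detection at or before
  the diagnosis visit; flags after diagnosis are ignored as clinically
  meaningless); specificity comes in per-patient and per-observation
  flavours over never-diagnosed patients; timeliness is the mean lead time
  of the earliest detection that persists through diagnosis, over patients
  that have one. ROC grids sweep the observed score values; in the
  per-observation kind the area equals the Mann–Whitney concordance
  statistic exactly, which the tests assert to 1e-12. `best_cutpoint()`
  breaks ties toward the larger cut-point (fewer detections). The two-year
  test-set exclusion window drops the trailing visits of never-diagnosed
  patients, anchored at each patient's original last visit so the filter
  is idempotent; we also apply the window's denominator to per-observation
  specificity, since the window is applied to the test set before any
  evaluation.

## Problem sizes used by the test suite

Chosen as a balance between statistical power and a suite that runs in
minutes: parameter recovery fits a 300-patient cohort under the fast
preset; simulation-based calibration runs 50 replicate fits of 12-patient
cohorts under narrowed priors (scale parameters drawn slightly off the
origin to avoid degenerate cohorts); the latent-conditional checks run
20,000-iteration single-patient chains against enumeration oracles; the
prediction-vs-threshold comparison scores a 50-patient cohort (about 650
per-visit refits at reduced iteration counts); calibration of the
predictive probabilities uses 30 patients generated from the reduced
model's own prior. Monte-Carlo comparisons use 3 standard errors
(batch-means errors for chains, binomial for frequencies); exact identities
use 1e-12.

## Known limitations

* The predictive probabilities are calibrated against the *reduced* model's
  world. Against the full generative truth they under-state risk for
  non-responder tumours (the mixture is removed by design), so the lowest
  probability bins look anti-conservative in full-model simulations; this
  is a property of the method, not of the implementation.
* In a synthetic world with a strong baseline–hazard link, the raw score
  itself is a genuinely informative classifier (high-baseline patients
  really are at higher risk), so the model's advantage over a fixed
  threshold concentrates where it matters clinically: per-observation
  specificity at high per-patient sensitivity.
* $\xi$, $\delta$ and $p_S$ are weakly identified in cohorts of a few
  hundred patients with a handful of diagnoses; their intervals are honest
  but wide, and the responder fraction among *diagnosed* patients drives
  $p_S$ far more than the cohort-wide responder rate.
* Diagnosis hazard is constant in time; covariates enter nowhere; a single
  biomarker is modelled. These are scope boundaries, not oversights.
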