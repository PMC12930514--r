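---
title: "Weighted multi-site partitioned survival modelling for tumour-agnostic therapies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted multi-site partitioned survival modelling for tumour-agnostic therapies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(basketpsm)
```

## The decision problem

Therapies approved on a molecular biomarker rather than a tumour site
("tumour-agnostic" indications) break the one-tumour, one-comparator,
one-model pattern of oncology health-technology assessment. The eligible
population is a mixture of tumour sites with different baseline
prognoses, standards of care, resource use and — often — different
treatment effects, and the pivotal evidence typically comes from small
single-arm basket trials. `basketpsm` implements a cost-effectiveness
framework for this situation: one three-state partitioned survival
model (PSM) per tumour site, combined through epidemiological weights
into a single aggregated incremental cost-effectiveness ratio (ICER),
with the ability to "break out" a site into its own dedicated submodel
as its evidence matures, and with deterministic and probabilistic
sensitivity analysis that distinguishes shared from site-specific
parameters.

## The per-site model

Each site submodel is a conventional three-state PSM. Given an overall
survival curve $OS(t)$ and a progression-free survival curve $PFS(t)$,
state occupancy is read directly off the curves, with no explicit
transition probabilities:

$$
\pi_{\text{pf}}(t) = \min\{PFS(t),\, OS(t)\},\qquad
\pi_{\text{pd}}(t) = OS(t) - \pi_{\text{pf}}(t),\qquad
\pi_{\text{dead}}(t) = 1 - OS(t).
$$

Because OS and PFS are extrapolated independently, the fitted curves can
cross; `compute_occupancy()` repairs a crossing by the `min()` clip and
reports how many grid points were affected rather than failing — the
crossing is a diagnostic about the extrapolation, not a reason to halt a
whole multi-site analysis.

Six parametric families are supported for extrapolation (exponential,
Weibull, Gompertz, log-normal, log-logistic, generalized gamma), fitted
by maximum likelihood to right-censored patient-level data
(`fit_parametric()`, delegating the optimisation to `flexsurv` with
positive parameters handled on the log scale). `select_distribution()`
ranks candidates by AIC with ties broken by parsimony; the ranking is
deliberately advisory, since visual fit and clinical plausibility of
the extrapolated tail are part of distribution selection and cannot be
automated. The generalized gamma, whose likelihood surface is the least
well behaved, is given up to three starting points.

Where only published curves exist, `reconstruct_ipd()` rebuilds
pseudo-individual-patient data from digitised Kaplan–Meier step
coordinates and numbers-at-risk tables using the standard
interval-by-interval algorithm: candidate censoring counts are spread
uniformly within each risk-table interval and adjusted until the implied
numbers at risk match the published table, and event counts then follow
from the published survival drops. The at-risk convention is
$n(t) = \#\{\text{subjects with observed time} \ge t\}$. When the
reported total event count is supplied, censoring in the final interval
is recalibrated toward it; integer rounding can leave a residual
discrepancy of a patient or two, and the implementation keeps the best
allocation encountered rather than oscillating. A round-trip check
(reconstruct, re-estimate, compare) is part of the test suite, with
sup-distance tolerance 0.02 on the survival scale.

Long-term extrapolations can imply better survival than the general
population. `apply_background_mortality()` enforces consistency by the
hazard-max convention: at every cycle the applied hazard is
$\max\{h_{\text{model}}, h_{\text{pop}}\}$, where the population hazard
comes from a life table (annual probabilities converted to monthly
hazards via $h = -\ln(1-q)/12$) collapsed over sex by the cohort's sex
mix. Hazard-max — rather than additive excess hazard — guarantees the
adjusted curve never exceeds the population survivor curve, and it is
idempotent. By default the adjustment applies to OS only; PFS is then
capped at the adjusted OS inside the engine, since applying population
mortality separately to a progression endpoint has no clean
interpretation.

### Economics

Time is in months throughout; the default grid is 1-month cycles over a
480-month (lifetime) horizon, and the built-in scenarios use 240 months
because their hazards make survival past 20 years negligible.
Per-cycle state membership is the trapezoid average of occupancy at the
cycle boundaries, so area-under-curve life-years converge at second
order in the cycle length (halving the cycle moves QALYs by well under
1% for smooth inputs). Discounting is discrete annual-rate with monthly
exponent, $(1+r)^{-t/12}$, with separate cost and effect rates
(default 3%) and an optional half-cycle correction that discounts at
cycle midpoints. Costs comprise drug and administration (accrued while
progression-free and on treatment, optionally capped at a fixed number
of treatment cycles — by default treatment runs until progression),
state-specific disease management, a one-off adverse-event cost at
model start, and an end-of-life cost attached to incident deaths within
the horizon (survivors at the horizon are never charged a terminal
cost). QALYs apply state utilities in $[0,1]$ to the same occupancy.

The incremental comparison classifies the usual quadrants: an ICER is
only reported when defined; gaining health at no extra cost is
*dominant*, losing health at no saving is *dominated*, and a zero
QALY difference leaves the ratio undefined. Net monetary benefit
$\lambda\,\Delta E - \Delta C$ is always reported.

## Weighted aggregation — the central rule

The framework's core rule is that weights are applied to incremental
costs and QALYs, never to ICERs, because ratios cannot be meaningfully
averaged. With site weights $w_i$ (non-negative, summing to one):

$$
\Delta C_{\text{agg}} = \sum_i w_i\, \Delta C_i,\qquad
\Delta E_{\text{agg}} = \sum_i w_i\, \Delta E_i,\qquad
\text{ICER}_{\text{agg}} = \Delta C_{\text{agg}} / \Delta E_{\text{agg}}.
$$

The distinction is not cosmetic. Two sites with
$(\Delta C, \Delta E) = (100{,}000,\ 2.0)$ and $(50{,}000,\ 0.5)$ and
equal weights give site ICERs of 50,000 and 100,000; their mean is
75,000, but the aggregated ICER is $75{,}000 / 1.25 = 60{,}000$.
When every $\Delta E_i > 0$ the aggregated ICER is a weighted mediant
and always lies between the smallest and largest site ICER — a property
the test suite checks on a thousand randomised draws.

Weights default to each site's biomarker-positive count
(`normalize_weights()`); trial-enrolment counts are accepted as an
alternative source, with the choice echoed in output metadata, because
neither source is canonically right: population epidemiology reflects
the reimbursement population, trial composition reflects the evidence.

## Pooling, break-out and versioning

Under sparse evidence all sites share survival curves fitted to the
*stacked* patient-level data of the pooled sites (one fit per arm and
endpoint). Stacking, rather than averaging fitted curves, was chosen
because it makes the pooled estimate an ordinary maximum-likelihood fit
with a covariance usable in sensitivity analysis, and it is testable:
when sites genuinely share baseline hazards and treatment effect, the
pooled and fully site-specific models must agree up to sampling noise.
The converse also holds — when baselines differ, pooled fitting is a
deliberate borrowing assumption, and that is exactly the situation
`breakout()` addresses: the named site switches to its own inputs while
every structural setting (grid, discounting, conventions, weights)
stays shared, and a new model version is appended to an append-only log.
Each version stores a snapshot sufficient to reproduce its results
exactly; `diff_versions()` reports per-site and aggregate changes so a
re-analysis shows precisely how new evidence moved the answer.
Re-analysis timing uses the one trigger that is concretely specifiable,
a sample-size rule (`check_reanalysis_triggers()`): a site is due when
its site-specific evidence has grown by at least `min_new_n` subjects
since the last version. The default of 50 is an explicit placeholder —
no evidence-based threshold exists — and should be set per decision
problem.

## Uncertainty

`run_psa()` distinguishes *shared* parameters (drawn once per iteration
and written to every site — assumptions the sites have in common must
move together, otherwise between-site correlation is silently lost)
from *site-specific* parameters (drawn independently). Only these two
extremes are implemented; partial sharing (cross-site correlation
between 0 and 1) is a recognised gap. Utilities use beta distributions,
costs gamma, log-normal or normal (negative normal draws truncated at
zero). Survival-parameter uncertainty propagates through a multivariate
normal on the estimation scale using the fitting covariance; a draw
whose back-transformed parameters fall outside the family's domain is
rejected and redrawn, with the count logged (with log-scale positive
parameters this is essentially never triggered). Pooled fits are
sampled once per iteration and shared by construction, which keeps the
pooled sites' survival uncertainty jointly varied. CEAC probabilities
are the fraction of iterations with strictly positive net monetary
benefit (ties count against the intervention). `dsa()` produces a
tornado table sorted by aggregate NMB range. PSA means are reported
alongside the deterministic base case, both labelled, rather than
choosing one.

Alternative distribution families and other structural choices are
handled as named scenarios (separate runs of the model), not sampled
probabilistically.

## The synthetic evidence generator

`generate_basket_trial()` exists so every part of the framework is
testable without any external data. Each synthetic subject has three
latent exponential clocks: progression, death before progression, and
death after progression. Death time is the pre-progression death time
if it comes first, otherwise progression time plus the post-progression
survival draw — so PFS $\le$ OS holds for every subject by
construction, which independent marginal simulation would not
guarantee. Marginal PFS is exactly exponential with the sum of the
progression and pre-progression death hazards; when the two death
hazards are equal, marginal OS is exactly exponential too (used by the
parameter-recovery tests, where the fitted family must be correctly
specified for recovery to be the thing under test). Censoring is the
minimum of an exponential dropout draw and an administrative cut-off,
shared between a subject's OS and PFS records.

Three built-in scenarios fix the study conditions: `homogeneous_effect`
(three sites, identical baseline hazards — progression 0.09/month,
death 0.02 before and 0.10 after progression — and a common hazard
ratio of 0.6; 200 subjects per arm per site; biomarker-positive counts
75/45/30), `heterogeneous_effect` (site-specific baselines and one site
with hazard ratio 1.0), and `small_n_site` (one site with 10 subjects
per arm). Dropout is 0.01/month with administrative censoring at
30 months; default costs and utilities are typical of targeted oncology
therapy (5,000 per cycle drug cost against 1,200 for comparator
therapy, utilities 0.75 progression-free and 0.55 progressed,
willingness to pay 100,000 per QALY).

What the generator deliberately does *not* emulate: non-proportional
or time-varying effects, cure fractions, dependent censoring,
diagnostic misclassification of biomarker status, and real digitisation
noise beyond monotone wobble. Passing tests therefore demonstrate that
the machinery is correct under clean, correctly specified conditions —
not that any particular extrapolation of real trial data is right. One
consequence is visible in the built-in scenarios themselves: their OS
marginal is *not* exponential (death hazards differ before and after
progression), so the default exponential fit is misspecified in the
tail, and the fitted aggregate ICER differs noticeably from the ICER of
the true curves. That bias is a property of parametric extrapolation
under censoring, the tests treat it as such, and comparisons made under
one shared fitting choice (e.g. pooled versus broken-out) remain valid.

## Numerical choices and problem sizes

Tie-breaks in distribution ranking go to fewer parameters, then to the
canonical family order. Degenerate inputs: an exhausted survival curve
(zero survivors) contributes infinite hazard and stays at zero through
background adjustment; all-censored data refuse to fit (the likelihood
is unbounded); all-zero weights refuse to normalise. The test suite
sizes were chosen to keep the full run in tens of seconds on one CPU
while retaining power: parameter recovery uses 2,000 subjects and 100
replicates per family (within 3 standard errors at least 95% of the
time), KM round trips use 50-200 subjects with 0-30% censoring,
the mediant-bound property uses 1,000 randomised draws, CEAC is
checked against a closed-form bivariate-normal probability at 10,000
draws, and the end-to-end recovery check uses 2,000 subjects per arm
per site over 20 seeds. The pooled-versus-broken-out agreement
tolerance under the homogeneous scenario was fixed at 15% before
running the check, roughly twice the per-site sampling coefficient of
variation of the incremental QALY at 200 subjects per arm.

## Known limitations

No treatment sequencing or post-progression therapy lines (a structural
limit of partitioned survival analysis generally); no spline or
cure-fraction extrapolation; no covariate-adjusted survival models; no
equity weighting beyond reporting disaggregated per-site results; no
expected-value-of-information analysis; reconstruction tolerances are
not propagated into the PSA.
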