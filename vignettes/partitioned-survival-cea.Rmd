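---
title: "Partitioned survival cost-effectiveness modelling with psmcea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioned survival cost-effectiveness modelling with psmcea}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psmcea)
```

## The model

`psmcea` implements the standard three-state partitioned survival model
(PSM) used in oncology health-technology assessment. A cohort starting
treatment is allocated at every time point among progression-free (PF),
progressed disease (PD) and death, directly from the progression-free
survival (PFS) and overall survival (OS) curves:

* PF(t) = min(PFS(t), OS(t))
* PD(t) = max(0, OS(t) − PFS(t))
* dead(t) = 1 − OS(t)

Unlike a Markov model, no transition probabilities are estimated: the
survival curves *are* the model. The min/max clipping matters in practice
because independently fitted parametric PFS curves can cross above OS in
the far tail; the partition then keeps occupancies non-negative and summing
to one, which the test suite asserts on every cycle.

The trade-off of a PSM is well known: it cannot represent post-progression
treatment effects or structural dependence between endpoints, and it
extrapolates each curve on its own. We accept those assumptions because the
data situation the package targets — published Kaplan–Meier figures from
single-arm or small randomized trials, no individual patient data (IPD) —
does not support anything richer.

## From published figures to curves

Three modules produce the survival curves the engine consumes.

**Synthetic trial data.** `sim_spec()`/`simulate_ipd()` simulate
right-censored records from a known parametric truth with uniform accrual,
an administrative cutoff and exponential dropout. This exists so that every
downstream stage — digitization, reconstruction, fitting, extrapolation —
can be tested against a ground truth without any external data.
`digitize_km()` then emulates what a plot digitizer yields from a published
figure: step-function coordinates plus a periodic number-at-risk table.
Reading error is modelled as additive uniform noise on the survival axis
(default 0), followed by isotonic (non-increasing) repair; this choice lets
round-trip tests quantify digitization error exactly. What the generator
does **not** emulate: pixel quantization, axis-calibration bias, overlapping
curve confusion, or at-risk tables that disagree with the plotted curve by
more than reading error. Passing round-trip tests therefore show the
algorithms are faithful to clean digitizer output, not that any particular
published figure was digitized accurately.

**Pseudo-IPD reconstruction.** `reconstruct_ipd()` inverts the
product-limit estimator interval by interval, solving iteratively for the
censoring count per number-at-risk interval such that the implied survival
drops match the digitized curve and the implied at-risk count matches the
published table — the approach introduced for reconstructing IPD from
published Kaplan–Meier figures. Design choices where the method is
genuinely open:

* censoring times are spread evenly within each interval (the convention of
  the published algorithm);
* non-integer event counts are serialised by cumulative-remainder rounding
  (emit `round(cumulative) − emitted`), which conserves interval totals by
  construction;
* a residual ±1–2 subject mismatch — an unavoidable artifact of integer
  rounding — is absorbed into the interval's event counts; anything larger
  means the curve and the risk table genuinely contradict each other
  (the curve implies more exits than the table allows) and raises a
  classed error rather than being repaired silently. With reading noise
  around 0.01 on the survival axis reconstruction succeeds; at 0.02–0.03
  genuine contradictions begin to appear, which is the flagged case.

**Parametric fitting.** `fit_mle()` maximizes the censored log-likelihood
Σ events log f(t) + Σ censored log S(t) over eight parameterizations:
exponential, gamma, generalized gamma (μ, σ, Q; Q = 0 reduces to
log-normal), Gompertz, Weibull in both accelerated-failure-time and
proportional-hazards forms, log-logistic and log-normal. Both Weibull forms
are first-class because published parameter tables mix them — an AFT scale
of ~22 months and a PH scale of ~0.02 describe similar hazards, and
silently assuming one convention misreads the other by three orders of
magnitude. The optimizer is multi-start BFGS on log-transformed positive
parameters with moment-based starts, followed by a damped Newton polish:
BFGS alone stops on a relative function-value criterion and can leave a
gradient norm around 1e-4, which fails closed-form checks (the exponential
MLE is events/total time to machine precision; the suite asserts agreement
to 1e-8). Standard errors come from the inverse observed information with a
delta-method map back to the natural scale. `select_model()` ranks
converged fits by AIC or BIC (ties: the other criterion, then fewer
parameters); BIC uses n = total record count, the standard convention for
censored data. Model selection on real extrapolation problems should still
involve visual and clinical judgement; the ranking is an input to that
judgement, not a substitute.

**Hybrid curves.** `hybrid_curve()` joins an observed KM segment on
[0, t\*] to a parametric tail rescaled for continuity:
S(t) = KM(t\*) · S_tail(t)/S_tail(t\*) for t > t\*. With `switch_time = 0`
the curve is purely parametric. The shipped base case uses pure-parametric
curves: the KM segments behind a published analysis are digitized from
figures and not themselves published, so the parametric fits are the only
reproducible specification. This choice has one important consequence for
uncertainty analysis, discussed below.

## The worked base case

The configuration returned by `base_config()` is a lifetime (40-year)
comparison of pemigatinib, an oral FGFR2 inhibitor for advanced
intrahepatic cholangiocarcinoma after progression on first-line therapy,
against two intravenous regimens — mFOLFOX and 5-FU/LV — from the
perspective of Taiwan's single-payer system, in 2023 US dollars. The
parameters worth knowing, with units and why they matter:

| Parameter | Default | Unit | Notes |
|---|---|---|---|
| horizon | 40 | years | lifetime; short horizons reverse the decision |
| cycle length | 1 | month | trapezoid integration; see below |
| discount | 3% | per year | applied at cycle midpoints |
| WTP | 97,048 | USD/QALY | three times GDP per capita |
| utility PF / PD | 0.76 / 0.68 | — | proxy values from advanced HCC |
| AE disutility | 0.16 | — | grade ≥ 3, aggregate |
| IV route disutility | 0.025 | per PF cycle | 0 for the oral arm |
| conversion factor | 0.9198 | — | applies to non-medication and supportive costs only; medication points are valued at par |
| medication cost | 97,645 / 13,230 / 5,707 | USD/year in PF | pemigatinib / mFOLFOX / 5-FU/LV |
| non-medication cost | 9,361 / 27,512 | USD/year in PF | oral vs chemotherapy delivery |
| supportive care | 15,978 | USD/year in PD | shared across arms |
| genetic testing fee | 934 (off) | USD, once | off because published cost components reconcile without it |

Times are months everywhere: the fitted medians only match the trial
medians in months, and mixing units is the easiest way to corrupt a
survival model silently.

Numerical choices:

* **Cycle length and integration.** One-month cycles with trapezoidal
  occupancy integration and midpoint discounting. The convergence test
  shows halving the cycle moves every total by < 0.5%, and an independent
  daily-step accumulator agrees to the same tolerance, so nothing hinges
  on the exact convention.
* **Adverse-event timing.** The default policy charges the AE disutility
  against PF time in the first month (one default cycle). Defining the
  window in calendar time rather than "the first grid cell" keeps results
  invariant under grid refinement. Alternatives (`first-6-months`,
  `every-cycle`, and event-specific disutility tables) are scenario
  switches.
* **Thresholds.** `threshold_search()` uses plain bisection on the INMB to
  a relative tolerance of 1e-6; INMB is continuous through dominance
  changes where the ICER is not.
* **Restricted means.** `mean_survival()` integrates by adaptive quadrature
  with the range split at 12/60/240 months so the far tail of heavy-tailed
  families is resolved.

## Decision metrics and uncertainty

`compare_arms()` reports incremental cost, QALYs, life-years, the ICER
(only in the trade-off quadrant; dominance is reported instead of a
meaningless ratio) and the incremental net monetary benefit
INMB = WTP·ΔE − ΔC. `breakeven_year()` finds the first time the cumulative
discounted INMB becomes non-negative *and stays non-negative* — the
sustainment condition guards against transient early touches — with linear
interpolation inside the crossing cycle.

`run_dsa()` varies each parameter to its deterministic bounds (published
95% CIs where available, ±25% otherwise). `run_psa()` draws all parameters
independently per iteration: normal for survival scale/shape (truncated
just above zero by redraw, since the published normal distributions put
mass on invalid values), gamma for costs, beta for utilities and the AE
disutility, uniform for the intervention's list price. Independence is a
deliberate simplification: only marginal distributions are published, so a
correlation structure would be invented. Note that independent draws
ignore the strong negative correlation real fits induce between scale and
shape parameters, which inflates predictive uncertainty somewhat. One
published gamma (the oral arm's non-medication cost) has a mean about 5%
from its stated base value; the distributions are used as published rather
than re-derived.

`ceac()` and `evpi()` follow the standard definitions; ties count as
cost-effective, and EVPI = E[max NMB] − max E[NMB] is asserted non-negative
and exact on analytic toy cases.

**What pure-parametric curves do to the PSA.** In a hybrid-curve analysis,
drawing survival parameters perturbs only the extrapolated tail beyond the
trial follow-up; with pure-parametric curves the same draws move the whole
curve from t = 0. The PSA here therefore carries *more* parameter
uncertainty than a hybrid-curve analysis with identical marginals — the
incremental-NMB standard deviation vs mFOLFOX is ≈ 27k USD rather than the
≈ 18k implied by a fixed within-trial segment. Expect the probability of
cost-effectiveness from this configuration to sit a few points lower, and
the per-person EVPI roughly twice as high, as the corresponding
hybrid-curve analysis. This is a property of the reproducible
specification, not a defect of the estimator; with `hybrid_curve()` inputs
the same machinery applies draws to the tail only.

## Scenarios

`base_scenarios()` ships thirteen structural scenarios: life-years as the
effect measure, optimistic (log-logistic) and pessimistic (Weibull PH)
extrapolations of the intervention's curves, a 10% price cut combined with
the pessimistic curves, horizons from 2 to 30 years, AE-timing variants and
event-specific AE disutilities. Overrides are sparse path–value pairs
validated against the base configuration, applied hermetically (the base
configuration is never mutated), with a `price_multiplier.<arm>` shorthand
that scales the medication cost component exactly linearly.
`scenario2_template()` sketches a reassessment on earlier, immature
efficacy reads; its cost inputs belong to a different price year and are
shipped as explicit `NA` placeholders rather than guessed.

## Problem sizes used by the test suite

The suite is designed to run on one CPU in well under the package's own
patience: simulation fixtures use n = 200–2,000 subjects (10,000 for
convergence checks), round-trip reconstruction runs 20 seeds at n = 250,
the model-selection consistency experiment runs 25 seeds at n = 1,500, and
the probabilistic analysis in the acceptance checks uses 1,000 iterations —
the size at which the binomial standard error of a cost-effectiveness
probability is about 1.3 points.

## Known limitations

* Pure-parametric base-case curves inflate PSA spread relative to a
  hybrid-curve analysis (discussed above); the deterministic results are
  insensitive to this.
* No background general-population mortality floor is applied to
  extrapolated curves; over a 40-year horizon heavy-tailed OS fits can
  retain implausible mass, which is exactly what the pessimistic scenario
  probes.
* Adverse events affect utility only; no AE management costs are modelled.
* One published PF-state quality/LY ratio for the 5-FU/LV arm exceeds the
  PF utility and cannot be produced by any disutility scheme; the package
  reports the internally consistent value instead of emulating it.
* Naïve indirect comparison: the three arms come from different trials
  with different populations; nothing here adjusts for that, by design.
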