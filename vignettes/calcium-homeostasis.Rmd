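---
title: "Modelling calcium homeostasis in round spermatids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling calcium homeostasis in round spermatids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spermCa)
```

## The biological problem

Round spermatids are haploid male germ cells whose cytosolic free calcium,
\[Ca²⁺\]~cyt~, is regulated by intracellular stores rather than by influx:
in the absence of extracellular calcium the cell behaves, kinetically, as a
closed system. Two store compartments matter — the endoplasmic reticulum
(ER), loaded by a thapsigargin-sensitive SERCA pump, and acidic vesicles
(AV), loaded by a thapsigargin-insensitive Ca²⁺-ATPase. Blocking SERCA with
thapsigargin empties the ER through its leak: \[Ca²⁺\]~cyt~ rises from a
15–50 nM baseline to a 300–500 nM transient and then relaxes over tens of
minutes toward a 100–200 nM stationary level set by the remaining vesicular
pump. Because both pumps burn ATP, and ATP synthesis in these cells is fed
by lactate taken up through a low-affinity transporter, the stationary
calcium level is modulated by extracellular lactate: more lactate, more
ATP, stronger pumping, lower stationary \[Ca²⁺\]~cyt~.

`spermCa` implements this picture as three coupled pieces: a closed
three-compartment flux model, a reduced two-variable dynamic system for the
post-thapsigargin transient, and a steady-state quadratic linking
stationary calcium to lactate. Around these it provides the inference
machinery (trace fitting, exponential-decay extrapolation, dose-response
fitting, cohort summaries) and seeded synthetic-data generators that stand
in for the original fluorescence records, which were never deposited.

## The dynamic model

After thapsigargin (SERCA off), with the vesicular compartment absorbed
into composite constants, the observable dynamics reduce to

$$\frac{d[\mathrm{Ca}]_{cyt}}{dt} = p - q\,[\mathrm{Ca}]_{cyt}
  + r\,[\mathrm{Ca}]_{ret} - d\,[\mathrm{Ca}]_{cyt}^2, \qquad
\frac{d[\mathrm{Ca}]_{ret}}{dt} = g\,([\mathrm{Ca}]_{cyt}
  - [\mathrm{Ca}]_{ret}),$$

with concentrations in nM and time in s. `p` (nM/s) is a constant source,
`q` (1/s) a linear removal, `r` (1/s) the ER leak feed, `d` (1/(nM s)) the
quadratic removal contributed by the two-ion-per-ATP pump stoichiometry,
and `g` (1/s) the ER equilibration rate. A note on units: the reference
parameter table prints `p` in 1/s, but the differential equation only
balances with `p` in nM/s; the package uses nM/s throughout.

Setting both derivatives to zero forces
$[\mathrm{Ca}]_{ret} = [\mathrm{Ca}]_{cyt}$ and leaves
$d\,x^2 - (r-q)\,x - p = 0$, whose root product $-p/d$ is negative whenever
$p > 0$: exactly one nonnegative root exists, returned in closed form by
`reduced_steady_state()`. At the cohort-mean constants the root is
≈ 105 nM, inside the observed 100–200 nM asymptotic band.

Only `g`'s composition from physical constants is dimensionally clean
(`g = P_leak · A_ret · f_ret / Vol_ret`, ≈ 2.77 × 10⁻³ 1/s from the
measured geometry, within 2% of the 2.80 × 10⁻³ reference). The printed
groupings for `p`, `q`, `r`, `d` carry unresolved composite factors and a
dimensional inconsistency in `d`, so `map_physical_to_reduced()` treats
them as order-of-magnitude initial values; all five constants are refit
from data in practice.

## Integration

No ODE-solver package is assumed; `src/integrate.cpp` implements the
Dormand–Prince 5(4) embedded pair (the `ode45` family) with standard
PI-free step control (safety 0.9, step-change clamp [0.2, 5], mixed
error norm with `abs_tol` 10⁻³ nM and `rel_tol` 10⁻⁸ by default) and
first-same-as-last reuse. Steps are clamped to land exactly on requested
output times; the first output row is the initial condition verbatim. The
integrator is validated in the test suite against an independent fixed-step
classical RK4 oracle written in plain R (agreement to < 10⁻⁵ nM over a
30-minute transient at tightened tolerances) and by a halved-tolerance
self-consistency check. A closed-system property backs it at the model
level: the three-compartment right-hand side sums its net fluxes to zero by
construction, so total calcium (`total_calcium()`, free concentration ×
volume / free fraction, summed) is conserved — the suite requires drift
below 10⁻⁶ relative over 1800 s.

## Fitting calcium traces

`fit_trace()` minimises the mean squared error between the integrated model
and the observed post-thapsigargin record, exactly as the original analysis
did (fminsearch-style Nelder–Mead; here `stats::optim`). Three choices
deserve explanation.

**Log-parameterisation.** All rate constants are positive and span eight
orders of magnitude; the simplex runs over their logarithms, which enforces
positivity without constraints and equalises step scales.

**The ER initial condition.** The recordings do not observe
\[Ca²⁺\]~ret~. By default the initial ER load is a sixth adjustable
quantity, started at 60 µM (a typical loaded-ER value). Users should know
its limits: the cytosol only observes the product
$r\,[\mathrm{Ca}]_{ret}(t)$, so `r` and the ER load are structurally
confounded — fits with both free give excellent curves but arbitrary
splits of the product. The synthetic-data recovery tests therefore pin the
ER load at the generator's true value and assess recovery of the five rate
constants.

**Single simplex run by default.** The simplex stops at a relative
objective change below 10⁻¹⁰ or 5000 evaluations. A `restarts` option
rebuilds the simplex at the current optimum and repeats; this polishes the
exact minimum and is what the noiseless recovery test uses. With realistic
noise (sd ≈ 10 nM) restarting is counterproductive in a specific, measured
way: the objective has a sloppy ridge along which `q` and `p` trade
against each other (the `q`-term contribution sits orders of magnitude
below the quadratic term, so `q` is unidentifiable — the original analysis
made the same observation about `q`'s error sensitivity). Restarted
simplexes crawl this ridge, lowering the MSE by only a few percent (below
the noise floor; the crawled optimum has *lower* MSE than the generating
truth) while moving `p` by ~50% and `q` by orders of magnitude. Early
termination here is regularisation, a familiar phenomenon in sloppy
dynamical models. With the single-run default, recovery medians over 20
seeded noisy traces are 2–6% for `p`, `r`, `d`, `g`.

`fit_exponential_decay()` implements the steady-state extrapolation used
for recordings that end before the decay completes: a least-squares
exponential `ca_ss + amplitude·exp(−rate·t)` on the record tail
(`stats::nls` with the self-starting asymptotic model and a `scaleOffset`
so noise-free records converge; direct simplex SSE as fallback). On reduced-
model transients the extrapolated asymptote lands within 10% of the
analytic steady state, which is the method's rationale.

`summarize_fits()` aggregates a cohort of fits: per-parameter mean, CV%
(sample sd, n−1 denominator — this convention reproduces the reference
82% for `p`) and mean-to-initial ratio.

## The lactate steady-state model

ATP obeys $dATP/dt = \nu + \gamma L/(K_L + L) - k\,ATP$ — constitutive
synthesis, transport-limited lactate-driven synthesis, first-order
consumption. At the ATP steady state the pumps' Michaelis saturation
$ATP/(K_M + ATP)$ becomes the lactate saturation

$$h(L) = \frac{\phi + \omega L/(K_L+L)}{1 + \phi + \omega L/(K_L+L)},
\qquad \phi = \frac{\nu}{k K_M}, \quad \omega = \frac{\gamma}{k K_M},$$

and the stationary cytosolic calcium solves
$\delta\,h(L)\,x^2 + B\,x - 1 = 0$ with pump-strength composite `δ`
(vesicular pump alone, post-thapsigargin) or `δ′` (ER + vesicular,
pre-thapsigargin). The constant term −1 forces one positive root;
`ca_steady_state()` returns it in closed form, checked against `polyroot`
in the tests. Two structural consequences are property-tested: the curve
decreases strictly in lactate when `ω > 0`, and as `δ → 0` (no vesicular
pump under thapsigargin) the root escapes to 1/B and loses all lactate
dependence — which is why the pump-free model variant is rejected by the
observed dose-response. The fitted `B` is treated as a free parameter: its
defining identity `B = (q−r)/p` gives a negative value at the cohort-mean
dynamics while the fitted value is positive, so the identity is reported
but not enforced.

`fit_lactate_curve()` minimises squared dose-response residuals over any
subset of (δ, ϕ, ω, K_L, B), the rest held fixed. The canonical two-stage
protocol (`fit_lactate_two_stage()`) fits all five to the post-thapsigargin
data, then only (δ′, ϕ) to the pre-thapsigargin data with (ω, K_L, B)
pinned to stage-1 values — transport and calcium dynamics should not care
about thapsigargin, pump strength and constitutive ATP may. On the
packaged dose table this reproduces the reference fit quality (R² = 0.98
both conditions) and the two headline physiology numbers: ER pumping ≈ 17×
vesicular pumping ((δ′−δ)/δ) and a 24% drop in ϕ after thapsigargin.

A caution on identifiability, quantified in development and reflected in
the test design: five free parameters against five dose points
interpolate the noise, and on the pre-thapsigargin curve (14–50 nM signal)
δ′ is confounded with ϕ at low lactate and amplifies observation noise
roughly as $1/x^2$. Single-replicate δ′ estimates at 5 nM noise scatter
with ~28% median error even with (ω, K_L, B) known; the estimator is
nevertheless nearly unbiased (≈ 4% over 12 replicates), so the pipeline
test asserts recovery of the mean estimate and the per-replicate δ′ > δ
ordering.

## What the synthetic data emulate — and what they don't

`generate_trace()` integrates the reduced model on a uniform grid (default
3 s over 1800 s, the recording time base) and adds i.i.d. Gaussian noise
clipped at zero. The 10 nM default noise sd places fitted R² in the
0.97–0.99 band of the reference fits. `generate_cohort()` emulates a
15-animal experiment series: per-experiment constants drawn log-normally
around central values with the observed per-parameter CVs (82, 107, 26,
38, 35 percent), baselines uniform on 15–50 nM, and the initial ER load
calibrated by root bracketing (`calibrate_er_load()`) so the noiseless
transient peaks uniformly in 300–500 nM. `generate_lactate_dataset()`
adds Gaussian noise (default 5 nM) to both steady-state curves.

Not modelled: raw fluorescence ratios and their calibration,
photobleaching, instrument drift, the slightly rising pre-thapsigargin
baseline, and any correlation structure in the noise. A green recovery
test therefore establishes that the estimators work under the model's own
assumptions with realistic magnitudes — not that the model is correct for
any particular recording.

One statistical point shapes the cohort acceptance test: with `p` drawn at
82% CV, the mean of 15 draws has ≈ 21% standard error, so even a perfect
fitter cannot reliably land within 20% of the *central* value. The
pipeline test compares fitted means to the cohort's realized (drawn) truth
means, which isolates what the pipeline can control.

## Numerical choices and degenerate inputs

* Integrator defaults `rel_tol` 10⁻⁸, `abs_tol` 10⁻³ nM; step-size
  underflow reports the failing time. Inside fitting objectives an
  integration failure returns a large finite penalty (10¹²) so the simplex
  can back away.
* Quadratic roots are taken in closed form; root uniqueness is structural
  (negative root product) and asserted against `polyroot` over random
  draws.
* `d ≤ 0` with `p > 0` has no finite steady state and errors; `p = 0`
  with `q ≥ r` returns 0.
* Zero-variance records: `r_squared()` errors (R² undefined);
  `fit_exponential_decay()` returns the constant with zero amplitude,
  flagged as non-decaying.
* Degenerate cohort draws whose kinetics cannot reach the target peak get
  the nearest achievable ER load (search-interval endpoint) instead of an
  error.
* CSV round trips write 17 significant digits; concentrations are nM,
  volumes dm³, areas dm², times s, lactate and ATP mM everywhere, with
  conversion only at I/O boundaries.

## Known limitations

* `q` is not identifiable from post-thapsigargin traces and is reported
  as-fitted without a recovery guarantee; `r` is identifiable only jointly
  with the ER load unless one of the two is pinned.
* The full three-compartment model's pump kinetics
  (flux ∝ \[Ca²⁺\]²·ATP-saturation) are the simplest form consistent with
  the reduced model's quadratic term; finer pump mechanics (Hill details)
  are not represented, and the full model is used for conservation and
  qualitative structure, not for fitting.
* The open-cell variant (plasma-membrane Na⁺/Ca²⁺ exchange) is covered
  only by the δ → 0 degeneracy check, mirroring its rejection on the
  grounds that it decouples stationary calcium from ATP.
* Point estimates only; no bootstrap or profile-likelihood uncertainty.
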