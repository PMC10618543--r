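---
title: "Methods: personalized BCG-immunotherapy dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: personalized BCG-immunotherapy dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcgdyn)
```

## The biological model

Intravesical BCG therapy treats non-invasive bladder cancer by instilling
live attenuated bacteria into the bladder, where they infect both cancer
and healthy urothelial cells; infected cells recruit effector immune cells
that destroy them. `bcgdyn` tracks six populations — BCG `B`, effectors
`E`, infected/uninfected cancer cells `T_i`/`T_u`, and
uninfected/infected healthy cells `H_u`/`H_i` — through mass-action
interactions: BCG decays (`mu_B`) and is consumed by effector uptake
(`p1`) and by infecting cancer (`p2`) and healthy (`p8`) cells; effectors
decay (`mu_E`), are recruited in proportion to the infected pool
(`alpha`) and to intravesical BCG (`p4`), and are lost while killing
(`p5`, `p6`); cancer cells grow exponentially (`lambda`) and die to
effector attack (`p3`, applied to infected and uninfected cells alike);
healthy cells regrow logistically (`p7`) toward the bladder capacity
`H_m` shared by all four tissue compartments.

Dosing is impulsive: `N` instillations of `b` BCG units every `tau`
hours. Mathematically each dose is a Dirac impulse; numerically the
package offers two equivalent administrations. The default `"jump"` mode
adds `b` to `B` at each dose time through solver events, which keeps the
stiff integrator away from `1/epsilon`-peaked forcing. The `"pulse"` mode
integrates the literal triangular epsilon-approximation (unit integral,
half-width `epsilon = 0.5` h by default); because the first pulse is
centred at `t = 0`, pulse-mode integration starts at `-epsilon` so the
full first dose is delivered. The two modes agree on the final tumor
burden to well under 1% at the default settings, and the delivered dose
is conserved exactly (`B` accumulates to `N * b` when elimination is
switched off).

Treatment starts from `B = 0`, a small resident effector population
`e0`, tumor burden `T0`, and a bladder otherwise filled to capacity:
`H_u = H_m - T0`.

## Parameters, units and defaults

Time is in hours, populations in absolute cells (or BCG units). The
protocol constants follow the standard weekly induction course:

| parameter | default | meaning |
|---|---|---|
| `b` | 2.8e6 | BCG units per instillation |
| `N` | 6 | instillations |
| `tau` | 168 h | inter-dose interval |
| `mu_B` | 4.16e-3 /h | BCG decay |
| `H_m` | 1.84e9 cells | bladder capacity (population average) |

The interaction rates are not directly measurable and are the objects of
fitting. The shipped baseline (`model_params()`) was chosen once so that
the simulated course is clinically sensible: an untreated tumor grows
about 7.5-fold over the 6-week course (`lambda = 2e-3` /h, doubling time
about two weeks), while the treated baseline patient ends at roughly 20%
of the presenting burden, with the effector population rising to a few
million cells and the healthy urothelium essentially unperturbed. `e0`
defaults to 1e3 effector cells; no published value exists, and the fit
may free it. The per-patient capacity helper `estimate_hm()` is an affine
calibration in the age and BMI midpoints with a gender offset, centred so
a balanced population averages 1.84e9 cells.

One conflict is worth noting: the instillation dose is quoted in the
source literature both as 2.8e6 and as 2.8e8 units; the package ships the
tabulated 2.8e6 and leaves `b` configurable — none of the package's
conclusions depend on which is used, since `b` only rescales the fitted
interaction rates.

## Equilibria and stability

With dosing off the system has exactly two equilibria: the trivial state
(everything zero) and the healthy state `(0, 0, 0, 0, H_m, 0)`. The
Jacobian is computed analytically from the implemented equations
(`model_jacobian()`); at both equilibria the infected-cell rows vanish,
forcing at least one zero eigenvalue (both equilibria are
non-hyperbolic), and the uninfected-cancer row contributes the eigenvalue
`lambda`, so for any growing tumor both equilibria are unstable: a single
seeded cancer cell drives the system away from health. The commonly
reproduced closed-form linearization matrices contain simplifications
(entries `-1/H_m` without the regrowth factor, a `p7 + 2` diagonal term,
a dropped infection coupling); they are retained verbatim as regression
fixtures in `reference_jacobians()` but are not used for analysis — the
qualitative conclusions (zero eigenvalue, instability) agree either way.

## Numerical choices

Integration uses `lsoda` (stiff-capable, `rtol = 1e-8`, `atol` scaled to
1e-6 of each compartment's characteristic size) on compiled C
right-hand sides. States are clipped to zero only on output; an excursion
below ten times the absolute tolerance raises an error instead of being
hidden. The fitting loss integrates all patients of a socio-demographic
group as one stacked system (they share parameters and differ only in
initial burden), which cuts per-patient overhead by an order of
magnitude. Correctness of the production path is pinned by three
independent cross-checks in the test suite: a closed-form exponential
limit (relative error under 1e-6), a central-difference Jacobian (the
right-hand side is at most quadratic, so central differences are exact up
to rounding), and a hand-rolled fixed-step RK4 integrator over the
R-level right-hand side (agreement to 1e-4 on the final burden).

## The fitting procedure

Clinical data is two burdens per patient plus socio-demographics, so the
fit works purely on treatment outcomes:

1. **Per-group gradient descent.** Free parameters (any subset of
   `p1..p9, mu_E, alpha, lambda, e0`; protocol constants stay fixed) are
   optimised in log-space with five-point-stencil gradients
   (`h = 1e-3`), projection to bounds, seeded restarts, and
   per-coordinate adaptive moment scaling. Plain fixed-step descent was
   tried first and crawls: with outcome-only data the growth and immune
   rates are strongly collinear (a faster-growing tumor under a stronger
   immune response produces nearly the same final burden), so the loss
   surface is a narrow curved valley. The adaptive scaling recovers
   two free parameters to a few percent on noise-free data where the
   fixed-step rule stalls at 30-50% error. The best-seen iterate is
   always returned, so the accepted-step loss trace is non-increasing.
   The RMAE loss — mean of |predicted − observed| / observed — weights
   patients equally regardless of burden scale.
2. **KNN-gated augmentation.** Synthetic feature vectors are drawn
   uniformly between the column-wise training minima and maxima (one-hot
   blocks snapped back to the nearest valid profile), labelled with the
   current model's simulated outcome, and accepted only when the model's
   error on that label is below an optimised KNN regressor's (neighbour
   count chosen by leave-one-out error among 1/3/5/7). An augmentation
   round is kept only if a paired one-sided t-test on the held-out test
   errors shows a significant improvement (alpha 0.05, at most 3 rounds,
   attempt cap 50 per requested sample); otherwise the pre-augmentation
   fit is restored.
3. **Pipeline extrapolation.** A fixed, self-contained candidate set —
   global mean, per-group mean, linear map, KNN regressor, random
   forest — learns the map from patient features (one-hot
   socio-demographics plus log presenting burden) to fitted
   log-parameters; candidates are scored by the RMAE of simulated
   outcomes on the validation split and the argmin wins (ties break by
   candidate order). A fixed candidate set was chosen over an AutoML
   search deliberately: it keeps the procedure deterministic under a
   seed and free of heavyweight dependencies, while preserving the
   design's intent of selecting the best of several pipeline families
   by a predefined metric.

The cohort is split into `k` folds, each fold split 60/20/20 into
train/test/validate (fractions are a package choice; the design only
fixes the three roles). Prediction for a new patient averages over folds,
using each fold's direct group fit where one exists and its pipeline
otherwise. Groups absent from a fold's training data fall back to the
pipeline — mirroring how sparse registries leave many of the 72 cells
empty.

## The virtual-cohort generator

`generate_cohort()` emulates the structure of the registry data the
method targets: several hundred patients; two burden observations each;
unbalanced socio-demographics (weights skewed toward older, male,
smoking patients, so many of the 72 groups are empty in finite samples);
presenting burdens log-uniform on 1e4–1e7 cells; multiplicative
lognormal measurement noise (`sigma = 0.1`) on the observed final
burden, reflecting how volume-derived cell counts err proportionally.
The shipped "strong" effect scenario makes smoking raise `lambda` 1.5x,
age accelerate effector decay (up to 1.5x), weight scale `H_m` (±15%)
and gender offset `alpha` (15%) — effect sizes chosen once so that
group differences are detectable above the noise at realistic group
sizes but far from trivially separable.

What the generator does **not** emulate: model mismatch (virtual
patients are produced by the same equations the fit assumes, except in
the legacy-model comparisons), missing or censored records, within-group
parameter heterogeneity, and measurement error on the *presenting*
burden. Passing tests therefore demonstrate that the pipeline recovers
structure it is designed for — not that the six-compartment model is the
true generative process of any clinical cohort.

## Problem sizes and evaluation design

The shipped tests and the acceptance script use desk-scale sizes chosen
as a package decision: recovery studies use a two-group cohort of 80
noise-free patients (two free parameters, ≥30 patients per group);
the three-way comparison uses a 417-patient strong-scenario cohort with
`k = 2` folds, three free parameters, and a fully converged legacy fit
(its single pooled optimisation is cheap, and a hobbled baseline would
flatter the comparison). The evaluation subset for model comparison
draws 50 records with pairwise-distinct profiles where available; the
one-way ANOVA across models is followed by one-tailed paired t-tests.
On this surrogate the personalized model roughly halves the pooled
model's error, and both dominate the legacy continuous-instillation
model, whose missing effector-kill term for uninfected cancer cells
leaves a large irreducible error on data generated with that pathway
active.

## Known limitations

* No spatial bladder geometry; dosing reaches all cells uniformly.
* Parameters are constant within a patient over the course; the
  personalization is entirely between-group (a time-dependence hook
  exists in the equations' structure but is unused).
* Identifiability from two time points is weak: distinct parameter
  combinations can produce near-identical outcomes, which is precisely
  why the procedure leans on groups, augmentation and pipeline
  extrapolation rather than per-patient fits.
* The weight/age vocabularies are fixed labels; alternative
  discretizations require only vocabulary swaps but are untested.
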