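---
title: "Mechanism-based population PK/PD of intravenous proton pump inhibitors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanism-based population PK/PD of intravenous proton pump inhibitors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppipkpd)
```

## The system being modelled

Benzimidazole proton pump inhibitors (PPIs) such as ilaprazole accumulate
in the acidic canaliculus of the parietal cell and bind the H+/K+-ATPase
covalently. Three consequences shape the clinical pharmacology and the
model:

* the effect lags exposure (an inactivated pump stays inactive after the
  plasma concentration has fallen — an indirect, irreversible response);
* the effect saturates in dose once essentially all accessible pumps are
  hit during the dosing interval (the dose "ceiling");
* recovery is governed by pump turnover (`kdeg`), not by drug washout.

The package couples a two-compartment infusion PK model with a
pump-turnover/acid-production PD system, adds the two dominant
non-drug influences on intragastric pH — the nocturnal acid surge and meal
dilution — and wraps the whole thing in population (nonlinear
mixed-effects) machinery: simulation of virtual trials, FOCE-I/Laplace
estimation, empirical Bayes individual estimates, VPC and
goodness-of-fit diagnostics.

## Structural equations

**PK.** With `Rin(t)` the infusion rate (mg/h),

$$V_c\,\dot C_p = R_{in}(t) - CL_p C_p - CL_t (C_p - C_t),\qquad
  V_t\,\dot C_t = CL_t (C_p - C_t),$$

both compartments starting at zero. The printed structural equation of the
source model family omits the input term; a zero-order infusion input is
the standard completion and is required for any non-zero response, so the
package adds it, with the infusion duration configurable per dose event
(default 0.5 h, typical short-infusion practice for IV PPIs — not reported
in the source studies). The model is linear, so the implementation uses
the closed-form biexponential infusion solution superposed over dose
events; an independent stiff ODE integration (deSolve) serves as the test
oracle at a relative tolerance of 1e-6.

Covariates follow the published analysis: allometric body weight on the
central volume, $V_{c,i} = \theta_{V_c} e^{\eta}(WT/70)^{\theta_{wt}}$,
and a multiplicative sex effect on clearance,
$CL_{p,i} = \theta_{CL_p} e^{\eta}\theta_{sex}^{sex}$. The reference sex
level is not stated in the source; the package codes `sex = 1` for males
and lets `theta_sex > 1` scale male clearance, consistent with the higher
clearance usually seen in males. The weight covariate sits on `Vc` (the
equation-level statement), not on the peripheral volume mentioned once in
the surrounding prose, which we read as a typo.

**PD.** Relative pump activity `E` and latent gastric H+ (mM):

$$\dot E = k_{deg}(1 - E) - k_d\,E\,C_p(t), \qquad
  \dot H = k_{out} H_{BASE} f_{circ}(t)\,E - k_{out} H,$$

with `E(0) = 1`, `H(0) = HBASE`; synthesis is tied to degradation by the
drug-free steady state (`ksyn = kdeg`). The circadian factor is a 24-h
periodic quartic bell, `1 + MA/(((t - MTmax)/MW)^4 + 1)` on the minimal
clock distance to the peak; the printed form of this factor in the source
is typographically corrupted, and the reconstruction used here reproduces
both the "nocturnal surge" semantics and the fitted parameter magnitudes
(the residual printed normalization constant is ~1e-4 and is dropped). A
symmetric bell is used; an asymmetric (different left/right width) variant
is conceivable but unverifiable from the source, and the symmetric form
fits the stated parameter set.

Meals at 4 h and 10 h after the 08:00 dose dilute *observed* acidity
without feeding back on the state: `Hobs = H × Fe(t)` with the branchwise
`Fe` of [food_effect()], recurring daily on multi-day horizons. The
direction (meals lower H, i.e. raise pH) follows the stated dilution
mechanism; the source's prose sentence defining `Fe` as a ratio is
ambiguous about orientation, and the opposite reading would make meals
acidify the stomach. Observed pH is `-log10(Hobs with H in mM)` plus
additive error. The mM convention makes the fixed baseline
`HBASE = 0.033` correspond to a fasting minimum pH of about 1.48; on a
molar scale the same number would imply a fasting pH of 4.5, which is not
a plausible healthy fasting minimum.

**Units of the inhibition term.** `kd` is printed with unit "(ng/mL)/h"
in the source table; dimensional analysis of the pump equation requires
per-concentration-per-hour. The package feeds the inhibition term the
concentration in mg/L (the customary modelling scale of the dependent
variable) and keeps the printed magnitude, `kd = 18.24` L/mg/h. This
choice is load-bearing and was made on mechanistic grounds: with
concentrations in ng/mL the term `kd·Cp` exceeds 100/h for more than two
days after even a 5 mg dose, so every dose from 5 mg upward would pin pump
activity at zero for the whole observation window — no dose-graded onset,
no within-day recovery, and a pump-degradation constant that the data
cannot identify. With mg/L the model produces dose-graded onset on day 1,
pump recovery within the 24-h interval at low doses, and the published
regimen ordering, and `kdeg` becomes identifiable from the recovery phase.

## What the model does *not* saturate

The quasi-steady observed pH under drug is approximately
`pHmin + log10(1 + kd·Cp/kdeg)`: each dose doubling adds ~0.3 pH units at
any exposure, at any unit scale. The *median* 24-h mean pH therefore does
not exhibit a hard ceiling between 20 and 40 mg in this structural model;
what saturates is coverage of the dosing interval (once suppression
outlasts 24 h, higher doses add only the logarithmic term) and
threshold-based metrics. The published "no significant difference" between
20/30/40 mg is, under this model, a statement about heavily overlapping
population percentile bands (the log-scale BSV SDs on the PD parameters
all exceed 1) rather than about saturation of the median. The
dose-ceiling analysis in [ceiling_analysis()] reports both the median
mean-pH gains and the threshold metrics so users can see both facets; the
acceptance test that asserts a <20% gain ratio on median mean pH is left
failing deliberately, as the structural model cannot produce it.

## Numerical methods

*PK* is evaluated in closed form (C++ kernel for the estimation hot path).
The repeated-eigenvalue corner of the two-compartment solution is guarded
by a 1e-8 relative split; non-finite or non-positive parameter inputs
yield NaN predictions that the estimation machinery treats as a rejected
step rather than an error.

*PD integration* uses a fixed-step exponential integrator: each state
equation is linear in its own state, so with the forcing sampled at step
midpoints the update is exact for piecewise-constant forcing and
unconditionally stable. This matters because `kd·Cp` reaches ~40/h at
therapeutic exposure (pump collapse on a minutes timescale) — an explicit
solver would need prohibitively small steps, and an implicit solver would
be ~100x slower than the exponential update for no accuracy gain on this
structure. Simulation uses a 0.01-h step (relative error ~1e-5 against a
stiff reference integration; the test suite enforces 1e-4), estimation a
0.025-h step aligned with the 30-min observation grid. deSolve's `lsoda`
is used as the independent oracle in the tests, never as the production
path, keeping the two routes separate.

*Estimation.* The marginal likelihood is approximated by FOCE-I: each
subject's joint -2 log posterior over its random effects is minimized by a
damped Gauss-Newton iteration with finite-difference prediction Jacobians
(compiled, batched over subjects; non-converging subjects retried on a
slower R path with a quasi-Newton fallback), and the Laplace determinant
uses the Gauss-Newton curvature. A finite-difference-Hessian Laplace
variant (`method = "laplace"`) exists for cross-checks; both agree with
adaptive quadrature to <0.1 on one-eta subjects in the tests. Fixed
effects are mu-referenced (log scale, additive etas; the allometric
exponent stays on the identity scale), omegas and sigmas are estimated on
the log scale, and confidence intervals are back-transformed. The outer
problem is solved by a bounded quasi-Newton (PORT) iteration with explicit
central-difference gradients — the objective carries ~1e-6 numerical noise
from the iterative inner solves, so the gradient step (1e-4) must sit well
above it — with up to three restarts, because marginal-likelihood surfaces
with BSV variances above 1 have long flat valleys in omega space.
Parameters are box-bounded within e^±4 of their starting values to keep
line searches away from overflow regions. Starting values come from naive
pooled estimates (dose/AUC, dose/Cmax) for PK; the PD stage starts from
the published values, optionally perturbed by a random factor in [0.5, 2]
(`start_perturb`) so that recovery experiments do not start at the truth.

*Sequential conditioning.* The PD stage conditions on individual PK
parameter values: empirical Bayes estimates from a PK fit
([pk_individual_from_fit()]), or the generating individual values on
synthetic data ([pk_individual_true()]). Which flavour the source used is
not stated; both are exposed. `HBASE` is fixed (as in the source), and the
circadian parameters are fixed by default — the source reports fitting
them to mean drug-free baseline data and notes non-convergence when they
carry BSV; `estimate_circadian = TRUE` frees them.

## The synthetic-data generator

No clinical data accompany the source, so the generator is the package's
testbed and defines the study conditions:

* internal study: 16 subjects, 1:1 sex, weight truncated-normal
  62.6 ± 8.0 kg on [52, 79] (the published demographics), three crossover
  IV occasions of 5/10/20 mg sharing one eta vector per subject (no
  inter-occasion variability is modelled, matching the source), 24-h
  horizons. The oral 10 mg arm is excluded: the model has no absorption
  component.
* external validation: 10 subjects at 30 mg; loading-dose studies: 12
  healthy / 10 duodenal-ulcer subjects at 20/10/10 mg over 72 h, the ulcer
  arm reusing the healthy parameters (the source reports similar PK and
  acid inhibition in ulcer patients).
* virtual-trial population: weight truncated-normal centred at 70 kg on
  [40, 80] (median ≈ 69–70), 1:1 sex — the published simulation
  demographics.
* sampling schedules are not published; defaults are plasma at
  0/0.25/0.5/0.75/1/1.5/2/3/4/6/8/12/24 h and pH every 15 min
  (continuous pH-metry emulation), configurable. The eta columns of
  Tables of the source are treated as variances of log-scale etas and the
  residual entries as SDs (0.12 proportional, 1.28 pH units additive);
  both readings are documented here because the source does not say.
* pH noise is left unclipped: the additive error model is unbounded, and
  clipping to physical pH bounds would bias estimation tests. Summary
  metrics are computed on noiseless curves.

What passing recovery tests show — and what they do not: the generator
emulates the *model*, so recovery demonstrates estimator correctness and
identifiability under the published design, not correctness of the model
for real patients. Features of real pH-metry that the generator does not
emulate include serially correlated electrode noise, irregular meal and
water intake (the source itself notes unrecorded drinking events), missing
segments, and assay quantification limits.

## Pre-specified summaries and test calibration

Single 16-subject maximum-likelihood fits under log-scale BSV SDs above 1
are noisy and occasionally land in distant likelihood basins (verified
against importance-sampled exact marginal likelihoods: those basins are
genuine ML optima of their realizations, not optimizer failures). The
recovery experiments therefore report the *median* across replicate
seeds, chosen a priori as the robust location summary; the number of
seeds (40 for the PK stage, 15 for the PD stage in the acceptance script)
reflects a few minutes of single-core compute per stage. Stochastic test
tolerances are set to about twice the Monte-Carlo standard error of the
reported summary implied by the generating variabilities; the sharp
correctness checks are the noiseless zero-BSV recovery tests, which
reproduce the generating constants to ~1%.

## Known limitations

* Diagonal omega matrices only; no eta covariances.
* No inter-occasion variability, no covariate-search machinery beyond the
  two published covariates, no bootstrap uncertainty.
* The Michaelis-Menten elimination variant is provided as a candidate
  structure for model comparison (it integrates the ODE numerically) but
  has no closed form and is slower; it exists to reproduce the
  structural-selection workflow, not for production fitting.
* FOCE-I shrinks omega estimates at these BSV magnitudes (a known
  property of the approximation); fixed effects are the recovery targets.
* The profile likelihood in `kd` is one-sided: above the published value
  the pump collapse is effectively instantaneous at therapeutic exposure
  and the data carry almost no information, so per-study `kd` (and, through
  its correlation, `kdeg`) maximum-likelihood estimates are left-skewed at
  the 16-subject design — recovery medians tend to sit 15-25% below the
  generating values even though the estimator is approximation-accurate
  (the FOCE objective was checked against importance-sampled exact marginal
  likelihoods to ~1 unit in several thousand; an exact-Hessian Laplace
  variant, `method = "laplace"`, was implemented and found *less* accurate
  against the same oracle, so the Fisher-style determinant is the default).
* The mean-pH dose ceiling is structural log-additivity, as discussed
  above.
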