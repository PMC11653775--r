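---
title: "A stock-and-flow model of caries progression and school-based prevention"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A stock-and-flow model of caries progression and school-based prevention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cariesSDM)
```

## The model

`cariesSDM` implements a cohort-level system-dynamics (stock-and-flow)
model of dental caries in school-aged children. A single birth cohort of
$N$ children is followed from age 6 (onset of the permanent dentition) to
age 15 through five mutually exclusive states:

* $C_0$ — caries-free,
* $U$ — untreated caries,
* $R$ — restored (filled),
* $E$ — endodontically treated,
* $M$ — missing teeth (tooth loss due to caries; absorbing).

Six annual flow fractions move children between states. Writing start-of-year
stocks on the right-hand side, one annual step (a discrete Euler update with
$\Delta t = 1$ year) is

$$
\begin{aligned}
C_0' &= C_0 - d, &\quad d &= f_{dev}\,(1 - e)\, C_0,\\
U'   &= U + d + r_R + r_E - (\rho + \eta + \lambda)\,U,\\
R'   &= R + \rho U - r_R, &\quad r_R &= f_{recR}\, R,\\
E'   &= E + \eta U - r_E, &\quad r_E &= f_{recE}\, E,\\
M'   &= M + \lambda U,
\end{aligned}
$$

with $\rho = f_{restore}$, $\eta = f_{endo}$, $\lambda = f_{loss}$, and $e$
the coverage-adjusted intervention efficacy (a proportion; 0 without
intervention). The two recurrence terms $r_R$ and $r_E$ are the model's
reinforcing feedback loops: treatment does not remove a child from the
disease process, and recurrent caries returns treated children to the
untreated pool. Tooth loss flows only out of the untreated state, and the
caries-free stock has no inflows.

Two structural invariants follow immediately and are enforced throughout:
the five stocks always sum to $N$ (conservation), and every stock remains
nonnegative whenever each fraction lies in $[0,1]$ and
$f_{restore} + f_{endo} + f_{loss} \le 1$. Because $C_0$ has no inflows it
also admits the closed form
$C_0(t) = N \prod_{s} \bigl(1 - f_{dev}(1 - e_s)\bigr)$,
which the test suite uses as an independent oracle for the simulated
caries-free trace.

### Choice of time stepping

All transition rates are annual fractions and ages are integers, so the
model is a discrete annual map rather than a continuous-time ODE; flows are
computed from start-of-year stocks and applied once per year. A
continuous-time formulation (e.g. via `deSolve`) would require rates, not
fractions, and the published description provides no within-year dynamics
to calibrate one against.

### Initial condition

The age-6 distribution of the cohort across states is not part of the
published description. The default places the entire cohort in the
caries-free state at age 6, which reads the model as tracking caries in the
*permanent* dentition from its eruption. The allocation is configurable
(`sim_config(initial_allocation = ...)`); calibrated fraction values are
conditional on this choice, and intervention-scenario endpoints shift
accordingly if a different allocation is assumed.

## Intervention scenarios

Interventions act by scaling down the caries-development flow. Each
scenario's multiplier is an *adjusted efficacy*: the trial efficacy
(from a meta-analytic risk ratio, $(1-RR) \times 100\%$) multiplied by the
national coverage rate of the programme. The four built-in scenarios are

```{r}
for (s in moph_scenarios()) print(s)
```

The sealant trial efficacy applies to molars only; the all-teeth figure
weights it by the molar share of caries
(`all_teeth_efficacy(0.82, 71, 0)` = `r all_teeth_efficacy(0.82, 71, 0)`%,
used as 58%). The combined intervention's 60% efficacy is an
expert-determined constant, not a function of the two component rates — no
combining formula exists in the source material, so none is invented here.
Coverage folds into efficacy multiplicatively; partial coverage is *not*
modelled as a split cohort. Interventions run from age 6 to age 12
inclusive, so with the default horizon the multiplier applies to the seven
annual steps starting at ages 6–12 and the last two steps (ages 13 and 14)
run unprotected.

One documented inconsistency in the source tables: the supervised
toothbrushing row describes its coverage as 95% in prose while computing
with 92.5%. The implementation uses 92.5%, the value actually multiplied.

## Calibration

The six flow fractions that generated the published base-case endpoint are
themselves unpublished (they derive from national survey and health-system
data). The package recovers them by fitting the no-intervention endpoint at
age 15 to the published base-case column. Identifiability dictates the
default strategy: the endpoint provides four independent constraints (five
compartments minus conservation), so at most four fractions can be freed.
By default the two recurrence fractions are pinned at zero and
$f_{dev}, f_{restore}, f_{endo}, f_{loss}$ are fitted — an exactly
identified problem. The objective is the sum of squared *relative*
endpoint errors, so the small endodontic compartment (≈1.9% of the cohort)
carries the same weight as the large ones.

The optimizer is derivative-free and bounded: multi-start Nelder–Mead
(default 16 starts drawn uniformly over the per-fraction boxes from a
seeded generator) on a logit reparameterization that enforces the boxes,
with a penalty keeping the untreated-stock outflows jointly below 1, and
ties broken by the smaller parameter norm. A fit counts as converged when
every compartment's relative residual is at or below the tolerance
(default $10^{-3}$). Because the problem is exactly identified, the fitted
$f_{dev}$ can be cross-checked analytically:
$f_{dev} = 1 - (C_0(15)/N)^{1/9}$ under the all-caries-free start.

The calibrated fractions are *model-consistent surrogates* for the
unpublished national values: they reproduce the base-case endpoint by
construction, but the intervention-scenario endpoints they imply can
deviate from the published ones by an amount depending on the unreported
initial condition and recurrence rates (with zero recurrence they land
within about 1% of the published intervention columns).

## Sensitivity analysis

The multivariate sensitivity analysis perturbs all six fractions
independently and uniformly within ±10% of their nominal (calibrated)
values — the published design — with 1000 Monte-Carlo draws by default
(the published run count is unreported). Draws are shared across scenarios
within a run, so scenario contrasts are paired. Intervention multipliers
and the cohort size are held fixed; only the flow fractions are perturbed.
The per-scenario summary is the sample mean and the empirical 2.5th/97.5th
percentiles (the source labels its interval a "95% CI" without stating an
estimator; the empirical percentile interval is the assumption-free
choice). Draws that violate the fraction invariants after clipping to
$[0,1]$ are discarded and counted; more than 10% discarded aborts the run.

One numerical property deserves emphasis. The caries-free endpoint
compounds $(1 - f_{dev})$ over nine steps and is therefore *convex* in
$f_{dev}$, so by Jensen's inequality the Monte-Carlo mean estimates the
expectation under the perturbation distribution, which sits slightly
*above* the unperturbed nominal run — about +660 persons (≈0.6% of the
endpoint) at the calibrated values with the ±10% range, comparable to two
Monte-Carlo standard errors at 1000 runs. The mean should therefore be
compared against the exact perturbed expectation (available in closed form
for the caries-free stock, since it depends on $f_{dev}$ alone), which is
what the unit tests do; the deterministic endpoint is expected to sit near,
but systematically below, the Monte-Carlo mean.

## Synthetic studies and what passing tests show

The synthetic-data generator produces the inputs the analysis assumes:
admissible random fraction sets (uniform within plausible annual ranges —
caries development 0.10–0.30, restoration 0.05–0.30, endodontic treatment
0.005–0.05, tooth loss 0.05–0.30, recurrence 0–0.20 — subject to the joint
outflow constraint), and "observed" endpoint tables simulated from known
fractions, optionally perturbed by multiplicative Gaussian noise and
renormalized to conserve the cohort. The noise model is a test-harness
construct: the real national survey tables carry no published error model.
Parameter-recovery experiments on these studies validate the calibration
machinery (noiseless round trips recover the generating fractions to
$10^{-3}$; under 5% endpoint noise the recovered $f_{dev}$ is unbiased).
Passing them shows the estimation pipeline is self-consistent; it cannot
show that the model family or the calibrated surrogates match Thai
epidemiology beyond the single published endpoint column they reproduce.

## Problem sizes and defaults

The full cohort (678,243) with its nine annual steps is used everywhere it
is cheap (simulation, scenarios, sensitivity); calibration-heavy
experiments (parameter recovery across many synthetic studies) use a
10,000-person cohort — endpoint *proportions*, and hence calibration, are
invariant to cohort scale, so this changes nothing but runtime — and the
recovery experiment in the test suite uses 60 noised studies with the
analysis script mirroring it. Reported defaults: calibration tolerance
$10^{-3}$ relative per compartment, 16 starts; sensitivity ±10%, 1000
runs. All randomness flows through explicit integer seeds.

## Known limitations

* Cohort-level only: no individual heterogeneity, no tooth- or
  surface-level structure, no age-dependent fractions.
* No demography: migration and mortality are outside the model; the cohort
  total is constant by construction.
* The recurrence fractions are unidentifiable from the published endpoint
  and default to zero; any positive recurrence consistent with the same
  base-case endpoint would imply different (generally larger) fitted
  treatment flows.
* Costs and cost-effectiveness are out of scope.
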