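---
title: "Methods: population pharmacokinetics of piperaquine and mapped power"
author: "piperaq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population pharmacokinetics of piperaquine and mapped power}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(piperaq)
```

## The model

Piperaquine is the long-acting partner drug in the fixed oral
dihydroartemisinin–piperaquine combination used against uncomplicated
*Plasmodium falciparum* malaria.  After weight-based once-daily dosing for
three days, venous plasma concentrations show a fast absorption phase, a
multiphasic distribution, and an extremely long terminal phase (weeks), with
a rich early sampling schedule followed by sparse follow-up out to day 126.

The structural model implemented here is a linear three-compartment
disposition system with transit-compartment absorption.  A dose enters a
chain of `n + 1` first-order stages (with `n = 3` transit compartments and
the absorption step out of the last stage sharing the inter-transit rate
constant `ktr`), so the absorption delay is Erlang-distributed with mean
transit time

$$\mathrm{MTT} = (n + 1)/k_{tr}.$$

Disposition is parameterised by the apparent elimination clearance CL/F,
central volume Vc/F, two inter-compartment clearances Q1/F and Q2/F and two
peripheral volumes Vp1/F and Vp2/F.  Because no intravenous reference
exists, all parameters are apparent (scaled by the relative bioavailability
F, fixed to 1 for the population).

All parameters are log-normally distributed across subjects.  Between-subject
variability (BSV) acts on CL, Vc, Vp1, Q2 and MTT; between-occasion
variability (IOV, redrawn at each of the three dose occasions) acts on F and
MTT.  The residual error is additive on the natural-log concentration scale
(equivalent to an exponential error on the natural scale), with SD `sigma`.

Covariate model:

* fixed allometric body-weight scaling, exponent 3/4 on clearances and 1 on
  volumes, referenced to 52 kg (the pooled cohort median);
* a linear increase of F per dose occasion (default slope 0.253/occasion),
  reflecting recovery from acute malaria over the treatment days;
* a linear age effect on Vp1 (default 4.10 %/year, centered at the pooled
  median of 33 years);
* optional categorical food effects on MTT and F, used by the full
  covariate analysis and the power mapping.

Doses are recorded as mg of piperaquine phosphate and converted to mg base
by the salt factor 0.577 before entering the model, so that apparent
clearances and volumes refer to base amounts.

Units: times in hours, amounts in mg, volumes in litres, concentrations in
ng/ml, half-lives reported in days.

## Solving the kinetic system

The compartment system is linear, so the concentration after any dosing
history is a superposition of single-dose responses.  The default solver
uses the closed form: the 3×3 disposition matrix built from
k10 = CL/Vc, k12 = Q1/Vc, k21 = Q1/Vp1, k13 = Q2/Vc, k31 = Q2/Vp2 has three
real non-positive eigenvalues (roots of a cubic solved trigonometrically),
and the central response to the Erlang input is a convolution with an
explicit finite-sum expression.  Near-confluent exponential rates
(`|ktr - lambda| * t < 1e-3`) switch to a power series to avoid
cancellation; near-coincident disposition eigenvalues are separated by a
relative nudge of 1e-10 so residues stay finite.  Cases with `Q = 0`
decouple a peripheral compartment cleanly (the residue vanishes), and the
terminal half-life ignores zero eigenvalues so the one-compartment limit
`ln 2 Vc/CL` is recovered.

A matrix-exponential path (`solve_profile(..., method = "matexp")`)
propagates the full state — transit stages, central, both peripherals, and
cumulative eliminated amount — across piecewise-constant intervals between
dose events.  It is the route used for mass-balance accounting and is
verified, together with the closed form, against an independent stiff ODE
integration to a relative 1e-6 in the test suite.  The two paths are
algebraically identical when the transit rate is constant; with
occasion-varying MTT, the closed form attaches each dose's chain to its own
occasion's rate while the state propagation switches rates at dose times.
The difference is confined to drug still in transit at a dose time, which
is negligible at the fitted rates (the chain empties with time constant
`MTT/(n+1)` of about half an hour).

```{r halflife}
terminal_halflife(pq_params())
```

## Estimation: FOCE-I with censored records

The marginal likelihood of each subject's data integrates the conditional
likelihood over that subject's random effects (up to 11 per subject: 5 BSV,
3 occasions × 2 IOV).  The engine uses first-order conditional estimation
with interaction: for each subject the conditional mode of the random
effects is found by a damped Gauss–Newton iteration (gradient from a
structured Jacobian of the predictions; the bioavailability-eta columns are
analytic because F enters multiplicatively), and minus twice the
log-likelihood is approximated by the Laplace expression with the
Gauss–Newton (first-order) Hessian

$$\mathrm{iOFV}_i = G_i(\hat\eta) + \log\det\Omega +
  \log\det(\Omega^{-1} + J^\top W J),$$

whose sum over subjects is the OFV.  With a constant log-scale residual SD
the interaction term is benign but the conditional weighting is retained.
The total OFV is exactly additive over subjects, a property the mapped
power procedure relies on.

Observations below the 1.2 ng/ml quantification limit are either omitted
(`blq = "omit"`, the model-building default) or integrated as censored
normal records (`blq = "m3"`), contributing
$-2\log\Phi((\log \mathrm{LLOQ} - f)/\sigma)$, with the matching curvature
terms in the inner optimisation.  The predose (0 h) sample of drug-naive
patients is a structural zero and never enters the likelihood.

Numerical choices:

* inner Newton convergence at a gradient infinity-norm below
  `1e-7 * (1 + |G|)`, at most 60 iterations, warm-started across outer
  evaluations (the converged mode does not depend on the start);
* outer minimisation by `nlminb` over transformed parameters (log scale for
  positive quantities; covariate slopes raw, bounded so that every
  individual multiplier stays positive over the observed covariate range),
  with an explicit forward-difference gradient using a step of 1e-4 on the
  transformed scale — chosen to sit well above the numerical noise floor of
  the inner optimisation, where the optimiser's own much smaller internal
  step would see only noise;
* outer convergence at a relative objective tolerance of 1e-6 (about 1e-3
  OFV units at the problem sizes used);
* random-effect variances are estimated on the log scale and therefore
  cannot collapse to exactly zero; a variance fixed to zero removes the
  effect (and its inner dimension) entirely;
* eta covariances are fixed to zero (diagonal Omega), as no correlations
  are part of the model;
* invalid parameter combinations (a covariate multiplier or an occasion
  effect driving a parameter non-positive) flag the subject and return an
  infinite objective, which the bounded outer search avoids.

Initial estimates: refitting experiments start from deterministic
perturbations of the generating values (log-scale jitter of SD 0.15 on
typical values and 0.3 on variances); the pipeline configuration layer
starts from the final-model defaults.

## The synthetic study

The raw clinical data are not deposited, so the package ships a
design-faithful simulator.  It emulates: 15 fed and 15 fasting adults;
weight-based dosing targeting 18 mg phosphate/kg/day with 320-mg tablets —
the three-day course is rounded conservatively to whole tablets
(`floor(w * 54/320 + 0.25)`) and split evenly, reproducing the published
administered-dose spread (median near 17.5, range about 16–18.8 mg/kg/day);
the exact sampling schedule (22 dosing-phase samples including the predose
baseline, 13 follow-up samples from day 4 to day 126); LLOQ censoring with
the value withheld; and demographics drawn per arm from scaled Beta
distributions matched to the published medians and ranges (weight 39–73 kg,
age 18–55 years, 13:2 male:female).  Weight and age are sampled
independently — the true joint distribution is unknown — and each subject
owns an independent random substream, so enlarging a cohort never perturbs
existing subjects.

What the simulator does *not* emulate: dropout, dosing-time deviations,
recurrent infections, assay batch effects, disease progression within the
treatment course beyond the dose-occasion effect, and any weight–age
correlation.  Passing recovery tests therefore demonstrates internal
consistency of estimator and design — identifiability of the model from
data of this shape — not robustness to the misspecifications real data
carry.

```{r sim, eval = FALSE}
pop <- sample_population(pq_design(), pq_covdist(), seed = 1)
dat <- simulate_dataset(pop, pq_model(), seed = 1)
fit <- pq_fit(dat, pq_model())
summary(fit)
```

## Covariate search and the food question

`scm_search()` implements forward addition (keep the largest OFV drop if it
exceeds 3.84; 1 df, p < 0.05) followed by backward deletion (remove any
retained covariate whose removal raises the OFV by less than 6.63;
p < 0.01).  Continuous covariates support linear, power, exponential and
piecewise-linear forms (the piecewise breakpoint fixed at the covariate
median, a common convention); categorical covariates are linear.  Ties are
broken toward fewer added parameters, then lexicographically, and the full
ΔOFV trail is logged.  The candidate set is caller-supplied configuration:
the original analysis screened age, initial parasitemia, hematocrit,
admission temperature, sex and food on all parameters, a combinatorially
large set that is not hard-coded.

`full_covariate_food()` is the complementary estimation view: both food
effects (on MTT and on F) are entered simultaneously and their bootstrap
distributions, stratified by arm, display the clinical relevance of any
effect.  By default bootstrap replicates re-estimate only the two food
slopes with all other parameters held at their point estimates — a
deliberate desk-scale choice (a full refit per replicate is available via
`refit = "full"`); the reported intervals therefore reflect sampling
variability of the food contrast conditional on the remaining parameters,
which slightly understates their width.

## Model evaluation

`vpc()` simulates replicate studies at the original design (default 2000),
bins by nominal scheduled time without smoothing, and reports the 95%
confidence band of the simulated 5th/50th/95th percentiles together with
the fractions of observations outside the simulated 90% prediction
interval, with percentile CIs taken over the simulated replicates.  Whether
BLQ records participate in the coverage counts is exposed as a flag
(`blq_in_coverage`, default off, counting them at LLOQ/2 when on), since
either convention is defensible.

`bootstrap_fit()` resamples subjects with replacement within food strata
(each replicate keeps 15 fed + 15 fasting at the default design), refits,
and reports 2.5–97.5 percentile intervals and RSE = 100·SE/mean.  It is the
uncertainty method of this package; no asymptotic covariance step is
provided.

`secondary_params()` derives per-subject post hoc parameters from the
empirical Bayes estimates: CL/F and total V/F per kg, terminal half-life,
AUC from 0 to day 138 as `sum(dose_base * F_occ)/CL` (exact for a linear
system, and checked against trapezoidal integration in the tests), Cmax and
Tmax on a dense 0.01-h grid over the dosing phase, and the day-7 (168 h)
concentration, with fed/fasting Mann–Whitney comparisons (exact for eight
or fewer subjects per group, normal approximation with tie and continuity
correction otherwise).

## Monte Carlo mapped power

The mapped-power question: how large must a categorical food effect on F be
before a study of 15 + 15 patients detects it by a 1-df likelihood-ratio
test?  For each effect size `e` on a 5–50% grid, a large cohort (default
1000 patients at paper scale; 200 at the desk scale used by the tests) is
simulated with F multiplied by `1 + e` in the fed half; the full model
(food effect estimated) and the reduced model (none) are evaluated on the
cohort; and each patient's ΔiOFV = iOFV(reduced) − iOFV(full) is recorded.
Because the OFV is additive, the ΔiOFVs sum exactly to the full-cohort LRT
statistic.  Resampling 15 ΔiOFVs per arm (10,000 bootstrap draws) and
comparing the summed statistic with 3.84 and 6.63 maps the per-patient
signal back to the original study size; power is the exceedance fraction.
A null cohort (effect 0) is prepended by default as a type-I calibration —
the published patient count is consistent with the 5–50% grid plus such a
null set, and including it makes the calibration explicit.

By default the full-model estimation profiles only the food effect, holding
typical values and variances at the final model (`reestimate = "food"`).
This keeps the desk-scale map tractable — the reduced model then needs no
optimisation at all — while retaining the per-patient likelihood-ratio
signal for the covariate of interest; `"food_variance"` and `"full"`
progressively re-estimate more.  Note that the power at effect 0 estimated
from a *single* null cohort is conditional on that cohort's fitted food
effect and is therefore itself a random quantity with a roughly chi-squared
likelihood-ratio behind it; it concentrates near the nominal level as the
simulated cohort grows.

`ttest_power()`/`ttest_power_min_effect()` reproduce the traditional
comparison: a two-sided Welch t test on total exposure with the fed-group
SD assumed proportional to its mean, solved for the smallest detectable
fractional difference at 80% power.

## Problem sizes

The shipped tests and the acceptance script run at desk scale, the
package's own default for a single-workstation analysis: parameter-recovery
refits use 200 virtual patients (100 per arm) in a single replicate; the
power map uses 200 simulated patients per effect size with 10,000 bootstrap
draws; VPC self-calibration uses 300 simulated studies; bootstrap examples
use tens of replicates.  The original-study settings (2000 VPC simulations,
1000 bootstrap replicates, 1000 patients per effect size) are plain
argument changes and are exposed through the pipeline configuration
(`scale: paper`).  At the reduced cohort sizes the Monte Carlo error of the
power curve widens; the smallest effect reaching 80% power is read from the
monotone (cumulative-maximum) envelope of the curve.

## Known limitations

* The estimator is FOCE-I, not an exact-likelihood method; its
  Gauss–Newton Laplace term is verified against adaptive quadrature only on
  low-dimensional cases.
* Omega is diagonal; correlated random effects are out of scope.
* Bootstrap and full-covariate defaults re-estimate a reduced parameter
  set per replicate (see above) unless asked otherwise.
* The reported CV transform is the conventional log-normal form
  `100 * sqrt(exp(omega2) - 1)`; one published table footnote prints the
  same quantity without the square root, which is read here as a
  typographical shorthand for the conventional form.
* The simulator's demographic model is a pragmatic Beta fit to medians and
  ranges; tails and covariate correlations are not identified by the
  published summaries.
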