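---
title: "Simulating serosurvey data with serogen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating serosurvey data with serogen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serogen)
```

## The generative model

Serological surveys measure biomarker quantities — typically antibody
titers — and analysts then infer hidden epidemiological quantities
(force of infection, attack rates, waning rates) from them. serogen
simulates the whole chain that produces such data, so that inference
methods and study designs can be evaluated against a known truth. The
chain has four layers, evaluated for every individual $i$, time step
$t$, exposure type $x$ and biomarker $b$:

1. **Exposure.** A force of exposure $\lambda_{g,t,x}$ (a per-time-step
   rate, possibly group- and time-varying) gives the probability of an
   encounter, $P(E_{i,t,x}=1) = h(\lambda_{g,t,x}, D_i)$. The bundled
   `exposure_model_simple_FOE` uses $1 - e^{-\lambda_{g,t,x}}$;
   `exposure_model_dem_mod` first multiplies $\lambda$ by per-covariate
   modifiers (e.g. age- or nutrition-dependent exposure) so the result
   remains a valid probability.
2. **Immunity.** Given an encounter, the probability that it elicits a
   measurable immunological response is
   $P(Z_{i,t,x}=1 \mid E_{i,t,x}=1) = m(Z_{i,j<t}, \Theta_i, D_i)$,
   conditioning only on history strictly before $t$. Bundled models:
   always-successful; per-type event caps with vaccine age eligibility
   (`immunity_model_vacc_ifxn_simple`); and biomarker-mediated
   protection (`immunity_model_biomarker_protection`), where the
   success probability declines with the current quantity of the
   protective biomarker(s).
3. **Antibody kinetics.** The latent quantity is a deterministic
   function of the immune history and per-event realized parameters,
   $A_{i,t,b} = f(Z_{i,j \le t, x}, \Theta_i, D_i)$. The monophasic
   model sums, over successful events at times $t'$, contributions
   $\text{boost} \cdot \max(0,\, 1 - \text{wane}\,(t - t'))$; the
   biphasic model adds a short-lived and a long-lived component per
   event. Parameters are realized per event by a `draw_parameters`
   function: fixed effects (the population mean) or random effects
   (independent draws per event and individual).
4. **Observation.** Observed values follow
   $Y_{i,t,b} \sim q(A_{i,t,b}, \Theta)$: Gaussian assay noise around
   $A$, imperfect sensitivity (false negatives reported as exactly 0),
   imperfect specificity (false positives drawn uniformly from the
   observable range), detection limits enforced by clamping, and
   optionally discretized titers. A sampling design restricts which
   $(i, t, b)$ cells are measured.

The engine (`simulate_serosurvey()`) collapses layers 1–2 into a single
Bernoulli trial per cell,
$Z_{i,t,x} \sim \text{Bernoulli}(\phi_{i,t,x})$ with
$\phi_{i,t,x} = P(E=1)\,P(Z=1 \mid E=1)$, which is distributionally
identical to drawing the encounter and its success separately. Any layer
can be replaced by a user function with the documented signature; the
model registry (`register_model()`) makes such plug-ins addressable from
configuration files.

## The quickstart scenario

`quickstart_inputs()` assembles the package's reference scenario: 100
individuals over 120 monthly time steps; one circulating pathogen
(exposure type 1, constant force of exposure 0.01/month) and one vaccine
(exposure type 2, 0.1/month), both boosting the same IgG biomarker; at
most one successful infection and one successful vaccination per
individual, with vaccine eligibility from age 9 months; monophasic
kinetics with log-normal random effects; and a cross-sectional sample of
everyone at the final month.

```{r quickstart}
inputs <- quickstart_inputs(n_individuals = 100, seed = 1)
res <- do.call(simulate_serosurvey, c(inputs, list(seed = 2)))
res
summarize_run(res, threshold = 1)$event_counts
```

The kinetics parameter table follows the layout
(exposure, biomarker, name, mean, sd, distribution):

```{r model-pars}
quickstart_model_pars(labels = TRUE)
```

with infection boosts of mean 4 (sd 2) IgG units waning at 0.0033 per
month (about 40% decay over the 10-year window), vaccination boosts of
mean 2 (sd 1) waning at 0.0016 per month, and assay noise sd 0.25. The
assay has sensitivity 85% and specificity 90% over the observable range
[0, 10]; the range is required because false positives are sampled
uniformly from it.

## Parameterization choices

Several functional forms the framework needs are not uniquely pinned
down by the verbal description of the processes; the package makes the
following choices and treats them as part of its definition.

* **Log-normal scale.** The `mean`/`sd` columns of the parameter table
  are interpreted on the natural scale: a boost row with mean 4 yields
  draws whose expectation is 4. The underlying log-scale parameters are
  moment-matched, $\sigma^2 = \ln(1 + (sd/mean)^2)$,
  $\mu = \ln(mean) - \sigma^2/2$.
* **Linear waning.** Each event's contribution decays linearly and is
  floored at zero. Anchors are exact — the full boost at the event time,
  zero beyond $1/\text{wane}$ steps; the shape between anchor points is
  a modeling choice, and analyses should not lean on it. With the
  quickstart waning rate, 0.0033/month, an infection boost retains about
  60% of its size after 10 years.
* **Per-event draws.** Random-effects parameters are realized per
  successful event (not once per individual), so re-exposures get
  independent kinetics; the fixed-effects model collapses this
  distinction.
* **Protection curve.** Biomarker-mediated protection uses a
  two-parameter logistic, $1 - 1/(1 + e^{-k(a - a_{50})})$, plus a
  hard-threshold mode (its steep limit). Quantities of multiple
  protective biomarkers are summed, weighted by
  $e^{-\sigma d}$ when the biomarker map carries antigenic distances.
* **False negatives are 0.** A missed positive is reported as exactly 0
  even when the assay's lower bound is above 0; the zero is a code, not
  a measurement, and collides with the bound on purpose.
* **Floor-then-clamp discretization.** Discrete assays floor nonzero
  observed values and clamp them into the integer detection range;
  dilution-ladder assays (e.g. haemagglutination inhibition) are
  represented by expressing $A$ in log-dilution units upstream.
* **Activity convention.** An individual is exposable and observable on
  the half-open interval $[\text{birth}, \text{removal})$; all outputs
  carry `NA` outside it. Age is $t - \text{birth}$ in time steps.
* **Within-step ordering.** Cells are visited time-outer,
  individual-middle, exposure-inner on one sequential RNG stream; a
  success at time $t$ influences immunity decisions from $t+1$ onward
  only. Reproducibility is defined by this ordering and the seed;
  bit-compatibility with other implementations of the same processes is
  not a goal, only distributional equivalence.
* **Removal times.** Birth times are uniform over the time grid. With
  probability `prob_removal` an individual receives a removal time
  uniform over the integers after its birth; an individual born at the
  final step cannot be removed. Both are conventions of this generator,
  not properties the framework depends on.

## Threshold evaluation

Because the simulated truth is known, `threshold_sweep()` can measure
what a seropositivity threshold would conclude: each observed individual
is labeled truly positive iff at least one successful infection-type
event occurred at or before its sampling time (vaccination alone never
counts as truth-positive, so vaccinated-but-uninfected individuals push
false positives at low thresholds — this drives the
specificity-vs-threshold trade-off), classified by `Y >= threshold`
(ties positive), and confusion matrices are pooled (micro-averaged)
across replicates.

```{r sweep}
sweep <- threshold_sweep(quickstart_inputs(n_individuals = 50,
                                           n_times = 60, seed = 3),
                         thresholds = c(0.5, 1, 2, 4),
                         n_replicates = 3, seed = 4)
sweep[is.na(sweep$replicate), ]
```

Specificity is nondecreasing and sensitivity nonincreasing in the
threshold by construction of the classifier.

## What the generator does and does not emulate

The synthetic scenarios exercise the mechanisms the framework models:
time-varying exposure rates, event caps, age eligibility,
biomarker-mediated protection, per-event kinetics heterogeneity, assay
noise, misclassification and detection limits. They do not emulate
transmission dynamics (no dependence of the force of exposure on
prevalence; epidemic feedback must be supplied via a time-varying FOE
grid or fixed histories), batch effects or cross-channel noise in
multiplex assays, migration between groups, or antigenic drift beyond
per-pair distances in the biomarker map. Tests passing on these
scenarios therefore validate the simulator's bookkeeping and
calibration, not the realism of any particular epidemiological
parameterization.

## Numerical and testing notes

Degenerate inputs are defined rather than accidental: `sd = 0` or an
empty distribution label makes a parameter deterministic; a zero force
of exposure yields structurally zero event probabilities; an empty
kinetics history evaluates to $A = 0$ everywhere active. Probabilities
at extreme rates saturate at double precision ($1 - e^{-\lambda}$ is
indistinguishable from 1 beyond $\lambda \approx 37$).

The test suite checks closed-form kinetics against an independent
step-by-step accumulator, assay calibration and random-effects moment
recovery at $n = 10^5$ within three Monte-Carlo standard errors, the
exact factorization $\phi = P(E)\,P(Z \mid E)$ over simulated grids, and
the gating invariants over replicate full-size quickstart runs (100
individuals, 120 steps, 25 replicates); sweep properties use reduced
sizes (50 individuals, 60 steps, 3 replicates) chosen to keep the suite
quick while leaving the binomial error bands decisive.
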