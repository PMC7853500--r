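---
title: "Modelling laminar connectivity change in evoked potentials with tcdcm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling laminar connectivity change in evoked potentials with tcdcm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcdcm)
```

## The scientific problem

Sensory long-term potentiation (LTP) paradigms induce lasting changes in
visually evoked potentials with high-frequency ("photic tetanus") visual
stimulation.  The measured change is a waveform difference between
pre-tetanus and post-tetanus evoked responses; the scientific question is
*which synaptic connections changed*.  tcdcm addresses this by fitting a
biophysical generative model of one visual-cortical column plus its
thalamic loop to the per-condition evoked responses of each subject, so
that condition differences in the waveform are explained by condition
differences in specific inter-population coupling gains and receptor time
constants.

The package provides the full analysis chain: the conductance neural-mass
model and its integrator (`tc_model()`, `tc_integrate()`), the
observation/contrast layer (`simulate_erp()`, `condition_design()`),
per-subject variational inversion (`invert_evoked()`), fixed- and
random-effects Bayesian model selection (`ffx_bms()`, `rfx_bms()`), group
statistics on parameter estimates (`rm_manova()`,
`univariate_followups()`), and a seeded synthetic-cohort generator
(`generate_cohort()`) so every stage is testable end to end without any
empirical recording.

## The generative model

Eight populations form one thalamocortical column: layer IV spiny
stellates (ss), superficial pyramidal cells (sp) and inhibitory
interneurons (si) in layer II/III, deep pyramidal cells (dp) and deep
interneurons (di) in layer V, cortico-thalamic projection cells (tp) in
layer VI, and thalamic relay (rl, excitatory) and reticular (rt,
inhibitory) populations.  Each population's mean potential obeys

$$C\,\dot V = g_L\,(V_L - V) + \sum_n g_n\,(V_n - V) + u,$$

with the NMDA term additionally multiplied by the magnesium-block gate
$f(V) = 1/(1 + 0.2\,e^{-\alpha V})$, and each channel conductance relaxes
towards the coupled presynaptic firing,
$\dot g_n = \kappa_n(\varsigma_n - g_n)$ with
$\varsigma_n = \sum_j \gamma_{ij}\,\sigma(\mu_{V_j} - V_R)$.  The firing
function $\sigma$ is the Gaussian cumulative distribution of the
presynaptic depolarisation around the threshold $V_R = -40$ mV.
Excitatory sources couple through AMPA and NMDA conductances, inhibitory
sources through GABA-A and GABA-B.  M- and H-currents exist only on tp
and rl; because the main-text model family does not specify their drive,
they are implemented as intrinsic voltage-dependent conductances (M
activation equals the firing sigmoid of the population's own potential, H
activation its complement, so H is active at hyperpolarised potentials
and depolarises the thalamic populations towards a realistic resting
point above the leak reversal).  Thalamo-cortical edges are delayed by 3
ms and cortico-thalamic edges by 8 ms; intra-compartment connections are
instantaneous.

Twelve connections — rl→ss, ss→ss, ss→sp, ss→si, si→sp, si→si, sp→sp,
sp→si, si→ss, sp→dp, dp→tp, tp→rl — plus the AMPA and NMDA decay rates
are estimable; all remaining edges (a canonical-microcircuit completion:
ss→dp, sp→di, dp→di, di→dp/di/tp, tp→rt, rl→rt, rt→rl/rt) are fixed.
Since the original supplementary parameter tables are not available, the
kinetic defaults are the published conventions of this model family
(decay time constants AMPA 4 ms, GABA-A 16 ms, NMDA 100 ms, GABA-B 200
ms, M 160 ms, H 100 ms; reversal potentials 60, −90, 10, −100, −70, −30
mV), and every value is overridable through `tc_model()`.

### Parameters that matter, and their defaults

| Parameter | Default | Units | Role |
|---|---|---|---|
| `V_R` | −40 | mV | firing threshold (sigmoid half-activation) |
| `Sigma` | 8 | mV | firing dispersion; one SD of the firing CDF |
| `V_L`, `g_L` | −70, 1 | mV, — | leak reversal and conductance |
| `C` | 8 | — | capacitance; leak time constant 8 ms |
| `delay_tc`, `delay_ct` | 3, 8 | ms | conduction delays |
| `alpha_NMDA` | 0.06 | 1/mV | magnesium-block steepness |
| connection gains | 0.3–2 | — | see `tc_model()$gains` |

The default coupling strengths and the input amplitude/width were chosen
once so that the column produces a physiologically plausible damped
evoked response — a graded primary deflection near 90 ms followed by a
smaller thalamocortical reverberation near 180 ms, with no up-state
latching and no saturation of the firing sigmoid — before any recovery
experiment was run.  With the steeper dispersion of ~4 mV the column
behaves almost bistably (all-or-nothing responses), which is both
biologically implausible for trial-averaged evoked responses and hostile
to gradient-based inversion; `Sigma = 8` mV keeps the operating point
graded.

### Numerics

The integrator is a fixed-step 4th-order Runge-Kutta scheme (default
`dt = 0.25` ms, output resampled to 1 ms) with delayed presynaptic firing
read from a stored history by linear interpolation *at each stage time*;
since the delays far exceed the step, the required history always
predates the current step.  This keeps the observed step-halving
convergence near second order (halving `dt` from 0.25 ms changes terminal
voltages by under 1e-3 mV).  Steady states are found by damped Newton
iteration on the voltage nullcline (at a fixed point every conductance
equals its coupled firing target, which reduces the root-finding problem
to the eight population voltages), with a relaxation-integration fallback
when a candidate parameter point puts the resting Newton start outside
the attractor's basin.  Zero-length spans and non-positive steps are
rejected, not clamped.

## Condition effects and observation

Condition-specific change is encoded by a between-condition general
linear model over three conditions (pre, early post, late post):
`nonlinear` `[-1 1 0]` captures an early-peaking change (short-term
potentiation contaminating the first post block), `linear` `[-1 0 1]` a
monotone change largest late (classic LTP time course), and
`combination` stacks both rows.  Every free quantity q is scaled
multiplicatively, $q \cdot \exp(\theta_q + \sum_k \beta_{kq} X_{kc})$ —
the log-space link guarantees positivity for any real effect size and
makes effect sizes comparable across quantities.

The observed channel is a fixed non-negative lead field over population
depolarisations, dominated by the superficial pyramidal population
(weights sp 0.8, dp 0.1, tp 0.1), times an estimable scalar gain.  Only
the gain is estimated by default; the Gaussian input's onset (64 ms) and
width (8 ms) are fixed, a documented package choice in the absence of a
stated empirical configuration.

## Inversion

`invert_evoked()` implements variational Laplace: Gauss-Newton updates of
the posterior mean using central finite-difference sensitivities (step
1e-3 in log space) of the concatenated three-condition prediction, a
closed-form Laplace covariance, and an observation precision updated
between parameter steps under a weak Gamma hyperprior.  The free energy
F = accuracy − complexity is recomputed consistently (fresh sensitivities)
at every accepted step; a step is accepted only if F does not decrease,
with step-size halving otherwise, so the recorded trace is non-decreasing
by construction.  Between full evaluations the optimiser takes up to
`inner_steps` cheap refinement steps that reuse the current sensitivities
(a lagged-Jacobian Gauss-Newton acceleration); candidates that leave the
feasible regime (no reachable steady state) are treated as rejected
steps.  Priors are zero-mean Gaussians with variance 1/16 for connection
and decay log-scalings, 1/8 for effect sizes, 1/16 for the log gain —
package defaults standing in for unavailable source tables, all
overridable via `default_priors()`.  Convergence: change in F below 0.01
nats for 3 consecutive iterations, or `max_iter`.  Initialisation is at
the prior mean; `settings$init` allows warm-starting, which the package
uses to initialise the combination model from the better of its nested
single-row fits (this only tightens the evidence bound, so model
comparison remains conservative for the larger model).

For a linear-Gaussian model with the exact posterior, the implemented F
equals the analytic log evidence; the test suite verifies this to 1e-6
and checks monotonicity of every accepted trace.

## Model selection and group statistics

Fixed-effects BMS sums F over subjects per model; differences of summed F
are group log-Bayes factors and posterior model probabilities follow from
a uniform model prior.  Random-effects BMS implements the variational
Dirichlet model of between-subject model frequencies; exceedance
probabilities are Monte-Carlo estimates from 1e5 Dirichlet samples under
a fixed seed, the Bayesian omnibus risk (BOR) compares the frequency
model against the equal-frequency null, and the protected exceedance
probability is pxp = xp·(1−BOR) + BOR/K.  A Gibbs-sampler oracle for the
same model lives in the test suite only and agrees with the variational
expected frequencies within 0.05 on toy tables.

Group statistics consume condition-specific parameter *values*
(`condition_parameters()`: baseline coupling times the fitted
exponential scaling; decay entries as time constants in ms, so a
lengthened AMPA time constant appears as an increase), not raw effect
sizes — matching how such estimates are usually plotted and tested.  The
repeated-measures MANOVA tests the within-subject condition effect on
difference scores against the pre condition: Wilks'
λ = det(E)/det(E+H) via the eigenvalues of E⁻¹H with Rao's F (exact
here, as the hypothesis has one degree of freedom).  Univariate
follow-ups are one-way repeated-measures ANOVAs per parameter, reported
with and without Greenhouse-Geisser correction and with the per-parameter
multivariate (Hotelling) p for reference — the multivariate version is
the one that coincides exactly with the MANOVA when a single parameter is
tested, since the sphericity-assuming univariate F is a different
statistic.  Benjamini-Hochberg FDR correction is applied across
parameters (to the Greenhouse-Geisser p by default).  The MANOVA requires
more subjects than dependent variables (two difference scores per
parameter); `run_pipeline()` subsets to the strongest univariate
parameters when a cohort is too small for all 14, and reports which.

## The synthetic-cohort generator

`generate_cohort()` emulates the data shape of a 20-subject,
three-condition visual-LTP study: per subject, source-level evoked
responses on a 0–300 ms grid at 1000 Hz, generated from the model itself
with subject-level log-scalings θ ~ N(0, 0.25²) (matching the inversion
prior), shared condition effects, and additive white Gaussian noise
scaled per condition to a target signal-to-noise variance ratio (default
5).  Randomness is split per subject, so subject i's data are invariant
to cohort size, and byte-identical for identical seeds.  Default effect
magnitude is 0.2 log units — large enough to move the waveform visibly at
SNR 5, small enough that recovery is not trivial; a package choice, not
an empirical value.  `canonical_ltp_scenario()` freezes the effect
pattern that mirrors the qualitative findings of visual-LTP work:
linear increases on rl→ss, ss→sp, sp→sp, si→ss and nonlinear effects on
ss→sp, ss→si, a *decrease* on sp→dp, and a decreased AMPA decay rate
(i.e. a lengthened AMPA time constant).

What the generator deliberately does not emulate: 1/f background
activity (a pink-noise flag exists for robustness checks only),
trial-level variability, eye or muscle artefacts, sensor-level volume
conduction, or the photic tetanus itself.  Passing recovery tests
therefore demonstrate the internal consistency of the pipeline under the
model's own assumptions — white noise, correct model class, known lead
field — and not robustness to the many ways real EEG violates them.

## Desk-scale study conditions and known limitations

The test suite and the acceptance script run everything at desk scale,
the package's documented study conditions: integration step 0.5 ms for
cohort experiments (0.25 ms default elsewhere), cohorts of 2–10 subjects,
iteration caps of 4–8 with the inner refinement enabled, and 10 seeded
repetitions per experiment.  These choices are stated here once and used
everywhere.

Two limitations are worth knowing about.  First, *equifinality*: serial
gains along the same afferent chain (rl→ss and ss→sp, both read out
through an sp-dominated lead field) trade off almost freely, so
per-parameter point estimates redistribute gain among confounded
parameters even at high SNR.  Cohort-mean effect *signs* recover
reliably, and so does the FDR flag on the strongly potentiated pathway,
but rank correlations between true and estimated per-parameter effect
profiles are low (~0–0.4 in our experiments) — a property of the model
class at these study conditions, not an optimiser defect (explained
variance reaches the SNR ceiling).  Interpret individual connection
estimates with the posterior covariance in hand, and prefer model-level
(BMS) and group-level (MANOVA/FDR) statements.  Second, the free energy
is a local Laplace bound: under-converged fits under-estimate the
evidence of flexible models, which is why the combination model is
warm-started from its nested fits in all comparisons.
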