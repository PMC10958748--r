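---
title: "Modeling left-turn gap acceptance with a generalized drift-diffusion model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling left-turn gap acceptance with a generalized drift-diffusion model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The decision problem

A driver waiting to turn left across the path of an oncoming car must decide,
within a closing window of opportunity, whether to go before the car arrives
or stay until it has passed. `gapddm` models this decision as noisy evidence
accumulation. The relative evidence $x$ for going over staying evolves as

$$dx = \alpha\,\big((\mathrm{TTA}(t) + \beta d(t)) - \theta_{crit}\big)\,dt + dW,$$

where $\mathrm{TTA}(t)$ and $d(t)$ are the current time-to-arrival and
distance of the oncoming car. Because the car moves at constant speed
$v = d_0/\mathrm{TTA}_0$, both quantities fall linearly during the decision:
the perceptual input itself is time-varying, unlike in classical
constant-stimulus accumulation tasks. The drift gain $\alpha \ge 0$ scales the
input ($\alpha = 0$ makes decisions pure diffusion), $\beta$ (s/m) weighs
distance against time, and $\theta_{crit}$ (s) is the combined-gap size at
which the momentary evidence is neutral.

Accumulation terminates at absorbing boundaries $\pm b(t)$ that collapse as
the time gap shrinks:

$$b(t) = \pm\, b_0\, f(\mathrm{TTA}(t)), \qquad
  f(\mathrm{TTA}) = \frac{1}{1 + e^{-k(\mathrm{TTA} - \tau)}}.$$

When the oncoming car is far away in time the driver can afford to
accumulate a lot of evidence ($f \approx 1$); as $\mathrm{TTA}$ falls through
$\tau$ the boundary passes its half-collapsed baseline $\pm b_0/2$ and the
decision is forced with less and less evidence. This mechanism lets the model
produce *slower* go responses at *longer* time gaps — the opposite of what a
fixed-boundary accumulator predicts, and the pattern that separates the full
model from its restricted variants.

Observed response time for a go decision is decision time plus a normally
distributed non-decision time $t_{ND} \sim N(\mu_{ND}, \sigma_{ND})$
accounting for perception and motor delays. The diffusion coefficient is
fixed at 1, so all evidence quantities are expressed on the noise scale; the
accumulator starts unbiased at $x(0) = 0$.

Two reduced variants serve as comparison models: a basic drift-diffusion
model with one free constant drift rate and a constant boundary
(`const_drift_const_bound`, 4 free parameters), and a model that keeps the
time-varying drift but holds the boundary constant
(`var_drift_const_bound`, 6 free parameters). The full model has 8.

## Numerical solution

`solve_fpt()` propagates the evidence density with a Crank–Nicolson scheme
on a fixed evidence grid; the time-varying boundary is absorbed at the
nearest grid line, and discrete boundary fluxes are extracted from the exact
mass balance of the scheme, so probability is conserved to numerical
round-off. The first few steps use backward Euler (Rannacher smoothing) to
damp the oscillations a delta initial condition otherwise excites under
Crank–Nicolson. Default grids are $dt = 0.005$ s and $dx = 0.01$ evidence
units, which reproduce the constant-coefficient closed forms
($P(\mathrm{upper}) = 1/(1+e^{-2\mu B})$, mean first-passage time
$(B/\mu)\tanh(\mu B)$) to about $10^{-5}$ and 0.3% respectively. Because the
drift does not depend on $x$, central differencing is oscillation-free as
long as $|\mu|\,dx < 2$ (cell Péclet condition with diffusion $1/2$);
parameter vectors violating it are refused rather than solved inaccurately,
and the fitter treats such refusals as infeasible candidates.

Integration stops at the arrival time $t_{max} = \mathrm{TTA}_0$: a go
decision after the car has arrived is physically impossible, so any still-
undecided probability mass is censored into the stay outcome. The collapsing
boundary makes this censored mass small for the full model. Inside the drift,
$\mathrm{TTA}(t)$ and $d(t)$ are clamped at zero past arrival (relevant only
when a longer horizon is requested); the boundary gain is evaluated on the
unclamped $\mathrm{TTA}$, whose logistic tends to zero on its own.

`simulate_trials()` is an independent Euler–Maruyama realization of the same
process, used as a cross-check of the density solver and as the trial
generator for synthetic datasets. A plain post-step boundary check misses
within-step excursions and biases first passages late by $O(\sqrt{dt})$
(measured at $dt = 0.005$: go probability off by $\approx 0.015$, RT
quantiles late by 0.01–0.03 s — comparable to the effects under study), so
the simulator applies the standard Brownian-bridge correction: after each
step with endpoints still inside the boundaries, the bridge crosses a bound
at distances $(b - x_0)$ and $(b - x_1)$ with probability
$e^{-2(b-x_0)(b-x_1)/dt}$. With the correction, simulator and solver agree
to within Monte-Carlo error at $dt = 0.001$; the dataset generator uses
that step.

## Fitting

The fitting target is one summary per condition: the go probability and the
go-RT quantiles at levels 0.1, 0.3, 0.5, 0.7, 0.9. The objective is a
weighted least-sum score,

$$\sum_c \Big[ w_p\, n_c (p_c - \hat p_c)^2
   + w_q\, n_{go,c} \sum_\ell (q_{c\ell} - \hat q_{c\ell})^2 \Big],$$

with defaults $w_p = 2$, $w_q = 1$. Stay decisions contribute only through
the go probability: the task provides no observable stay response time.
Quantile terms are dropped for conditions with fewer than four go decisions
(whose empirical quantiles are meaningless) and for candidate parameters
predicting essentially no go responses.

Minimization uses differential evolution (best/1/bin, $CR = 0.9$, with the
differential weight dithered uniformly in $[0.5, 1]$ each generation —
fixed-weight best/1/bin loses population diversity and stalls on the
plateau regions of this objective, where entire parameter blocks predict
all-go or all-stay in every condition). Out-of-bound proposals are
reflected back into the search box, and a seed is required, so every fit is
exactly reproducible. An optional bounded Nelder–Mead pass (`polish`)
refines the returned solution, which pays off at tight evaluation budgets. Default bounds span
the physically plausible range for this design: $\alpha \in [0,5]$,
$\beta \in [0,1]$, $\theta_{crit} \in [2,20]$, $b_0 \in [0.5,5]$,
$k \in [0.05,5]$, $\tau \in [1,10]$, $\mu_{ND} \in [0,1.5]$,
$\sigma_{ND} \in [0.01,0.5]$.

Group-level targets can be built two ways. `group_summaries()` follows the
convention of averaging each participant's own statistics: go probability as
the unweighted mean of within-participant go rates, and RT quantiles by
vincentizing (averaging per-participant quantile functions at fixed levels;
the group CDF is the inverse of the averaged quantile function, computed by
swapping the axes of the level–quantile pairs). `summarize_conditions()`
pools trials directly. With few go responses per participant and condition,
per-participant quantile functions are estimated from a handful of order
statistics and vincentized tails regress toward the median, so for
homogeneous populations (as in parameter-recovery simulations) the pooled
summaries are the unbiased group target and are what the recovery analyses
use; vincentization earns its keep when participants genuinely differ.

## Cross-validation and model comparison

`run_cv()` implements the hold-one-condition-out scheme: for each of the
nine cells of the TTA × distance grid, the model is fitted to the other
eight conditions and the fitted parameters are used to predict the held-out
cell's go probability and mean go-RT. Folds are ordered by the deterministic
condition-grid order (TTA-major), and each fold's seed derives from the
master seed plus the fold index. Perturbing a held-out condition's observed
data changes nothing about that fold's fit or predictions — leakage is
structurally impossible and tested.

`cmd_compare()` fits the full model and both restricted variants to the same
summaries with the same seed. On data generated by the full model, the
characteristic discrimination pattern is the sign of the RT–TTA relation at
fixed distance: the full model reproduces go-RTs increasing with the TTA
condition, while constant-boundary variants predict flat or decreasing RTs
because stronger evidence can only speed a fixed-threshold accumulator.

## The synthetic population

`generate_dataset()` emulates the structure of the driving-simulator study
the model targets: 16 participants, 8 routes with 15 left turns each
(120 per participant), initial TTA drawn balanced — exactly five turns per
TTA level (4, 5, 6 s) per route — and initial distance (90, 120, 150 m)
uniform per trial, giving the implied constant oncoming speeds between 15
and 37.5 m/s. Decisions and go-RTs are simulated from each participant's own
parameters; participants are independent normal draws around group-mean
parameters (clipped to the parameter constraints), since nothing is known
about the correlation structure of individual differences.

The group means (α = 0.9, β = 0.065 s/m, θ_crit = 11.45 s, b₀ = 1.4,
k = 1.3 s⁻¹, τ = 3.4 s, μ_ND = 0.3 s, σ_ND = 0.06 s) were chosen once so
the simulated group reproduces the study-level facts reported for the real
population: an overall go rate close to 47%, go probability increasing in
both TTA and distance, mean go-RTs rising with the TTA condition while
staying well under 2 s (extreme RTs above 2 s are a roughly one-per-dataset
event), and a nearly empty shortest-gap cell (TTA = 4 s, d = 90 m). The
between-participant standard deviations are moderate fractions of the means,
producing visible but not degenerate individual differences.

Task-artifact exclusions are modeled as random labels, not mechanistically:
failing to come to a full stop (1.4% of left turns) and holding the gas
pedal down so no RT exists (0.5% of go decisions), plus the deterministic
exclusion of go-RTs above 2 s. `apply_exclusions()` removes flagged records
and reports counts per reason.

What the generator does not emulate: changes of mind and "rolling" starts,
post-decision acceleration, any correlation between a participant's
parameters, or condition order effects. Passing recovery tests on this
synthetic population therefore demonstrates that the pipeline is a faithful
estimator of the model's own data-generating process — not that the model is
true of human drivers.

## Numerical and design choices

* **Quantile convention.** Linear interpolation of order statistics
  (type 7) everywhere, the common vincentizing convention.
* **Vincentizing levels.** 19 levels, 0.05–0.95, for smooth group CDFs
  without extrapolating tails.
* **Non-decision time truncation.** The normal non-decision time is
  truncated at zero (rejection sampling; a plain normal admits negative
  delays). For fitted regimes $\mu_{ND} \gg \sigma_{ND}$ the truncation is
  negligible.
* **Observed RT composition.** RT = decision time + non-decision time; the
  observed-RT density is the discrete convolution of the go first-passage
  density with the truncated-normal kernel, renormalized to preserve mass to
  $10^{-3}$.
* **Restricted variants.** The constant-drift variant replaces
  $(\alpha, \beta, \theta_{crit})$ by one free drift constant; both
  restricted variants keep $b_0, \mu_{ND}, \sigma_{ND}$. These are the
  minimal restrictions consistent with "constant drift" and "constant
  bound".
* **Problem sizes.** Long-running analyses in the test-suite and the
  acceptance script use the simulation sizes of the emulated design
  (16 × 120 trials). Eight-parameter fits use a differential-evolution
  population near the standard 12 × dimension (96, up to ~120 generations)
  with the polish pass — about a minute per fit on the coarser
  $dt = 0.01$/$dx = 0.02$ grid, which reproduces the constant-coefficient
  closed forms to ~3 × 10⁻⁵ in probability. Cross-validation's nine fold
  fits run on a $dt = 0.02$/$dx = 0.04$ grid with all comparisons computed
  on that same grid. Monte-Carlo oracle comparisons use 5 × 10⁴ trials at
  a 1 ms step.

## Known limitations

* Parameter identifiability from choice proportions and five RT quantiles is
  limited: the boundary scale, non-decision mean, and non-decision spread
  trade off along a shallow valley of the objective, so point estimates of
  $b_0$ and $\sigma_{ND}$ from a single dataset of ~1900 trials carry
  substantial uncertainty even when the model is exactly true. The
  location parameters $\theta_{crit}$, $\tau$, and $\mu_{ND}$ are recovered
  much more reliably.
* The solver's nearest-grid-line boundary absorption floors the boundary one
  cell away from the start point; for boundaries far below $dx$ this slightly
  delays full collapse (immaterial at default grids).
* No across-trial variability in drift or starting point, no bias
  parameter, and no stay-RT information — all consequences of the modeled
  task, not implementation shortcuts.
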