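---
title: "Regression slopes, covariance structure, and the additivity assumption"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regression slopes, covariance structure, and the additivity assumption}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slopebench)
library(dplyr)
```

## The question

Sensorimotor adaptation to a visuomotor rotation is standardly decomposed
into implicit recalibration $I$ and explicit strategy $E$, assumed to sum at
motor output:

$$A = I + E,$$

with all three quantities in degrees of hand angle. This additivity
assumption licenses subtractive measurement ($I = A - E$ from aim reports,
or $E = A - I$ from process dissociation) and underlies most state-space
models of adaptation. A line of argument in the literature treats the
between-subject regression slope of $I$ on $E$ as a test of additivity: if
the processes sum, the slope should be $-1$, and observed "sub-additive"
slopes (shallower than $-1$) are read as evidence that they do not.

`slopebench` implements the analytic and simulation machinery needed to
examine that argument. The central point is a category distinction:
additivity is a within-individual claim about how components combine at
output, whereas a regression slope measures how components covary across
individuals. The package's closed forms and experiments make the
consequences of that distinction quantitative.

## Expected slopes

**Subtractive measurement.** If $I$ is derived as $A - E$, then

$$\beta_{I \sim E} \;=\; \frac{\mathrm{Cov}(A - E,\, E)}{\mathrm{Var}(E)}
\;=\; \rho_{A,E}\,\frac{\sigma_A}{\sigma_E} - 1 .$$

The benchmark $\beta = -1$ is recovered only when $\rho_{A,E} = 0$, i.e.
when total adaptation is uncorrelated with the measured component — a
condition additivity does not impose. With equal SDs the expression
simplifies to $\beta = \rho - 1$. `expected_slope_subtractive()` evaluates
this.

**Independent measurement.** If $I$ and $E$ are measured separately and
additivity is enforced by constructing $A = I + E$, the $I \sim E$ slope is

$$\beta_{I \sim E} \;=\; \rho_{I,E}\,\frac{\sigma_I}{\sigma_E},$$

the correlation scaled by the SD ratio (`expected_slope_independent()`).
Additivity constrains neither factor: a slope of $-0.3$ is equally
consistent with a weak correlation at equal SDs or a strong correlation
($\rho = -0.6$) compressed by $\sigma_I/\sigma_E = 0.5$.

```{r slopes}
expected_slope_subtractive(rho = 0, sigma_A = 2.5, sigma_E = 2.5)
expected_slope_independent(rho = -0.6, sigma_I = 1.25, sigma_E = 2.5)
```

**Shared-error coupling.** The shared-error model is an *additive* model
with coupled acquisition: the explicit strategy is drawn as
$E \sim N(\mu_E, \sigma_E^2)$ and the implicit system recalibrates toward
the residual rotation, $I = p_i (r - E)$, with $r$ the rotation magnitude
and $p_i \in [0,1]$ the implicit steady-state capacity. Measurement adds
independent Gaussian noise ($\tau_I$, $\tau_E$) to each component, and the
observed total is the sum of the noisy measures. Writing $v = \sigma_E^2$
and $a = 1 - p_i$, covariance algebra gives the three population slopes

$$\beta_{I \sim E} = \frac{-p_i v}{v + \tau_E^2}, \qquad
  \beta_{E \sim A} = \frac{a v + \tau_E^2}{a^2 v + \tau_I^2 + \tau_E^2}, \qquad
  \beta_{I \sim A} = \frac{-p_i a v + \tau_I^2}{a^2 v + \tau_I^2 + \tau_E^2}.$$

These closed forms are a contribution of this package; they are gated
behind a property test that checks them against a $10^6$-participant
simulation oracle over ten random parameter sets (agreement within three
Monte Carlo standard errors). Defining the observed total as the sum of
the *noisy* measures matters: with the canonical parameters below it gives
$(\;-0.325,\; 0.984,\; 0.016\;)$, whereas regressing on the noise-free
total would give $(\,-0.325,\; 2.857,\; -1.857\,)$ — only the former
matches what a study that computes $A$ from its own measurements would
estimate.

```{r shared}
params <- shared_error_params(r = 30, p_i = 0.65, mu_E = 12, sigma_E = 4,
                              tau_I = 2, tau_E = 4)
shared_error_expected_slopes(params)
```

**Attenuation of the loose-additivity slope.** Regressing $A$ on the sum
of the measured components is a more direct check ("loose additivity"),
but with noisy components the composite predictor has reliability below 1
and the slope is diluted:

$$\beta_{A \sim (I_{obs}+E_{obs})} = \frac{V}{V + \tau_I^2 + \tau_E^2},
\qquad V = \sigma_I^2 + \sigma_E^2 + 2\rho\,\sigma_I\sigma_E$$

(`attenuation_expected_slope()`). Slopes below 1 are therefore expected
under *exact* additivity whenever measurement is imperfect.

## What the generators emulate — and what they do not

All data in this package are synthetic steady-state populations; the
generators are first-class, tested code, and every one of them enforces
`total = implicit + explicit` exactly (bit-exactly: totals are stored as
the recomposed floating-point sum). That identity is asserted in the
regression tests precisely because the package's point is that slope
deviations arise *anyway*.

- `make_subtractive_triad()` samples $(A, E)$ from a bivariate normal and
  derives $I = A - E$, mirroring aim-report designs. Default moments in
  the experiments ($\mu_A = 25°$, $\sigma_A = 2.5°$, $\mu_E = 5°$,
  $\sigma_E = 2.5°$, $n = 25$) approximate a typical aim-report study arm.
- `make_independent_triad()` samples $(I, E)$ directly and constructs the
  total, emulating independent measurement under enforced additivity.
- `make_shared_error_population()` implements the shared-error model
  above. Explicit draws are *not* truncated — negative aims are allowed —
  because truncation would bias the analytic slopes.
- `make_iso_A_scenarios()` returns three 3-person populations showing that
  under exact additivity the $I$–$E$ correlation can be $-1$, $+1$ or
  $-1$ depending only on whether and how the total varies. The bar
  heights are illustrative; the correlations and the identity are the
  contract.

What the generators deliberately do **not** model: trial-by-trial learning
dynamics (only steady-state cross-sectional populations), temporal
instability of the component processes, measure-validity problems (aim
reports versus inclusion–exclusion contrasts), and any non-additive output
rule. Passing tests therefore show that the *statistical argument* holds
under the stated generative assumptions — they say nothing about whether
real motor output is additive, which is exactly the package's thesis about
regression slopes too.

## The experiments

Four drivers reproduce the simulation studies at their native scale
(10,000 iterations each runs in seconds here):

1. `run_subtractive_sweep()` — for each $\rho_{A,E}$ on a grid, 10,000
   datasets of $n = 25$, an $I \sim E$ fit each, and the rejection rate of
   the $\beta = -1$ benchmark by 95% CI exclusion. Calibrated (≈5%) only
   at $\rho = 0$; false rejection exceeds 50% by $|\rho| > 0.4$.
2. `run_independent_sweep()` — the same design with directly sampled
   $(I, E)$ at SD ratios 0.5/1/2 and benchmark $\beta = 0$.
3. `run_shared_error_study()` — one population of 1,000 shared-error
   participants, the three pairwise population slopes, and 10,000
   bootstrap resamples of $n = 25$ (with replacement; the standard
   bootstrap) for their sampling distributions.
4. `run_loose_additivity_study()` — a fixed additive base population
   (default $N = 1000$, $\sigma_I = \sigma_E = 2.5°$, $\rho = -0.5$), a
   noise grid $0$–$5°$ in $0.5°$ steps applied independently to both
   components, and bootstrap slope distributions of $A$ on
   $(I_{obs} + E_{obs})$ against the closed-form attenuation curve.

`residual_diagnostics()` supports the constructive alternative: residuals
$\varepsilon = A - I - E$ from independent measurements should be centred
on zero and uncorrelated with $I$, $E$, their product and their sum.
A multiplicative gating term leaves $\varepsilon$ correlated with
$I \times E$; a saturating output rule leaves residuals that grow more
negative with $I + E$. The function reports the mean residual and those
four correlations (defined as 0 when the residual is identically zero),
accepting any triad so users can probe their own generative models.

## Numerical and design choices

- **OLS engine.** Slopes are computed from the covariance-ratio definition
  with a $t$-based two-sided CI on $n - 2$ degrees of freedom; the test
  suite pins it to `stats::lm()` + `confint()` at $10^{-8}$ and to a
  two-pass covariance-ratio oracle at $10^{-10}$. Exactly collinear data
  collapse the CI to a point; benchmark rejection is CI exclusion with
  boundary values counted as non-rejections. No robust or
  errors-in-variables regression is provided — attenuation under predictor
  noise is part of the phenomenon being studied, though Deming-type fits
  are the natural remedy when an unbiased slope is the goal.
- **Rejection criterion.** CI exclusion rather than an explicit $t$-test
  of $H_0\!: \beta = \beta_0$; the two are numerically equivalent for a
  two-sided level.
- **Sampling.** Bivariate draws use an explicit 2×2 factorization;
  $|\rho| = 1$ is an exact rank-1 linear map, so the conceptual boundary
  cases (iso-A populations) carry no numerical fragility.
- **Seeding.** One master seed per experiment; every (condition,
  iteration) pair derives its own `set.seed()` value through a
  Lehmer-style integer mix modulo $2^{31}-1$ keyed on the condition's
  parameter values. Consequences, both tested: per-condition results are
  invariant to grid order, and doubling `iterations` leaves the first
  half of every condition's draws unchanged. All derived seeds stay below
  $2^{31}$.
- **Grid defaults.** $\rho$ from $-0.9$ to $0.9$ in steps of 0.1
  (endpoints as in the source analyses; the step is a package choice
  matching the visual density of the published curves). The loose-
  additivity base SDs ($2.5°$) sit in the range used by the other
  experiments and are arguments, not constants.
- **Tolerances.** Every sweep row carries Monte Carlo standard errors
  (`mc_se_slope`, `mc_se_rejection`); tests bound deviations at 3 MC SEs
  per condition, widening to 3.5–4 for maxima taken over a whole grid
  (a union-bound allowance decided before any run).
- **Problem sizes.** Moment-recovery and oracle-validation tests use
  $10^6$-draw samples; sweeps run at the native 10,000 iterations in the
  acceptance checks and at 500–2,000 iterations in unit tests, sizes
  chosen so the whole suite completes in well under a minute on one core.

## Known limitations

- The analytic shared-error slopes are exact for the stated Gaussian
  model only; a finite population of 1,000 participants scatters around
  them (the $I \sim E$ slope has a sampling SD of roughly 0.015 at
  $N = 1000$), which is why the reference value $-0.35$ from a single
  published run differs from the analytic $-0.325$. The package never
  treats the single-run value as truth.
- CSV output is the contract surface; figures are conveniences and make
  no attempt at pixel-level replication of any published styling.
- `fit_slope()` is plain OLS and inherits its assumptions; the package
  quantifies what happens when the predictor is noisy rather than
  correcting for it.
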