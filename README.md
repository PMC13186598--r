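# slopebench

Covariance-structure benchmarks for regression slopes in sensorimotor
adaptation.

## The problem

Adaptation to a visuomotor rotation is standardly decomposed into implicit
recalibration *I* and explicit strategy *E*, assumed to combine additively
at motor output: *A* = *I* + *E* (all in degrees of hand angle). A popular
test regresses one component on the other across participants and compares
the slope to a benchmark — *β* = −1 when *I* is derived by subtraction
(*I* = *A* − *E*), *β* = 0 under independent measurement — reading
deviations as evidence that the components fail to sum.

`slopebench` provides the machinery to examine that inference. The
between-subject OLS slope is fixed by covariance structure, not by the
combination rule:

- subtractive measurement: *β* = *ρ*<sub>A,E</sub>·*σ*<sub>A</sub>/*σ*<sub>E</sub> − 1,
  so *β* = −1 holds only when total adaptation is uncorrelated with the
  measured component;
- independent measurement: *β* = *ρ*<sub>I,E</sub>·*σ*<sub>I</sub>/*σ*<sub>E</sub>,
  which additivity does not constrain at all;
- shared-error coupling (*E* ~ N(*μ*<sub>E</sub>, *σ*<sub>E</sub>²),
  *I* = *p*<sub>i</sub>(*r* − *E*), independent measurement noise
  *τ*<sub>I</sub>, *τ*<sub>E</sub>, observed total the sum of the noisy
  measures): an additive model whose closed-form population slopes
  reproduce the "sub-additive" patterns reported empirically;
- loose additivity (*A* regressed on *I*<sub>obs</sub> + *E*<sub>obs</sub>):
  slope *V*/(*V* + *τ*<sub>I</sub>² + *τ*<sub>E</sub>²) with
  *V* = Var(*I* + *E*), i.e. regression dilution below 1 under exact
  additivity.

The package is aimed at motor-learning researchers who want to check what
a slope estimate can and cannot say, simulate the relevant designs, and
benchmark their own generative models via residual diagnostics.

## What is in the box

- closed-form expected slopes (`expected_slope_subtractive()`,
  `expected_slope_independent()`, `shared_error_expected_slopes()`,
  `attenuation_expected_slope()`);
- seeded population generators returning tidy triads of
  implicit/explicit/total (`make_subtractive_triad()`,
  `make_independent_triad()`, `make_shared_error_population()`,
  `make_iso_A_scenarios()`), all enforcing `total = implicit + explicit`
  exactly;
- an OLS slope engine with t-based CIs, broom-style `tidy()`/`glance()`
  methods and CI-exclusion benchmark tests (`fit_slope()`,
  `benchmark_reject()`);
- the four experiment drivers (`run_subtractive_sweep()`,
  `run_independent_sweep()`, `run_shared_error_study()`,
  `run_loose_additivity_study()`) plus `residual_diagnostics()`;
- tidy CSV writers, `autoplot()` methods, `render_figures()`, and a CLI
  (`run_cli()`; shell script in `inst/cli/slopebench`).

## Worked example

Sweep the subtractive slope test over the correlation between total
adaptation and explicit strategy, with additivity enforced by construction
in every simulated dataset:

```r
library(slopebench)

spec_AE <- covariance_spec(mean_x = 25, mean_y = 5,
                           sd_x = 2.5, sd_y = 2.5, rho = 0)
sweep <- run_subtractive_sweep(
  spec_AE, rho_grid = c(-0.9, -0.6, -0.3, 0, 0.3, 0.6, 0.9),
  n = 25, iterations = 10000, seed = 42
)
print(sweep, width = Inf)
#> # A tibble: 7 × 7
#>     rho expected_slope mean_slope sd_slope mc_se_slope rejection_rate
#>   <dbl>          <dbl>      <dbl>    <dbl>       <dbl>          <dbl>
#> 1  -0.9           -1.9    -1.90     0.0937    0.000937         1
#> 2  -0.6           -1.6    -1.60     0.172     0.00172          0.910
#> 3  -0.3           -1.3    -1.30     0.202     0.00202          0.306
#> 4   0             -1      -1.00     0.211     0.00211          0.0503
#> 5   0.3           -0.7    -0.702    0.203     0.00203          0.310
#> 6   0.6           -0.4    -0.399    0.171     0.00171          0.914
#> 7   0.9           -0.1    -0.0996   0.0926    0.000926         1
#>   mc_se_rejection
#> ...
```

Every dataset satisfies *A* = *I* + *E* identically, yet the mean fitted
slope tracks *ρ* − 1 (compare `mean_slope` with `expected_slope`), and the
*β* = −1 benchmark is rejected at the nominal 5% rate only at *ρ* = 0
(`rejection_rate` 0.0503); at |*ρ*| = 0.6 the "additivity violation" is
declared in 91% of datasets and at |*ρ*| = 0.9 in essentially all of them.
The slope test rejects additivity even where additivity is true by
construction.

The shared-error study shows the converse — an additive coupled model
producing the empirically reported slope pattern:

```r
params <- shared_error_params(r = 30, p_i = 0.65, mu_E = 12, sigma_E = 4,
                              tau_I = 2, tau_E = 4)
study <- run_shared_error_study(params, population_n = 1000, n_sub = 25,
                                iterations = 10000, seed = 42)
glance(study)
#> # A tibble: 3 × 8
#>   relationship population_slope expected_slope boot_mean boot_se boot_q25
#>   <chr>                   <dbl>          <dbl>     <dbl>   <dbl>    <dbl>
#> 1 slope_I_on_E          -0.323         -0.325    -0.325    0.100  -0.389
#> 2 slope_E_on_A           0.989          0.984     0.987    0.149   0.890
#> 3 slope_I_on_A           0.0111         0.0164    0.0135   0.149  -0.0859
#> ...
```

The implicit–explicit slope is ≈ −0.33 (far from −1), explicit–total is
strongly positive and implicit–total near zero — the pattern read in the
literature as "sub-additive", generated here by a model in which
*A* = *I* + *E* holds for every participant. `autoplot(sweep)` and
`autoplot(study)` draw the corresponding figures.

From a shell:

```sh
Rscript inst/cli/slopebench sweep-subtractive --n 25 --iters 10000 \
    --seed 7 --out results/
Rscript inst/cli/slopebench shared-error --pop-n 1000 --n-sub 25 \
    --iters 10000 --out results/ --plot
```

Each run writes a tidy CSV, a fully resolved `*_config.json` sidecar (a
later `--config results/<experiment>_config.json` reproduces the run
byte-for-byte), and optional PNG figures.

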