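# cigame

Cooperation through public goods is fragile: when individuals can benefit
from the contributions of others without paying the cost themselves, groups
risk the tragedy of the commons. Social amoebae (*Dictyostelium discoideum*)
face exactly this dilemma every time genetically distinct strains aggregate
into a chimeric fruiting body, where a fraction of cells dies to build the
stalk (the public good) so the rest can disperse as spores.

`cigame` is an R package for scientists analysing this system (and
public-goods cooperation in microbial groups more broadly). It implements:

* **The Collective Investment game.** Each genotype invests a fraction
  `x ∈ [0, 1]` of its cells into stalk; with relatedness-to-group `r` equal
  to its frequency, fitness is multiplicative,
  `ω = (1 + r b x)(1 − c x)`, giving the optimal investment
  `x̂(r) = max{(1/c − 1/(b r))/2, 0}` — zero below the Hamilton threshold
  `r < c/b`, rising to the group optimum `θ = (b − c)/(2 b c)` at clonality.
* **Imperfect information.** Cells act on perceived relatedness, Gaussian
  around the truth with SD `e·4^t [r(1−r)]^t`, integrated by quadrature over
  a truncated, renormalised Gaussian.
* **By-product enforcement via transdifferentiation.** A negative feedback
  of strength `D` pushes realised allocations towards the optimum:
  `x_i = A_i + D(θ − A_G)`, with the enforcement-aware inherent allocation
  in closed form.
* **Spore-count scale.** Conversion between measured spore totals and
  inferred stalk investment (`E_G = Σ r_i T_i`, `S_G = E_G/T_G`,
  `I_G = 1 − (1−θ)/S_G`) and the reverse map for model predictions.
* **Fitting.** Exhaustive, vectorised grid search over `(b, c, e, t)`, a
  one-dimensional `D` search, parametric-bootstrap confidence intervals,
  nested-model F tests, and goodness-of-fit summaries.
* **smFISH cell-fate classification.** Censoring, per-replicate
  normalisation, the pspA index `pspA_norm/(ecmA + pspA_norm)` with
  prestalk/transdifferentiated/prespore calls, and the χ² contrasts.
* **Group statistics.** Fruiting-body collapse regressions, the
  collapse–investment correlation, pair-frequency bias adjustment, and the
  enforced-minimal-df comparison of two-strain versus twenty-strain groups.
* **A synthetic-data generator** reproducing the assay structure (transect
  and equal-frequency designs, log-normal spore noise, negative-binomial
  smFISH counts, logistic collapse), so every stage of the pipeline is
  testable without laboratory data.

All user-facing functions take data frames first and return tibbles, so the
pipeline composes with the pipe; fitted objects support `tidy()`,
`glance()` and `autoplot()`.

## Worked example

Simulate a three-strain transect assay under the study conditions, infer
investment from spore counts, fit the game, and then estimate the
enforcement pressure from equal-frequency N-strain groups:

```r
library(cigame)
library(dplyr)

p <- game_params(b = 12, c = 1)
theta(p)
#> [1] 0.4583333

design <- design_three_strain()                       # 60 compositions
sim <- simulate_assay(design, simulation_spec(D = 0, map = "linear", seed = 1))
obs <- sim |>
  estimate_investment(theta = theta(p)) |>
  summarize_investment()

fit <- design |>
  left_join(obs[, c("strain_set_id", "s_mean", "s_se")], by = "strain_set_id") |>
  fit_investment_game(fit_config(b_grid = seq(3, 12.5, by = 0.5)))
fit
#> Collective Investment game fit (grid search, 60 compositions)
#>   b = 12, c = 1, e = 0.2, t = 0.55  (theta = 0.4583)
#>   RSS = 0.00182414 on the linear empirical scale
glance(fit)
#> # A tibble: 1 × 6
#>       rss r_squared pearson_r     n map    n_ties
#>     <dbl>     <dbl>     <dbl> <int> <chr>   <int>
#> 1 0.00182     0.929     0.964    60 linear      1

tidy(bootstrap_ci(fit, seed = 2))
#> # A tibble: 4 × 4
#>   parameter estimate   lower upper
#>   <chr>        <dbl>   <dbl> <dbl>
#> 1 b            12    10.5    12.5
#> 2 c             1     1       1.35
#> 3 e             0.2   0.15    0.35
#> 4 t             0.55  0.0500  1
```

The generating parameters (b = 12, c = 1, e = 0.2) are recovered on the
grid; `t` lands one grid step from its generating value 0.5, and the
bootstrap intervals show which parameters the design pins down tightly
(`b`, `c`) and which it leaves diffuse (`t`). `theta = 0.458` is the
inferred group-optimal stalk fraction — about 46% of cells.

Equal-frequency groups of 4–20 strains probe low relatedness, where the
game without enforcement predicts collapse to zero investment:

```r
dn <- design_nstrain()                                # N = 4..10, 15, 20
simN <- simulate_assay(dn, simulation_spec(D = 0.15, n_rep = 22,
                                           map = "linear", seed = 72))
obsN <- summarize_investment(estimate_investment(simN, theta(p)))
dataN <- dn |>
  select(strain_set_id, strain_id, frequency) |>
  left_join(obsN[, c("strain_set_id", "s_mean", "s_se")], by = "strain_set_id")

fitD <- fit_transdifferentiation(dataN, fit, fit_config())
fitD
#> Transdifferentiation fit (D search, 9 compositions)
#>   D = 0.18 with fixed b = 12, c = 1, e = 0.2, t = 0.55
#>   RSS = 0.000168651 on the linear empirical scale

no_d <- fit_transdifferentiation(dataN, fit, fit_config(D_grid = 0))
c(without_D = glance(no_d)$r_squared, with_D = glance(fitD)$r_squared)
#> without_D     with_D
#>     0.849      0.992
```

Freeing `D` lifts the variance explained from 0.85 to 0.99: the plateau of
investment at low relatedness is the enforcement floor `D·θ`, not zero. The
recovered `D = 0.18` sits three grid steps from the generating 0.15,
reflecting the one-step error in the fixed `t`.

The smFISH side works from per-cell dot counts:

```r
cells <- simulate_smfish(n_cells = c(clonal = 365, chimeric = 327), seed = 75)
cl <- classify_cells(cells)          # censor, normalise, index, call fates
compare_conditions(cl, "transdifferentiated")
plot_pspa_index(cl)
```

## Package layout

| file | contents |
|---|---|
| `R/game-params.R`, `R/game-core.R` | game parameters, optima, fitness, error quadrature, enforcement |
| `R/empirical-scale.R` | spore-count ↔ investment conversions |
| `R/fit*.R` | grid search, D search, bootstrap, F test, goodness of fit |
| `R/smfish.R` | censoring, normalisation, pspA index, χ² contrasts |
| `R/group-stats.R` | collapse statistics, frequency adjustment, two-vs-twenty |
| `R/synthetic.R` | designs and simulators |
| `R/io.R` | CSV readers/writers with validation |
| `vignettes/collective-investment.Rmd` | the methods vignette |
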