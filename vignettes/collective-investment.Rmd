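---
title: "The Collective Investment game: models, fitting and cell-fate classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Collective Investment game: models, fitting and cell-fate classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cigame)
library(dplyr)
```

# The model

Social amoebae such as *Dictyostelium discoideum* aggregate into chimeric
fruiting bodies in which a fraction of cells dies to build a stalk (a public
good) while the rest become dispersing spores. `cigame` models the underlying
cooperative dilemma as a *Collective Investment game*: each genotype
("player") in a group invests a fraction $x_i \in [0, 1]$ of its cell budget
into stalk. Because all strains in a group are assumed pairwise unrelated, a
player's relatedness to the group, $r_i$, equals its frequency. Investment
costs the player $c$ per unit directly, and benefits the whole group at rate
$b$ diluted by the player's own share, giving multiplicative fitness

$$\omega_i = \underbrace{(1 + r_i\, b\, x_i)}_{\text{group benefit}}
             \underbrace{(1 - c\, x_i)}_{\text{personal cost}}.$$

Maximising $\omega_i$ gives the perfect-information optimum

$$\hat x_i(r_i) = \max\!\left\{\tfrac12\left(\tfrac1c - \tfrac1{b\,r_i}\right),\, 0\right\},$$

which vanishes once $r_i < c/b$ (Hamilton's rule) and rises to the
group-optimal level $\theta = (b - c)/(2bc)$ at clonality. Collective
investment is the frequency-weighted sum $x_G = \sum_i r_i \hat x_i$.

```{r theta}
p <- game_params(b = 12, c = 1)
theta(p)
optimal_investment(c(0.05, 0.2, 0.5, 1), p)
```

## Imperfect information

Cells cannot measure their relatedness exactly. Each cell acts on a
*perceived* relatedness drawn from a Gaussian centred on the truth with

$$\mathrm{sd}(r) = e \cdot 4^t\,[r(1 - r)]^t,$$

so `e` is the noise at $r = 0.5$ for every `t`, and `t > 0` concentrates
noise at intermediate relatedness where group composition is hardest to
assess. The expected investment is the strategy averaged over this
distribution. Two numerical decisions matter here:

* **Support.** Relatedness only exists on $[0, 1]$, so the Gaussian is
  truncated to $[0, 1]$ and renormalised. A reflected variant
  (`tails = "reflect"`) is provided for sensitivity analysis; the default is
  truncation because renormalisation keeps the mean interpretation ("correct
  on average") closest for interior $r$.
* **Quadrature.** The integral is computed on a fixed 2001-point trapezoid
  grid. The strategy is piecewise smooth with a single kink at $r = c/b$, for
  which this density keeps quadrature error far below the Monte-Carlo
  resolution used to validate it (the test suite checks 20 random
  configurations against $10^6$-draw truncated-Gaussian Monte-Carlo
  estimates, requiring agreement within three Monte-Carlo standard errors).
  `sd < 1e-12` short-circuits to the exact strategy value.

The error-model exponent is written `t` throughout; a single parameter
controls the frequency dependence of noise everywhere it appears.

## Transdifferentiation as by-product enforcement

*D. discoideum* development buffers stalk:spore proportioning: prespore
cells produce (and prestalk cells degrade) stalk-inducing factors, so a
group whose initial prestalk allocation $A_G$ falls below the optimum
$\theta$ pushes some prespore cells to transdifferentiate. The package
models this as a pressure $D(\theta - A_G)$ applied to every strain:

$$x_i = A_i + D(\theta - A_G), \qquad A_G = \sum_i r_i A_i,$$

with realised investments clipped to $[0, 1]$ (clipping never triggers at
the default parameters; a test asserts the enforcement floor
$x_G \ge D\theta$). Selection shapes the *inherent* allocation $A_i$
anticipating enforcement. Under the many-strain assumption (non-focal
strains allocate nothing, so the expected group allocation is $r_i A_i$),
the optimal inherent allocation is

$$\hat A_i(r_i) = \max\!\left\{\tfrac12\left(\tfrac{1 - D}{c(1 - D r_i)} -
\tfrac1{b r_i}\right),\, 0\right\},$$

which reduces to $\hat x_i$ at $D = 0$ and equals $\theta$ at $r_i = 1$ for
any valid $D$. Algebraically, $\hat A_i$ is exactly the perfect-information
optimum backed out through the enforcement map, and the test suite verifies
both closed forms against brute-force fitness maximisation (dense grid plus
an exact parabolic refinement — the fitness is quadratic in the investment)
on 1,000 random parameter draws. The two-strain variant of the inherent
allocation has no closed form here and is deliberately out of scope; actual
predictions for arbitrary compositions always use the realised-investment
map on the actual group allocation, via `predict_collective()`.

```{r enforcement}
pD <- game_params(12, 1, D = 0.15)
twenty <- tibble::tibble(strain_id = sprintf("s%02d", 1:20),
                         frequency = rep(0.05, 20))
# all strains below the allocation threshold: the enforcement floor D * theta
predict_collective(twenty, pD, with_transdiff = TRUE)
```

# From spore counts to investment

Stalk cells die, so stalk investment is inferred from spores. For a chimera
with measured total $T_G$ and per-strain clonal totals $T_i$:

$$E_G = \sum_i r_i T_i, \qquad S_G = E_G / T_G, \qquad
I_G = 1 - \frac{1 - \theta}{S_G}.$$

$S_G = 1$ is read as investment at the optimum $\theta$; $S_G = 1 - \theta$
is the zero-investment limit. Negative inferred investments
($S_G < 1 - \theta$) are *reported with a warning rather than clipped*:
they flag noise or misfit, and clipping would bias least squares.

Model predictions are mapped onto the same scale. Writing the predicted
collective investment as a proportion of the optimum, $y = x_G/\theta$, the
default map is linear,

$$X_G = 1 - \theta(1 - y),$$

while the exact algebraic inverse of the investment scale is hyperbolic,
$X_G = (1-\theta)/(1 - y\theta)$. The two agree at both endpoints but differ
by up to $\approx 0.07$ mid-scale at $\theta \approx 0.46$. The linear map
is the default for fitting (matching the analysis convention this package
follows); the exact map is available everywhere via `map = "exact"`, and the
synthetic generator exposes the same choice. Self-consistency matters: exact
parameter recovery (zero residual at the generating grid point) is only
defined when generator and fitter use the same map, and the recovery tests
pair them accordingly.

# Fitting

`fit_investment_game()` minimises the unweighted sum of squared differences
between per-composition mean $S_G$ and predictions over an exhaustive grid
of $(b, c, e, t)$, 20 values per parameter by default, spanning
$b \in [2, 15]$, $c \in [1, 2)$, $e \in [0, 1)$, $t \in (0, 1]$. A
two-stage refinement is the intended workflow: search the default coarse
grid, then refit on a finer grid bracketing the optimum (the examples use
`seq(3, 12.5, by = 0.5)` for $b$, which carries integer benefit values and a
0.5 resolution). Grid bounds are fully configurable through
`fit_config()`. Ties are broken deterministically towards the smallest
$(b, c, e, t)$ and all tied grid points are reported.

The search is vectorised: strategy curves are evaluated once per $(b, c)$ on
the quadrature grid, perception-error weights once per $(e, t)$ at the
unique relatedness values appearing in the data, and the full
$20^4$-combination prediction matrix assembles from matrix products (about
three seconds on one CPU for a 60-composition design). Because predictions
do not depend on the observations, the matrix is cached in the fit object
and every bootstrap refit is an exact re-minimisation at negligible cost.

`fit_transdifferentiation()` then searches $D$ on $[0, 0.25]$ in steps of
0.01, holding $(b, c, e, t)$ fixed at the earlier fit — freeing only $D$
keeps the three-strain fit intact while the equal-frequency group data
identify the enforcement strength.

## Uncertainty and model comparison

* `bootstrap_ci()` resamples each composition mean from a Gaussian with its
  standard error — the sampling distribution of the mean — refits, and
  summarises each parameter by the 5th–95th percentile range of deviations
  from the point estimate (100 iterations by default). A nonparametric
  variant resamples replicate-level estimates within compositions
  (`method = "resample"`). The conservative prediction band evaluates all
  corner combinations of the parameter bounds and keeps the envelope,
  reporting the corner that deviates most from the point predictions.
* `model_compare_F()` compares the perfect-information fit ($e = 0$) with
  the full fit. The restriction removes both `e` and `t` (a model without
  noise has no use for its frequency dependence), so $\Delta p = 2$ by
  default; the value is configurable for the stricter reading that only `e`
  is dropped.
* `goodness_of_fit()` reports $R^2 = 1 - \mathrm{RSS}/\mathrm{TSS}$, the
  Pearson correlation between predictions and observations, and a paired
  $t$ test of the pairs.

# smFISH cell-fate classification

`classify_cells()` runs censoring, normalisation and classification on
per-cell transcript (dot) counts of the prestalk marker *ecmA* and prespore
marker *pspA*:

1. **Censoring** removes cells with fewer than 17 dots. The package reads
   this as *both genes below 17*: a committed prespore cell legitimately has
   near-zero *ecmA*, so requiring both genes to clear the threshold would
   censor most committed cells; what the rule must remove is cells with too
   little total signal for an unambiguous call. The strict variant
   (`rule = "either_below"`) is provided.
2. **Normalisation** multiplies *pspA* counts by the ratio of *ecmA* to
   *pspA* means over retained cells, independently per replicate (absorbing
   hybridisation-efficiency differences), so both genes share a mean.
   Censoring precedes normalisation.
3. **Classification** uses the index
   $\mathrm{pspA}^{norm}/(\mathrm{ecmA} + \mathrm{pspA}^{norm})$: $\le 0.3$
   prestalk, $\ge 0.7$ prespore (boundaries inclusive), in between the mixed
   signature of transdifferentiation.

Condition contrasts use Pearson $\chi^2$ on the 2×2 table (category vs not,
by clonal vs chimeric) with one degree of freedom and *no continuity
correction* — cell counts in this assay are in the hundreds, where the
correction only distorts; a `correct` flag restores it.
`replicate_homogeneity()` tests the replicate-by-fate table (2 df for two
replicates and three categories).

# Group-level statistics

* `collapse_regression()` reports the simple OLS of the collapsed proportion
  on relatedness — the headline $F(1, n-2)$ — alongside a
  maximum-likelihood mixed model with a strain-combination random intercept.
  `collapse_trend_cubic()` is the cubic-relatedness visual aid.
* `compare_two_vs_twenty()` fits an ML mixed model of low-frequency
  investment on group type with a replicate-group random intercept, and
  *enforces the minimal degrees of freedom* (number of replicate groups
  minus one) on the two-sided $t$ test, overriding the model's default df —
  with four replicate groups this gives $t_3$.
* `adjust_pair_frequencies()` converts nominal pair frequencies to
  effective ones using the focal strain's observed share $s$ in 50:50
  control mixes. The default is odds scaling,
  $f' = f\beta/(f\beta + 1 - f)$ with $\beta = s/(1-s)$, which preserves
  the pair sum and is the natural model of a multiplicative representation
  bias; a linear variant is provided for sensitivity analysis.

# The synthetic-data generator

The generator produces assay-shaped data so the entire pipeline is testable
end to end. Its defaults are the study conditions the package targets:

| quantity | default | rationale |
|---|---|---|
| $b$, $c$ | 12, 1 | best-fit benefit/cost; $\theta = 0.458$ |
| $D$ | 0.15 | best-fit enforcement pressure |
| $e$, $t$ | 0.2, 0.5 | moderate perception noise, intermediate frequency dependence (not independently pinned by the fit outputs; both sit on the refined grids) |
| clonal totals | $10^6$, CV 0.3 | hemocytometer-scale totals; strains differ substantially |
| measurement noise | CV 0.03 on $S_G$ | counting-dominated error for $\sim 10^3$ spores counted per sample; consistent with the precision at which composition means resolve $D$ to $\pm 0.01$–$0.02$ |
| replicates | 21 (three-strain), 22 ($N$-strain) | study replication |
| transect splits | $k/11$, $k = 1..10$ | yields 60 unique labelled compositions per triplet with no collision with the 0.2/0.8 focal levels; configurable, and the readers accept arbitrary composition tables |
| smFISH counts | NB, majors 120, minors 4, transdiff 60, size 40 | committed cells show essentially no marker overlap; moderate technical overdispersion |
| collapse link | $p = \mathrm{logit}^{-1}(1 - 4y)$ | $\approx 5\%$ collapse at optimal investment, $\approx 60\%$ at the enforcement plateau |

Noise enters multiplicatively (log-normal) *on the relative-production
scale*, so replicate means of $S_G$ are unbiased for the generating value —
noise applied to $T_G$ directly would bias every downstream ratio by
$1 + \mathrm{CV}^2$. Per-strain variation in clonal investment level is
available (`strain_theta_sd`) but off by default.

What the generator does **not** emulate: allorecognition-driven
segregation, spatial slug structure, biological replicate variance beyond
counting noise, developmental-timing differences, and strain-specific
responses to particular partners. Passing tests therefore demonstrate that
the estimators and fitters recover the truth under the stated statistical
structure — not that real assay data satisfy that structure.

# Numerical choices and degenerate inputs

* Relatedness $r = 0$ is handled as a limit ($\hat x = 0$); divisions are
  guarded.
* $D r \ge 1$ is rejected (infeasible allocation).
* Realised investments are clipped to $[0, 1]$; fractions of cells cannot
  leave the unit interval.
* Zero-variance observations make $R^2$ undefined and raise an error rather
  than returning `NaN`; a perfect full-model fit makes the nested $F$
  infinite and is flagged.
* All generators and the bootstrap are pure functions of their seed.

Problem sizes exercised by the test suite: the full $20^4$ grid on 60
compositions, 50-seed enforcement-recovery simulations at study-scale
replication, $10^6$-draw Monte-Carlo quadrature checks, a 500-permutation
null for the collapse regression, and $10^4$-cell classification
recoveries.

# Known limitations

* The grid search returns grid points; off-grid optima require refinement,
  and the reported bootstrap intervals inherit the grid resolution.
* The linear empirical map and the hyperbolic investment scale are mutually
  inconsistent mid-scale (kept deliberately, with the exact map behind a
  flag).
* The mixed models report ML fixed effects with enforced or asymptotic df;
  no Satterthwaite/Kenward-Roger approximation is attempted.
* The two-strain inherent-allocation optimum under enforcement is only
  available through numeric maximisation, not in closed form.
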