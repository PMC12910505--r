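---
title: "Modelling temperature-stress effects on tomato reproduction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling temperature-stress effects on tomato reproduction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermofruit)
```

## The problem

Short episodes of heat or cold around flowering are a major driver of yield
loss in fruiting crops, yet most crop growth models treat yield through
carbon balance and ignore reproduction. In tomato, temperature acts on a
chain of reproductive processes: how many pollen grains a flower produces,
what fraction of them is viable, what fraction of the viable grains
germinates, how many ovules are fertilised into seeds, and how large the
fruit grows — fruit growth being stimulated by the developing seeds through
auxin and gibberellin signalling. `thermofruit` implements this chain as a
deterministic five-stage cascade driven by two inputs only: the stress
temperature $T$ (°C) and its duration $D$ (days), with $D = 0$ denoting the
unstressed control grown at the optimum.

## The model

**Pollen number.** Pollen per flower follows a skewed (beta-function)
temperature response

$$N_{\mathrm{pollen}}(T) \;=\; e^{\mu}\,
  \Big(\frac{T - T_b}{T_0}\Big)^{\alpha}
  \Big(\frac{T_c - T}{T_0}\Big)^{\beta},
  \qquad T_b < T < T_c,$$

and 0 outside $(T_b, T_c)$, including at the boundaries — defining the
function as zero there avoids raising negative bases to real powers. The
exponents are not free: they are pinned by the requirement that the curve
peaks at the optimum $T_{opt}$ with the measured peak value $N^{*}$. With
$\delta_1 = (T_{opt}-T_b)/T_0$, $\delta_2 = (T_c-T_{opt})/T_0$ and
$\delta_3 = \delta_1/\delta_2$,

$$\beta = \frac{\log N^{*} - \mu}{\delta_3 \log \delta_1 + \log \delta_2},
  \qquad \alpha = \beta\,\delta_3 .$$

This leaves $\mu$ as the single free parameter of the stage. The skew
matters biologically: the fitted curve declines faster on the cold side of
the optimum than on the warm side (a 4 °C drop costs about as much pollen
as a 12 °C rise). `derive_beta_shape()` errors explicitly when
$\delta_3\log\delta_1 + \log\delta_2 = 0$, where no exponent pair can
satisfy the peak constraint.

**Viability and germination fractions.** Each fraction follows a quadratic
surface in scaled temperature $u = T/T_{opt}$, anchored away from the
optimum by a duration-interpolation level $p(D) = \theta_1 + \theta_2 D^2$:

$$f(T, D) \;=\; \mathrm{clamp}_{[0,1]}\!\big[\,p(D)\,(1 - w) +
  \alpha_{\max}\, w\,\big], \qquad w = 2u - u^2 .$$

The quadratic's vertex sits at $u = 1$, so the surface returns the control
fraction $\alpha_{\max}$ at the optimum for *every* duration. The latent
level $p(D)$ is allowed to go negative (the default viability calibration
reaches $-0.98$ at four days) — only the surface itself is clamped. The
lower clamp at 0 is part of the model definition; the upper clamp at 1 is a
package design choice: it cannot trigger with the default parameters
($\alpha_{\max} < 1$), but it guarantees that no user-supplied parameter
set can produce a fraction above 1 and break the cascade ordering. The
$p(1-w) + \alpha w$ arrangement is algebraically identical to
$p + (\alpha - p)w$ but returns $\alpha_{\max}$ *bit-exactly* at the
optimum, which the tests rely on.

**Counts and links.** Viable pollen is the viability fraction times the
pollen number; germinated pollen is the germination fraction times the
viable count, so $0 \le N_{germ} \le N_{viable} \le N_{pollen}$ always.
Seed number per fruit and individual fruit mass are linear links,

$$N_{seeds} = m_1 N_{germ}\, c_{flower \to fruit} + b_1, \qquad
  M_{fruit} = m_2 N_{seeds} + b_2,$$

with $c_{flower \to fruit} = 1$ by default (each flower assumed to set one
fruit; abortion is handled separately through the fruit-set fraction). The
intercepts are biological baselines — seeds in a fruit with no germinated
pollen, mass of a seedless (parthenocarpic) fruit — so with the default
non-negative links the predicted fruit mass is floored at
$m_2 b_1 + b_2 \approx 2.23$ g. `predict_fruit_mass()` is definitionally
the composition of the stage functions and agrees with the step-by-step
chain bit for bit.

**Measurement conversion.** Haemocytometer counts convert to pollen per
flower as $N = \mathrm{count} / vol_{chamber} \times vol_{sample}$ with a
0.2 mm³ chamber and a 200 µl suspension (1 µl = 1 mm³): one counted grain
is 1000 grains per flower.

**Truss yield.** Yield per truss is
$n_{flowers} \times f_{set}(T) \times M_{fruit}(T, D)$, separating the two
routes to yield loss: smaller fruits (heat and cold, via seeds) versus
fewer fruits (mainly cold, via fruit set). The fruit-set quadratic
$f_{set}(T)$ ships **without** default coefficients — no fitted
coefficients are published for it — and `truss_yield()` raises an explicit
error rather than silently assuming full fruit set. A synthetic example
configuration passing through plausible point values (0.70 at 14 °C, 0.90
at 30 °C) is installed as
`extdata/fruit_set_synthetic_example.json`.

## Default parameters

The defaults (also shipped as `extdata/default_params.json`) are the
published calibration for an indeterminate round tomato cultivar:

```{r}
thermofruit_params()
```

$T_0 = 1$ °C is kept as an explicit constant rather than hard-coded,
preserving the dimensionless-difference construction. The fruit-mass unit
is carried as a metadata label (`mass_unit = "g"`), not converted: the
calibration's parameter table labels fruit mass as dry matter while its
results discuss fresh mass, and the package does not adjudicate that.
Predictions outside the calibrated envelope ($T \in [14, 34]$ °C,
$D \in [0, 8]$ d) are accepted but flagged with an extrapolation warning.

A documented quirk: composing the rounded default parameters does **not**
regenerate the narrative scenario values sometimes quoted for this model
(≈2.9 g at 30 °C/4 d). At that regime the germination surface clamps to 0,
so the chain bottoms out at the intercept cascade:

```{r}
predict_cascade(c(18, 30, 14), c(0, 4, 4))
```

The package treats this as a property of the rounded parameter set and
asserts it in the test suite rather than patching it.

## Estimation

`thermofruit()` fits the cascade to a tidy observation table the way the
calibration itself was performed: **per function, sequentially and
independently**, by least squares on treatment means. Joint optimization
would redistribute error across stages and change how errors propagate
through the cascade, so it is deliberately avoided.

* Observations are pooled to treatment means before fitting (blocks,
  plants, and trusses are replication, not model terms), which also makes
  every fit invariant to row order and labelling. Pollen counts are
  additionally pooled across durations, since pollen number depends on
  temperature only.
* Measured quantities are held fixed: $N^{*}$ is the observed control mean
  (overridable), and each surface's $\alpha_{\max}$ is the observed control
  fraction.
* The 1-D $\mu$ fit uses a deterministic 61-point grid over $[0, 15]$ to
  locate the basin, then golden-section refinement (`optimize`, tolerance
  $10^{-10}$). A property test checks agreement with an exhaustive
  0.001-step grid search.
* Each $(\theta_1, \theta_2)$ surface fit uses Nelder–Mead from five fixed
  starting points spread over plausible values (relative tolerance
  $10^{-14}$), keeping the best run. Residuals are computed on the
  *clamped* surface: clamped regions contribute flat-gradient residuals
  with no special-casing, matching the surface definition. Degenerate
  designs (fewer than three temperatures; all observations at the optimum;
  fewer than two durations off-optimum) raise explicit errors.
* The linear links use ordinary least squares (`lm`). A constant response
  is handled by convention: slope 0, intercept at the mean, $R^2 = 0$.
* $R^2$ is $1 - SS_{res}/SS_{tot}$ about the observed mean for every
  stage, including the nonlinear ones; negative values are allowed and
  meaningful.

The whole-model summary error is the per-function RMSE over the ten
treatment means, aggregated as the unweighted mean of the five
root-mean-squares. The five functions are measured in different units, so
the aggregate is a unit-incoherent convention: `aggregate_rmse()` warns
about this, and the per-function values are always reported alongside.
(The alternative reading — root of the pooled mean square — was rejected
as even less coherent across units.)

## The synthetic experiment generator

`simulate_experiment()` emulates the calibration experiment's structure:
ten treatments (18 °C control; 14 °C for 4, 6, 8 d; 30 and 34 °C for 1, 3,
4 d), three blocks (repetitions over time), pollen traits on four plants
per block and fruit traits on six, trusses 1–3, nine flowers per truss.
The generative chain per plant × truss is:

1. grains in the counted chamber volume drawn around the volume-scaled
   expectation (Poisson by default; a negative-binomial switch with a
   variance-to-mean dial is exposed because the true overdispersion of
   chamber counts is not knowable from summary data);
2. viable grains binomial on the grains actually counted — the measured
   fraction really is a ratio of counted grains, so its sampling error
   shrinks with the count;
3. germinated grains binomial on 150 scored grains per assay (assay totals
   are unpublished; 150 is a plausible per-aliquot total,
   configuration-exposed);
4. seeds Poisson around the seed-link mean;
5. fruit mass Gaussian around the mass-link mean *given the drawn seed
   count*, truncated at zero, with a 0.9 g residual scale — a calibration
   choice placing individual-fruit scatter on the order of the published
   whole-model error, not itself a published value;
6. optional multiplicative log-normal block effect on pollen production
   (default 0, matching the model's indifference to blocks).

Setting every noise component to zero (`zero_noise()`) reproduces the
deterministic cascade exactly — the generator's central invariant, and the
reason count integrality is *not* enforced by `validate_observations()`
(noise-free tables carry expected, generally non-integer, counts).

What the generator does **not** emulate: flower developmental timing and
stage-dependent sensitivity windows, within-truss position effects,
microclimate offsets between air and tissue temperature, and any
correlation between a plant's pollen and fruit measurements (the real
protocol measured them on different plants, which the generator mirrors by
construction). Passing recovery tests therefore demonstrate that the
estimation machinery is consistent and well-identified under the declared
design and noise — not that the noise model is the field's truth.

`recovery_study()` wraps the generate-and-refit loop and reports, per
estimated parameter, the median absolute relative error and the fraction
of runs within a tolerance (default 10%). Failed fits are counted, not
fatal. With the default design and noise, 100 replicates put the median
relative error near 3% for $\mu$ and 1–2% for the four $\theta$s; the link
intercepts are the noisiest recoveries because they extrapolate the
regression to zero germinated pollen.

## Problem sizes and reproducibility

The test suite runs the full property grid at 50 × 20 regimes, the
Monte-Carlo convergence check at 30 replicates, and the recovery study at
100 replicates of the complete 10 × 3 design — sizes chosen so the whole
suite completes in well under a minute while keeping Monte-Carlo standard
errors far below the tolerances being asserted. All simulation entry
points take an explicit integer seed and are bit-reproducible under it.
`scripts/acceptance.R` recomputes the headline calibration quantities
(shape exponents; both control fractions across all design durations) from
the installed package.

## Known limitations

* The cascade is calibrated for one cultivar and one stress-timing window
  (stress applied just before first anthesis); stage-dependent sensitivity
  is real but outside the model.
* Fruit set enters only through the user-supplied quadratic; the package
  ships no coefficients for it.
* The model carries no uncertainty quantification beyond Monte-Carlo
  recovery — the calibration publishes no standard errors, and the package
  does not invent them.
* Aggregate RMSE mixes units by construction; compare per-function values
  across studies instead.
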