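---
title: "Modeling migratory pacing with a dynamic-persistence correlated random walk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling migratory pacing with a dynamic-persistence correlated random walk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(movepersist)
```

## The model

`movepersist` treats an autumn migration track as a correlated random
walk whose *persistence* changes continuously in response to the
environment the animal is experiencing. For individual $j$ at fix $i$
(planar location $\mathbf{x}_{j,i}$, time gap
$\Delta t_{j,i} = t_{j,i} - t_{j,i-1}$ in hours):

$$
\mathbf{x}_{j,i} \sim \mathcal{N}\!\left(
  \mathbf{x}_{j,i-1} +
  \gamma_{j,i}\,\frac{\Delta t_{j,i}}{\Delta t_{j,i-1}}
  \left(\mathbf{x}_{j,i-1} - \mathbf{x}_{j,i-2}\right),\;
  \Delta t_{j,i}\,\sigma_x^2\,\mathbf{I}\right)
$$

The latent persistence $\gamma_{j,i} \in (0,1)$ measures how strongly
the previous displacement is continued: values near 1 describe
directional, migratory movement, values near 0 tortuous, encamped
movement. Its logit follows a linear regression on contemporaneous,
standardized environmental covariates:

$$
\mathrm{logit}(\gamma_{j,i}) \sim \mathcal{N}\!\left(
  \mathbf{Z}_{j,i}^\top \boldsymbol\beta_j,\;
  \Delta t_{j,i}^2\,\sigma_\nu^2\right),
\qquad
\mathbf{Z}^\top\boldsymbol\beta =
\beta_0 + \beta_1\,\mathrm{Temp} + \beta_2\,\mathrm{Snow}
+ \beta_3\,\mathrm{Temp}\cdot\mathrm{Snow}
+ \beta_4\,\mathrm{Wind} + \beta_5\,\mathrm{NDVI}
+ \beta_6\,\mathrm{Pressure}.
$$

Individual coefficients are tied together by an annual population
hierarchy, $\beta_{j,k} \sim \mathcal{N}(\beta_{p,k},
\sigma_{\beta,k}^2)$, so that population-level effects $\beta_{p,k}$
summarize which cues drive migratory pacing in a given year.

Units are explicit throughout: coordinates in km, time gaps in hours,
so $\sigma_x$ is km per $\sqrt{\text{hour}}$ and $\sigma_\nu$ is logit
units per hour (the latent sd at an 8-h cadence is $8\sigma_\nu$).

## Two-stage inference

Stage 1 fits each individual-season independently. The sampler is an
adaptive Metropolis-within-Gibbs scheme implemented in compiled code:

* $\boldsymbol\beta \mid \boldsymbol\eta$ is conjugate (weighted normal
  regression of the latent series on $\mathbf{Z}$) and drawn exactly;
* each latent $\eta_i = \mathrm{logit}(\gamma_i)$ gets a random-walk
  update and an independence update drawn from its latent prior
  conditional (whose acceptance depends only on the movement
  likelihood);
* $\log\sigma_x$ and $\log\sigma_\nu$ get adaptive random-walk updates;
* two non-local moves handle the posterior's slow directions: a joint
  $(\sigma_\nu, \boldsymbol\eta)$ rescaling, and *ridge translations*
  that shift $\beta_k$ and the whole latent series together so latent
  residuals are unchanged and only the movement likelihood and the
  $\beta$ prior arbitrate.

All proposal scales adapt toward 0.44 acceptance during burn-in and are
frozen afterwards, so the post-burn-in kernel is a fixed, valid MH
kernel. Convergence is reported as rank-normalized split-$\hat R$ per
parameter with the conventional 1.01 bound.

The ridge moves deserve a note. When per-step information about
$\gamma_i$ is modest, the posterior contains long, gently curved ridges
along which a coefficient and the latent series trade off almost
freely. Ordinary single-site samplers (ours, and equivalently a JAGS
implementation of the same model, which we used as an independent
cross-check during development) mix very slowly along these directions;
the translation moves walk them directly.

Stage 2 scales inference to the population with recursive Bayesian
computation: a second MCMC whose proposals for each $\beta_{j,k}$ are
uniform draws from that individual's stage-1 posterior pool, accepted
with the ratio
$\frac{N(\beta^\ast\mid\beta_{p,k},\sigma_{\beta,k})/g_0(\beta^\ast)}
      {N(\beta_{j,k}\mid\beta_{p,k},\sigma_{\beta,k})/g_0(\beta_{j,k})}$,
where $g_0$ is the stage-1 prior: the stage-1 likelihood cancels
because the proposal *is* the stage-1 posterior. $\beta_{p,k}$ and
$\sigma_{\beta,k}^2$ then have conjugate normal and inverse-gamma
updates. Proposals are drawn uniformly with replacement from the pool;
this is a valid MH kernel and, with the pool sizes produced by stage 1
(hundreds to thousands of draws), we saw no practical benefit from
without-replacement sweeps.

## Priors and their scales

Stage 1 uses $\beta_k \sim \mathcal N(0, 2^2)$ — wide relative to
standardized covariates — and half-Normal priors on the process scales:
scale 5 for $\sigma_x$ and scale **0.5** for $\sigma_\nu$. The
asymmetry is deliberate. $\sigma_\nu$ is multiplied by $\Delta t$, so
at an 8-h cadence a value of 0.6 already implies step-to-step jumps in
logit-persistence with sd near 5 — behavioral churn with no biological
reading. A prior that admits such values does real damage beyond
implausibility: the latent series can then chase the flat logit tails
of the per-step movement likelihood, which inflates every coefficient
multiplicatively. We verified with an independent sampler (rjags) that
this inflation is a property of the exact posterior under a diffuse
$\sigma_\nu$ prior, not a sampler artifact; the weakly-informative
scale restores well-behaved inference. The prior actually used is
serialized into every fit object, and the population stage reads $g_0$
from there, so the two stages are always self-consistent.

The population stage defaults to the informative zero-centered
hyperprior $\beta_{p,k} \sim \mathcal N(0, 1)$ (so that only
reasonably strong population effects move away from zero) and
$\sigma_{\beta,k}^2 \sim \mathrm{InvGamma}(2, 1)$; both are arguments
of `fit_population()` and results should be read with that sensitivity
in mind. Credible intervals are equal-tailed; effects are reported per
covariate-year as "90% CI excludes zero", and per covariate as
consistent when at least two years exclude zero with a common sign.

## What the synthetic data emulate

The restricted nature of real collar data motivates a first-class
generator. `sim_covariate_spec()` + `generate_covariate_fields()`
produce seasonal fields on a regular planar grid: temperature with a
linear seasonal decline (10 °C falling 0.25 °C/day) plus AR(1)
synoptic noise, snow that is exactly zero before a fixed onset day
(~day 45, late September) and then accumulates by reflected
non-negative increments to tens of cm, AR(1) wind floored at zero,
AR(1) pressure, NDVI declining logistically from a 0.8 plateau as
16-day composites, and smooth south-north gradients on every variable.
Weather is produced at 3-h cadence, matching reanalysis products.

`simulate_track()` runs the movement model forward. One approximation
is unavoidable in forward simulation: the covariates entering step $i$
are evaluated at the previous location $\mathbf{x}_{i-1}$ (at time
$t_i$), because $\mathbf{x}_{i}$ does not exist yet, whereas fitting
associates covariates with $\mathbf{x}_i$ itself. The fields are smooth
in space, so the discrepancy is far below the covariate sds (we
measured maximum design-matrix differences of order $10^{-2}$ standard
units); parameter-recovery tests pass through both code paths, which
also exercises this approximation.

Default "truth": $\boldsymbol\beta_p = (1, -1.5, -0.8, 1.5, 0.6, -1,
0.5)$, $\sigma_{\beta,k} = 0.2$, $\sigma_x = 1$ km/$\sqrt{\text h}$,
$\sigma_\nu = 0.1$ h$^{-1}$. Signs follow the established picture of
autumn migration — persistence rises as temperature falls, snow
arriving at mild temperatures triggers movement (positive interaction),
senescing NDVI releases animals from foraging, wind and pressure act
weakly and positively. The magnitudes are chosen so that a simulated
season spans the full behavioral contrast of a migratory caribou:
encamped phases with $\gamma$ near 0 and migratory runs with $\gamma$
above 0.9. That contrast is not cosmetic. Per-step information about
$\gamma_i$ scales with the length of the previous displacement relative
to the process noise, roughly $1/\sqrt{1-\gamma^2}$; a track that never
leaves the tortuous regime leaves the logit-scale coefficients close to
unidentified no matter how many fixes it has. Tracks with real
migratory runs are both what the species does and what makes the
inference work.

What the generator does **not** emulate: realistic spatial covariance
of weather fields (gradients are smooth and monotone), geography
(no mountains, coasts or corridors), fix dropout or irregular duty
cycles, and collar error. Passing recovery tests on these data
therefore demonstrate correctness of the inference machinery under the
model, not robustness to real-data pathologies.

## Track preparation choices

The analysis window is August 15 - December 31, boundaries inclusive
(with an August 15 - November 15 truncated variant as a sensitivity
switch). Subsampling to the 8-h target anchors the grid at each
individual-season's first fix and keeps the nearest fix within a 1-h
tolerance per grid slot; the operation is idempotent, and clipping and
subsampling commute except at window edges. Gaps are retained — the
model's $\Delta t$ terms absorb them — and no outlier screening is
applied. Individual-seasons are excluded for mortality, mid-season
deployment, or fewer than half of the expected fixes
(`expected_fix_count()`: 417 for the full window at 8 h), with exactly
one primary reason recorded per exclusion; mortality and deployment are
user-supplied flags, never inferred from movement.

Coordinates are projected with a spherical Albers equal-area conic
centered on the data (standard parallels by the 1/6 rule), implemented
in the package and verified against geodesic distances; the projection
parameters travel with the data so the transform is invertible.

## Covariate handling

Annotation interpolates bilinearly over the four surrounding cell
centers and linearly in time between 3-h slices; NDVI uses the value of
the containing 16-day composite. Raw NDVI is set to 0 wherever snow
depth is positive (strictly $> 0$; no trace threshold) *before*
standardization. Standardization is to mean zero, unit variance, pooled
by default across all retained individual-seasons so that individual
coefficients are commensurable within the annual population model;
per-individual scope and a user-supplied fixed scaling table are
available (the latter is how simulation and fitting share one
reference frame in the tests). The interaction column is the product of
the two standardized main effects — not a re-standardized product — so
the response-curve algebra below stays exact. A Pearson screen warns,
without aborting, when any pair of raw covariates reaches |r| = 0.7.

## Post-fit products

`predict_gamma_surface()` maps
$\hat\gamma_i = \mathrm{logit}^{-1}(\mathbf{Z}_i^\top\hat{\boldsymbol\beta}_p)$
over a landscape at one time, using the stored training means/sds and
the same NDVI-under-snow rule as training.
`temperature_response_curves()` draws the predicted
persistence-vs-temperature curve at fixed snow depths (defaults 0, 11
and 46 cm: no snow, average and deep snow), other covariates held at
their
training means, one curve per posterior draw plus the mean curve.
Because the temperature slope on the logit scale is
$\beta_1 + \beta_3\,s_{\mathrm{std}}$, it changes sign at
$s_{\mathrm{std}} = -\beta_1/\beta_3$;
`snow_inversion_depth()` back-transforms this to a depth in cm and
reports the per-draw distribution together with the fraction of draws
admitting no physical inversion ($\beta_3 \approx 0$ or depth below
zero — flagged, never an exception).

## Numerical choices and degenerate inputs

Chains initialize at $\beta = 0$ with per-chain jitter, $\eta = 0$, and
method-of-moments process scales; inputs are validated up front
(finite coordinates, increasing timestamps, positive scales), which
makes the target density finite at any reachable initialization. Fits
are pure functions of (data, config, seed). Zero-variance covariates, missing design columns, fixes outside
a stack's extent, non-increasing timestamps, and single-chain $\hat R$
requests are hard errors with the offending item named. $\gamma$ is
treated as open-interval $(0,1)$ throughout (the logit link forces
this).

Problem sizes used by the routine test-suite runs: tracks of 30-400
fixes, 2-3 chains of 400-8,000 iterations for the unit layer; the
acceptance layer uses 5 tracks of 300 fixes with 3 chains of 40,000
iterations (half burn-in, thinned by 10) for the convergence bound, 20
replicate fits at 8,000 iterations for individual-level recovery, and a
15-individual two-stage run at 6,000 iterations. `mcmc_config()`
defaults to 3 chains of 5,000 (seconds per track, for interactive
work); `paper_scale = TRUE` switches to 100,000/50,000/10 for
production runs.

## Known limitations

* The logit-scale coefficients remain weakly identified for tracks
  that never express persistent movement; posteriors are then wide and
  pulled by the priors. This is a property of the model class, not of
  the implementation (see the prior section).
* The population hierarchy is univariate per coefficient; no
  correlated random effects across coefficients.
* One model structure only: the seven-term linear predictor with the
  temperature-by-snow interaction. No model selection.
* The pipeline's simulated-data stages are the supported entry point;
  real Movebank exports will typically need their covariate stacks
  assembled by the user into `covariate_stack` objects first.
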