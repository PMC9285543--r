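---
title: "Phylogenetic prediction of muscle cross-sections and bite force: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic prediction of muscle cross-sections and bite force: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phybite)
```

## The model

`phybite` fits, per jaw-adductor muscle group, the regression of
log10 physiological cross-sectional area (A_Phys, mm²) on log10 skull
width (W_Sk, mm) with phylogenetically structured residuals:

$$ y \sim \mathrm{MVN}\!\left(\alpha + \beta x,\; \sigma^2_{BM}\, C_\lambda \right) $$

`C` is the Brownian-motion covariance implied by the time tree: entry
(i, j) is the path length in Myr from the root to the most recent common
ancestor of tips i and j, and the diagonal is the root-to-tip path
length. Fossil tips simply end above the present, so their diagonal
entries are shorter — no special handling is needed. $C_\lambda$
multiplies the off-diagonals by Pagel's λ; λ = 1 is pure Brownian
motion, λ = 0 a star phylogeny.

The assumptions a user buys into are therefore: (i) a linear allometry
on the log-log scale, (ii) Brownian residual evolution at a single rate
σ²_BM per Myr across the whole tree, and (iii) branch lengths in
consistent time units. The regression is on the log10 scale. The scale
is a deliberate choice: the expected scaling of an area against a
length is a power law (exponent 2 under isometry), which is linear only
in log space, and log10 keeps slopes readable as scaling exponents. The
synthetic-data defaults (below) use slope 2 for exactly that reason.

### Priors and the sampler

Published applications of this family of models rely on opaque default
priors in external software, so the package pins down an explicit,
reproducible choice: improper flat priors on α and β, a uniform prior
on log σ²_BM over a wide fixed range (±30 in natural log), and
uniform(0, 1) on λ when it is estimated. With these priors the
posterior mean of (α, β) coincides with the generalized-least-squares
closed form $(X' C^{-1} X)^{-1} X' C^{-1} y$ up to Monte-Carlo error,
which gives the package an exact independent oracle — the test suite
exploits this, and it is the main reason for preferring flat priors
over weakly informative ones.

Sampling is MCMC: (α, β) has an exact conditional normal and σ²_BM an
exact conditional (scaled inverse-χ²) density, so both are Gibbs steps;
λ, when estimated, uses a reflected uniform random-walk Metropolis step
(width 0.15) whose proposals trigger a fresh Cholesky factorisation.
Because the Gibbs conditionals are exact, chains mix within a few
sweeps at the sample sizes this method targets (tens of taxa), and the
default configuration — two chains, 1,000 iterations each, 500 burn-in,
no thinning, 1,000 pooled retained draws — is deliberately small. The
pooled posterior size of 1,000 matches the scale of posterior samples
used in comparable published analyses; users who estimate λ or distrust
mixing can raise `ppm_config()` to any chain length.

Reproducibility is seed-derived throughout: chain k runs under a seed
derived from the master seed and the chain index, predictions under a
"predict" tag, and each LOOCV fold under a seed derived from the master
seed and the left-out taxon's *name* — so folds give identical results
whatever their order, and reruns are byte-identical.

### Prediction at unobserved tips

For a target tip with predictor x\* and no response, every posterior
draw contributes one draw from the target's conditional normal given
the observed tips:

$$ \mu^* = \alpha + \beta x^* + c_*' C^{-1}(y - \alpha - \beta x), \qquad
   v^* = \sigma^2_{BM}\,(c_{**} - c_*' C^{-1} c_*) $$

with $c_*$ the target–observed covariance vector (λ-scaled) and
$c_{**}$ the target's diagonal entry. Two design points deserve
emphasis:

* The prediction *conditions on the observed residuals* (phylogenetic
  BLUP), not just on the regression line. This is what makes
  "phylogenetic position" informative: a target nested inside a clade
  whose members sit above the line is pulled above the line. The
  independence limit behaves correctly — with λ = 0 or no shared
  history the mean collapses to α + βx\*.
* The predictive draw includes the conditional-normal *sampling* step,
  not just the mean, so predictive intervals and p-values reflect
  predictive uncertainty rather than parameter uncertainty alone. With
  flat priors this makes the central predictive interval exactly
  calibrated on correctly specified data (a pivotal-quantity argument),
  which is what the calibration tests check.

Batch prediction of many fossils conditions each target on the observed
tips only, never on other targets, and is therefore identical to
predicting tips one at a time.

### The cross-validation score

LOOCV refits on N − 1 taxa and scores the left-out observation with a
posterior predictive p-value,

$$ p_{MCMC} = \min\!\left(1,\; 2\,\frac{\min(\#\{d \le y\},\, \#\{d \ge y\})}{\#d}\right), $$

ties counted inclusively on both sides. The two-tailed, factor-2 form
is chosen because the failure criterion is "beyond 95% of the
distribution", i.e. a central interval; a one-tailed convention is
available as a switch. Inclusive ties prevent p = 0 for degenerate
(constant) predictive distributions. A fold *passes* at
p ≥ 0.05 exactly, since failure is defined by the strict inequality
p < 0.05. No multiple-testing correction is applied across folds, by
design. A fold whose reduced covariance is singular is recorded as a
failed fold with its reason rather than aborting the whole
cross-validation.

## Tree handling

* **FAD/LAD time-scaling.** The input tree's node depths are read as
  divergence dates (root age defaults to the tree height, i.e. the
  deepest tip touches the present); each fossil terminal branch is set
  to run from its divergence date down to the taxon's last appearance
  date, so the full stratigraphic range lies on the branch — using the
  full temporal duration maximises the time available for trait
  evolution. Extant tips extend to 0 Ma. An LAD older than the
  divergence date is an error; an FAD older than the divergence date
  only warns, because the range then cannot lie fully on the terminal
  branch but the LAD rule still applies.
* **"Equal" zero-branch resolution.** Zero-length internal branches
  (common after calibrating nodes to identical dates) are resolved by
  pooling each maximal run of zero branches with the nearest ancestral
  branch of positive duration and sliding the intervening node ages to
  evenly spaced positions. Sliding node ages cannot change any
  root-to-tip path length, and the tests assert depth preservation to
  1e-9 Myr. Where several branching zero runs share one donor the
  donor's duration is interpolated by node depth, the closest
  generalisation of the chain rule; a zero branch with no
  positive-length ancestor (at the root) is an error since there is no
  time to share. Terminal zero branches are left alone — a tip's age is
  data, not something to slide.
* **Polytomies** are accepted natively; the covariance is well defined
  on multifurcations, so nothing is dichotomised.
* Tip-name matching is exact and case-sensitive after trimming
  whitespace, with spaces and underscores equivalent (the two common
  newick dialects).

## Muscle calculators

`A_Phys = M cos θ / (ρ L)` with mass in g, fibre length in mm, the
default specific density ρ = 1.056 × 10⁻³ g/mm³, and angles in degrees
(converted internally; θ = 0 means parallel fibres, cos θ = 1). For
fossil reconstructions the gross cross-section is corrected for
pennation by division by sin θ with group defaults 45° (temporal), 0°
(quadrate) and 30° (pterygoid) — factors √2, 1 and 2. The sine
correction is undefined at θ = 0; the quadrate group is therefore left
uncorrected, the parallel-fibre reading consistent with the
architecture formula. The correction is implemented exactly as the
division by sin θ — deliberately *not* silently replaced by a cos θ
factor, although the two move in opposite directions with pennation;
the sine form is the stated reconstruction convention this package
reproduces. Left/right gross areas are averaged; a single measurable
side (damage, asymmetry) is accepted as-is.

## The lever model

Muscle force is `F = σ A_Phys` at tetanic stress σ = 0.3 N/mm²
(300 kPa), applied identically to pennate and parallel groups. Torques
`F_i r_i` about the jaw joint are summed and converted to a bilateral
bite force `2 Σ(F_i r_i)/d` at the anterior-most and posterior-most
bite points. The model is scalar (2-D static): forces act perpendicular
to the in-lever, with no 3-D orientation, no gape dependence and no
force–length effects. Geometry (moment arms, out-levers, mm) is
per-taxon input data; the package never measures it from images. When
predictions feed the lever model, the predictive *median* of log10
A_Phys is back-transformed (10^median equals the median of the
back-transformed draws, by monotonicity) — medians are robust to the
log-normal skew that means would inherit. Internally everything is full
precision; rounding to whole newtons belongs to the reporting layer.

## The synthetic-data generator

`simulate_tree()` produces pure-birth ultrametric trees, or "fossil"
trees in which a random ~30% of terminal branches are truncated at a
uniform fraction of their length, emulating last-appearance-dated tips;
depth is rescaled to 100 Myr. `simulate_dataset()` evolves the
predictor as Brownian motion on the same tree (root state 2, i.e.
100 mm skull width; tip SD 0.5 log10 units) — real skull widths are
themselves phylogenetically structured, and although GLS estimators are
valid for any fixed x, calibration studies are only realistic with a
structured predictor. An i.i.d.-x option exists for oracle tests. The
response is the model itself: `y = alpha + beta x + e`,
`e ~ MVN(0, sigma2_bm C_lambda)`. Defaults: α = −1.5, β = 2 (the
area–length scaling exponent), λ = 1, and σ²_BM set so the residual SD
is ≈ 0.2 log10 units at the mean tip depth — the visual scatter of real
area-on-width allometries.

What passing the simulation-based tests shows is that the sampler,
predictor and cross-validation are *internally* correct and calibrated
under the model's own assumptions. It does not show that real data meet
those assumptions: measurement error in reconstructed areas, rate
heterogeneity across clades, non-Brownian evolution and topological
error are all outside the generator, so real-data accuracies can
legitimately fall below the calibrated 95%.

## Numerical choices and degeneracies

* Singular covariances (phylogenetically identical observed tips) get a
  diagonal jitter of 1e-8 × max(diagonal) with a warning; if still
  singular, an error suggests resolving zero-length branches.
  Conditional predictive variances are clipped at zero against
  rounding.
* The σ²_BM Gibbs step enforces its wide log-range prior by redrawing
  (bounded retries); in practice the bound never binds.
* A duplicate of an observed tip at zero distance is predicted with
  zero conditional variance — every draw equals the observed value —
  which the tests use as an exactness check.
* Problem sizes in the shipped tests and acceptance script (59-tip
  recovery studies, 40-tip × 20-replicate LOOCV calibration, 200
  coverage replicates, chains of a few hundred retained draws) were
  chosen as the smallest sizes at which the Monte-Carlo error of each
  check is comfortably below its decision margin; all scale up through
  `ppm_config()`.

## Limitations

Single predictor, single response (no multivariate regression — true of
phylogenetic regression generally); Brownian motion only (no OU or
early-burst residuals); λ is the only signal parameter; no
measurement-error model on x or y; the lever model is static and 2-D.
Tree uncertainty is not propagated — the tree is taken as fixed input,
consistent with the robustness of Brownian-motion regression to branch
length error, but users with credible tree samples should loop the fit
over them.
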