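---
title: "Sampling uncertain parameters in declarative models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sampling uncertain parameters in declarative models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellsamp)
```

## The model of uncertainty

`cellsamp` treats an uncertain parameter as a random variable with a single,
fixed-but-unknown true value: the model remains an ordinary ODE initial-value
problem, *not* a stochastic differential equation. Uncertainty enters a
CellML document through three Content MathML `csymbol` operators rooted at
`http://www.cellml.org/uncertainty-1#`:

* `uncertainParameterWithDistribution` binds one variable — or a vector of
  variables drawn jointly — to a distribution;
* `distributionFromDensity` supplies the distribution as a symbolic
  univariate probability density function, a `lambda` of one bound variable;
* `distributionFromRealisations` supplies it as an ordered vector of
  realisations, each a scalar (one target) or a tuple (several targets).

Keeping the density symbolic preserves the declarative character of the
format: any continuous univariate distribution expressible in the supported
MathML operator set can be attached, with no controlled vocabulary. The
trade-offs accepted here, and deliberately out of scope, are discrete
distributions (probability mass functions), multivariate *densities* (joint
uncertainty is representable only through realisation tuples), and
distribution-specific optimized samplers.

Units follow the usual rule that every variable and constant is annotated;
only presence is validated. Probability values are dimensionless; the one
directly checkable case (a constant-valued density body with other units)
produces a warning, not an error, because full dimensional analysis of
arbitrary expressions is a separate project.

## Sampling from a symbolic density

Draws use inverse-transform sampling with a numerically built CDF. Because
the density's support is unknown a priori, the CDF integral over
`(-∞, y]` is transformed with `w = tan(u)`, mapping the real line onto
`(-π/2, π/2)`; the integrand becomes `f(tan u)·sec²(u)`, and any point value
`F(y)` is a finite-interval adaptive quadrature (QUADPACK through
`stats::integrate`). Any substitution with finite limits would give the same
`F`; the tangent map is the standard full-line choice and is fixed here.

At construction the integrand is accumulated over a fixed grid in `u`
(default 65 nodes), which serves three purposes: the total is the
normalization check (`|F(∞) − 1| ≤ 1e-3`, otherwise the density is
*rejected*, never silently renormalized — a wrong normalization usually
signals a mis-written density, and renormalizing would mask it); negative
subinterval mass detects signed "densities"; and the cached partial sums
provide cheap brackets for later evaluations and inversions.

Inversion finds the smallest `x` with `(F(x) − z)²` minimal for a uniform
deviate `z`. Monotone `F` makes the only local minimum global, so the
implementation brackets from the cached grid and runs a safeguarded Newton
iteration on `F − z` (the density is the exact derivative; steps leaving the
bracket fall back to bisection — the damped analogue of a
Levenberg–Marquardt step on the squared residual). When the density
vanishes at the solution, `F` has a plateau and the minimiser set is an
interval; a second bisection then walks to the left edge, so zero-density
gaps resolve to the smallest minimiser. `z` is clamped to
`[1e-12, 1 − 1e-12]` to avoid infinite quantiles from degenerate deviates.

Tunables (all in `quadrature_settings()`): quadrature `rel_tol` `1e-8` /
`abs_tol` `1e-10` (unitless; tight enough that sampling error dominates),
normalization tolerance `1e-3`, inversion tolerance `1e-9` on the
probability scale, and the cache-grid size. Each draw consumes exactly one
uniform deviate; realisation draws likewise consume one deviate and take
`floor(z·n) + 1` as the index, so tuples are returned whole and joint
structure is never broken.

All randomness flows through `rng_stream`, a seeded Mersenne-Twister stream
isolated from R's global RNG. An experiment run uses a single master stream
in document order — assertion by assertion, sample by sample — which makes a
one-sample sensitivity analysis bit-identical to a plain time course at the
same seed, and the entire pipeline reproducible from one integer.

## Simulation and SED-ML

Models compile to an evaluation plan: states (variables under `diff`),
a single bound variable, topologically sorted algebraic assignments (a cycle
is an algebraic-loop error — true DAE systems are rejected), folded
constants, and parameter slots for the uncertain variables. Integration is
an adaptive Dormand–Prince RK4(5) with FSAL and standard step control
(`rel_tol` `1e-8` by default); no external solver package is required. The
output grid has `number_of_points + 1` uniform entries, except the
degenerate `output_start == output_end` case which reports a single row.

The SED-ML subset covers models, uniform time courses, tasks,
single-variable identity data generators and report outputs. The sampling
extension is carried as a `numberOfSamples` attribute in the uncertainty
namespace on the simulation element (a `samplingSensitivityAnalysis`
element name is also accepted); where the attribute lives in XML was an open
dialect choice and is documented rather than standardized. Per-sample
failures abort the ensemble with the failing sample index and the completed
count — partial ensembles are never silently returned.

## What the fixture generator emulates

The example is a projectile in two dimensions under constant acceleration
with uncertain initial conditions: x₀, y₀ ~ N(0, 1) m and vₓ₀ ~ N(10, 1)
m/s as symbolic densities, and v_y₀ as 1000 realisations from the posterior
predictive of a two-spring mixture: spring chosen with probability ½, each
spring's velocity normal with unknown mean (prior N(9, 0.5²)) and unknown
variance (prior Exp(rate 20), i.e. prior mean 0.05 — "rate" read as a rate,
not a scale), fitted to 40 observations of which twenty equal 6 and twenty
equal 12. The accelerations are not part of the statistical story and are
plain config (defaults aₓ = 0, a_y = −9.81 m s⁻², the obvious physical
choice for a projectile).

The posterior is sampled by Metropolis-within-Gibbs: exact Gibbs updates for
the latent spring labels and (conjugate) per-spring means, and random-walk
Metropolis on the log variance, whose exponential prior breaks conjugacy.
Label switching is never "fixed" by relabeling; every reported summary is
label-invariant (order statistics of the means, the predictive
distribution).

Two honest caveats about this stated world:

* **The variance posterior is improper.** With every observation exactly 6
  or 12, a component that captures one cluster has a sum of squares of
  exactly zero, and its variance posterior behaves as
  `(σ²)^(−n/2)·e^(−20σ²)`, which diverges at the origin — the chain's log
  variance drifts downward forever. This is a property of the published
  statistical model on its degenerate dataset, not of the sampler. A
  numerical guard rejects proposals below `log σ² = −60`; every asserted
  quantity (means locked on 6 and 12, bimodal predictive, 50/50 spring
  weights) is insensitive to the bound, and on non-degenerate data (the
  parameter-recovery test) the guard is never touched and Metropolis
  acceptance sits in the usual 20–50 % band.
* **What a green test establishes.** The generator reproduces the *stated*
  inputs — printed priors, printed data, chain sizes — so passing tests
  establish that the sampling and simulation machinery recover the
  analytically known consequences of those inputs (means, weights, modes,
  closed-form kinematics). They do not establish agreement with any
  particular historical chain, which is unrecoverable; the realisation
  vector is a fresh, seeded draw from the same posterior.

The long-run oracle chain used by the bimodality property test is scaled to
2.5×10⁴ retained iterations to stay inside test-time budgets; the mode
locations it checks lock within a few hundred iterations.

## Numerical choices and limitations

* Relational and logical MathML operators evaluate to 1/0 reals and
  piecewise treats nonzero as true, keeping the evaluation environment
  single-typed.
* Narrow piecewise features can in principle be missed by any quadrature
  rule with finitely many samples (a uniform density of tiny width, say);
  the grid accumulation mitigates but cannot eliminate this. Densities that
  lose mass this way fail the normalization check rather than sampling
  wrongly.
* Realisation elements must be constant expressions; they are evaluated
  once at load, so a realisation vector cannot reference model variables.
* CellML `import` is rejected (single-document models only), units algebra
  is presence-only, and stiff/implicit DAE systems are out of scope.
* Where `F` is extremely flat in a tail, inversion accuracy is bounded by
  the inversion tolerance on the *probability* scale: quantiles deep in a
  tail inherit the local `1/f` amplification, which is inherent to
  inverse-transform sampling with a numerical CDF.
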