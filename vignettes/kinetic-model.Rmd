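---
title: "A simplified first-order kinetic model for the enantioselective hydrogenation of 1-phenyl-1,2-propanedione"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A simplified first-order kinetic model for the enantioselective hydrogenation of 1-phenyl-1,2-propanedione}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppdkinetics)
```

## The model and its assumptions

1-Phenyl-1,2-propanedione (**A**) is hydrogenated over Ir/TiO₂ in the
presence of cinchonidine, a chiral modifier adsorbed from solution. The
first hydrogenation reduces one of the two carbonyls and yields four
chiral hydroxyketones (**B**–**E**); the second reduces the remaining
carbonyl and yields four diols (**F**–**I**). With four parallel first
steps and two exits from each hydroxyketone, up to twelve reactions are
possible.

`ppdkinetics` implements the deliberately minimal description of this
process as a homogeneous-like first-order irreversible network:

* every step is apparent first order in its single substrate;
* no step is reversible (no dehydrogenation);
* hydrogen partial pressure, solvent, catalyst loading, temperature and
  modifier concentration are not state variables — their effects are
  lumped into the apparent constants *k*₁…*k*₁₂ (units min⁻¹);
* adsorption/desorption is not modelled explicitly; any adsorption
  contribution also lives inside the constants.

These assumptions buy an enormous simplification: the mass balances form
a linear time-invariant ODE system

$$\frac{dc}{dt} = K\,c, \qquad c(t) = e^{Kt} c(0),$$

with a 9×9 generator $K$ whose off-diagonal entries are the formation
rates `K[target, source] = k(edge)` and whose diagonal entries are minus
the total consumption rate of each species. Every column of $K$ sums to
zero, so total concentration is conserved exactly (1:1 stoichiometry,
terminal diols). The price is that the model cannot represent saturation,
site competition, modifier-coverage effects or any pressure/temperature
dependence; it is a local description of one operating point.

The twelve edges carry fixed indices (`k1: A→E`, `k2: A→B`, `k3: A→D`,
`k4: A→C`, `k5: B→I`, `k6: B→F`, `k7: C→H`, `k8: E→I`, `k9: C→G`,
`k10: E→H`, `k11: D→F`, `k12: D→G`). The pairing of `k5`/`k12` with
`{B→I, D→G}` is a declared package convention — the route evidence pins
down the other ten assignments but not these two — and the network
definition is loaded from YAML
(`system.file("extdata", "network.yaml", package = "ppdkinetics")`), so
the convention can be swapped without touching code. Species order is
fixed as `A, B, …, I` in every matrix, file and report.

## Forward solution and closed-form cross-checks

`simulate_profile()` propagates the state with the matrix exponential.
We deliberately use scaling-and-squaring (`Matrix::expm`) rather than
eigendecomposition: the generator of a network with repeated or
near-equal rates can be defective, and scaling-and-squaring does not
care. Along a time grid the propagation is sequential — one exponential
per *distinct* time step, then matrix–vector updates — which is exact for
a time-invariant linear system (semigroup property) and makes the
equally spaced default grid cheap.

Two independent routes to the same numbers guard the solver:

* `ode_oracle()` integrates the same system with an adaptive
  Runge–Kutta/BDF solver (`deSolve::lsoda`, rtol = atol = 1e−12). It
  exists purely as a cross-check; tests require agreement with the
  matrix-exponential path within 1e−8 max-abs over random rate draws.
* `bateman_intermediate()` gives the textbook closed form for each
  hydroxyketone, $x(t) = k_\mathrm{in}\,
  \frac{e^{-k_\mathrm{out}t} - e^{-k_\mathrm{tot}t}}
  {k_\mathrm{tot}-k_\mathrm{out}}$. We evaluate it through `expm1` as
  $k_\mathrm{in}\,t\,e^{-k_\mathrm{out}t}\,\phi(x)$ with
  $\phi(x) = -\mathrm{expm1}(-x)/x$, $x = (k_\mathrm{tot}-k_\mathrm{out})t$,
  which removes the catastrophic cancellation of the naive difference of
  exponentials and passes continuously through the equal-rate degeneracy
  ($\phi \to 1$), instead of switching branches at a hard threshold.

`time_of_maximum()` returns the interior peak time
$\ln(k_\mathrm{tot}/k_\mathrm{out})/(k_\mathrm{tot}-k_\mathrm{out})$ of an
intermediate (equal rates: $1/k_\mathrm{tot}$). The peak time is
independent of the formation rate constant — it only scales the
amplitude — so the function takes two arguments, not three. A terminal
species (`k_out = 0`) has no interior maximum and yields `NA`.

## Estimation

`fit_kinetics()` minimises the pooled sum of squared residuals over all
times and all nine species subject to $k_i \ge 0$, by
Levenberg–Marquardt (`minpack.lm::nls.lm`) from a common initial guess of
0.01 min⁻¹ — the standard protocol for this system. A constant the data
push negative is clipped to the bound and flagged `at_bound`; it is
reported without an interval and excluded from the covariance, because
the local quadratic approximation is invalid at an active bound.

Uncertainty comes in two flavours:

* **Laplace** (default): covariance $s^2 (J^\top J)^{-1}$ over the free
  parameters, with $J$ the residual Jacobian at the optimum (central
  differences, relative step 1e−5) and $s^2$ the residual mean square.
  The 95% marginal HPD half-width is $1.96\,\mathrm{se}$; an interval
  that would cross zero is truncated and flagged one-sided.
* **MCMC** (`uncertainty = "mcmc"`): random-walk Metropolis over the free
  parameters with flat $k \ge 0$ priors, Gaussian likelihood with the
  plug-in residual variance, and a proposal scaled from the Laplace
  covariance ($2.38^2/d$). `hpd_interval()` then reports the narrowest
  interval containing 95% of the marginal posterior mass. For this model
  the posterior is close to Gaussian away from the bound, so the two
  routes agree; the sampler exists to verify that, and for datasets where
  a constant hovers near zero and normality fails.

Initial concentrations default to the dataset's first row (profiles are
fitted as observed; the model then propagates from the first observed
state). When the initial charge is known — as it is in a real batch
experiment, and for synthetic data by construction — pass `c0` explicitly;
this avoids attributing measurement noise on the first sample to the rate
constants.

**Residual weighting.** The default is uniform (a diagonal, equal
observation covariance): every cell of the times × species table counts
the same, in concentration units. This is the conventional choice when
the error structure is unknown, and it is scale-invariant in the sense
that multiplying all concentrations by α changes no estimate. But if the
measurement error is *relative* (multiplicative), uniform pooling
misstates the information content of the cells: high-concentration cells
carry more noise than the pooled variance admits, and Laplace intervals
for the constants they inform undercover (we measure ≈ 80–85% instead of
95% at 2% relative noise). `fit_config(weighting = "relative")` scales
each residual by its observed magnitude (floored at 0.1% of the largest
observation to keep empty cells finite), which matches a multiplicative
error model and restores nominal coverage (89–95% measured across all
identifiable constants, 200 replicates). The coverage and
correlation-structure tests in the suite therefore use the relative
weighting, which matches the noise their own generator injects;
`per_species` (one scale per species) is a coarser intermediate option.

Convergence tolerances are tight (`ftol = ptol = gtol = 1e−15`, up to 500
iterations) so that refitting noiseless self-generated data returns the
generating constants to ~1e−8 relative — far inside the 0.1% the
self-consistency tests demand. Non-convergence is flagged on the result,
not raised; genuinely under-determined inputs (fewer observations than
parameters, missing species columns, a single time point) are rejected up
front.

`correlation_matrix()` exposes the parameter interdependence
diagnostics. Under the default design the strongest couplings are
between the parallel-route pairs feeding the same diol — in particular
`k10↔k1` and `k10↔k7`, the two legs toward **H** via **E** against the
competing route via **C** — which is the expected signature of routes
that can partially trade off against each other while matching the same
diol accumulation curve.

## Synthetic data: what it emulates, what it does not

No concentration table for this system is publicly deposited, so the
package carries a first-class generator. `experiment_design()` defaults
are the study conditions: 10 sampling times on 0–360 min, a pure reactant
charge (`A = 1`, arbitrary units — first-order constants are
scale-invariant, and no absolute concentrations are published), and the
published constants as the generating truth. The exact sampling grid is
not published; we use 10 equally spaced points including *t* = 0, the
natural reading of "10 experiments, one per reaction time" over that
range.

`noise_spec()` defaults to multiplicative Gaussian noise with σ = 2%,
chosen once to match the visual scatter of the reported profiles on the
major species while leaving the minor diols (**G**, **I**) noisy relative
to their small signals, as described qualitatively for the experimental
data. Negative noisy values are clipped to zero (measured concentrations
are physical). Every generated dataset records seed, noise and generating
constants in its metadata.

The generator emulates i.i.d. per-cell noise only. Real
chromatographic data have correlated calibration errors, drift,
species-specific detection limits and possibly non-Gaussian tails; none
of that is modelled. Passing tests therefore demonstrate that the
*pipeline* is correct and well-calibrated under its own assumptions — not
that those assumptions hold for any particular instrument.

## Pathway classification

`classify_pathways()` turns a fitted constant vector into the qualitative
route summary. An edge is negligible when its constant is at or below the
threshold (default 0 — i.e. exactly at the imposed bound), and a route
containing a negligible edge is negligible. Among the rest, route
`A–X–Y` is preferential when its first leg is strictly the largest of the
first legs feeding the same diol *and* its second leg is strictly the
largest of the edges leaving the same hydroxyketone; ties are reported as
ties rather than broken arbitrarily. This is the operationalisation of a
summary that is usually drawn, not defined: it reproduces, from the
published constants, the known picture — negligible **E**→**I** and
**C**→**G**, preferential **A**–**B**–**F** and **A**–**C**–**H**, the
other four routes intermediate.

`selectivity_metrics()` adds the standard derived quantities
(regioselectivity (B+C)/(B+C+D+E); enantiomeric excesses (B−C)/(B+C) and
(D−E)/(D+E)), guarded to `NA` when a denominator is zero, e.g. at
*t* = 0. These are reporting conveniences layered on the model's outputs.

## Numerical and design choices

* Matrix exponential: scaling-and-squaring, robust to repeated
  eigenvalues; sequential propagation caches one exponential per distinct
  time step.
* Bateman evaluation via `expm1`: no branch threshold, continuous through
  the degeneracy.
* At-bound detection: an estimate within 1e−9 min⁻¹ of the lower bound
  (four orders of magnitude below the typical constants here) is snapped
  to it.
* Laplace Jacobian: central differences with step 1e−5 relative to
  max(estimate, initial guess).
* The raw (unweighted) SSR is always reported in concentration² units,
  whatever weighting drives the optimiser.
* SSR and the correlation matrix are reported as diagnostics but never
  compared against external values: both depend on the actual
  experimental data, which are not deposited.

## Problem sizes used by the tests

The suite runs entirely on generated data: single fits for the
self-consistency checks (90 observations, 12 parameters); 20 random
systems for the solver-equivalence and conservation properties; 200
replicate fits at 2% noise for interval coverage and for the noise-bias
check; 50 replicate fits for the correlation-structure ranking. These
sizes put Monte-Carlo error comfortably inside the asserted bands (e.g.
binomial standard error ≈ 1.5% at 200 replicates for a 95% coverage
proportion) while keeping the whole suite in the minutes range on one
core.

## Known limitations

* The model is local: constants are valid for one catalyst, solvent,
  temperature, pressure and modifier concentration. Extrapolation needs
  an adsorption-aware model, which is out of scope here.
* With only 10 time points and 12 parameters, the weakly expressed
  constants (those of the minor routes toward **G** and **I**, and the
  small `k10`) are estimated with wide intervals and can hit the zero
  bound under realistic noise; this mirrors the large published
  uncertainties for the same constants.
* The published SSR and correlation entries cannot be reproduced exactly
  without the original raw data; the package reproduces the *structure*
  of those diagnostics (which pairs correlate most strongly, which
  constants sit at the bound), not their numerical values.
* The MCMC sampler is a single-chain random-walk Metropolis, adequate for
  this 10-dimensional, near-Gaussian posterior; it is not a
  general-purpose sampler.
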