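---
title: "Spatio-temporal small-area estimation of Caesarean-section rates: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatio-temporal small-area estimation of Caesarean-section rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

National birth registries record every delivery with its outcome
(Caesarean section or vaginal birth), the mother's municipality of
residence, and clinical covariates. Crude municipal CS rates are noisy
— many municipalities see fewer than a hundred births a year — and they
confound case-mix differences (parity, breech presentation, previous
CS, ...) with differences in obstetric practice. `csfields` implements
a model-based answer: a logistic regression at the individual-birth
level with a smooth spatio-temporal latent field that captures the
residual, geographically structured variation in CS use, plus the
supporting pipeline (registry-style simulator, cohort exclusion rules,
WHO Robson ten-group classification, and reporting).

## The model

For birth $i$ in municipality $s(i)$ and year $t(i)$,

$$\operatorname{logit} P(\text{CS}_i = 1) \;=\; x_i^\top\beta \;+\;
\omega\,(t(i) - t_0) \;+\; u(s(i),\, t(i)),$$

where $x_i$ holds the categorical clinical covariates (reference
levels: age 20–34, multiparous without previous CS, term gestation
37–41+6 weeks, medium-volume unit, male infant, absence of each binary
factor), $\omega$ is a global linear time trend per year, $t_0$ is the
midpoint of the study window (centring decorrelates $\hat\omega$ from
the intercept), and $u$ is a zero-mean latent Gaussian field.

The field is *separable*: Matérn in space, first-order autoregressive
in time,

$$u(\cdot, 1) \sim \mathrm{GF}\!\left(0,\; \tfrac{\sigma_\epsilon^2}{1-\alpha^2}\, r(\cdot)\right),
\qquad
u(\cdot, t) = \alpha\, u(\cdot, t-1) + \epsilon_t,$$

with spatial innovations $\epsilon_t$ of marginal standard deviation
$\sigma_\epsilon$ and Matérn correlation (smoothness $\nu = 1$)

$$r(d) = \kappa d\, K_1(\kappa d), \qquad \kappa = \sqrt{8}/\rho .$$

Under this convention $r(\rho) \approx 0.14$, the usual reading of
"the correlation has dropped to about 0.1 at the range". Stationary
initialisation makes the marginal variance
$\sigma_\epsilon^2/(1-\alpha^2)$ identical in every year, and the
correlation between the same place in consecutive years exactly
$\alpha$ (a property the tests verify against a dense Kronecker
oracle). The odds ratio of a fixed effect is $e^\beta$.

## Discretisation: SPDE on a triangulated mesh

The Matérn field is represented as a Gaussian Markov random field
through the stochastic-partial-differential-equation construction:
on a Delaunay triangulation with piecewise-linear elements, the sparse
precision is

$$Q_s = \tau^2\left(\kappa^4 C + 2\kappa^2 G + G C^{-1} G\right),$$

with lumped (diagonal) mass matrix $C$, stiffness matrix $G$, and
$\tau$ fixed by the nominal marginal variance
$1/(4\pi\kappa^2\tau^2) = \sigma_\epsilon^2$. The space–time precision
is the Kronecker product $Q_t(\alpha) \otimes Q_s$ with $Q_t$ the
stationary AR(1) tridiagonal precision (unit innovation variance,
$\det Q_t = 1-\alpha^2$ for every length). The mesher is a direct
Bowyer–Watson implementation; no triangulation library is required.

Mesh policy and its consequences:

* vertices are the municipality centroids, an optional regular
  interior fill at spacing `max_edge_km`, and a coarser rectangular
  ring of boundary-extension points at distance `extension_km`
  (default recommendation: `max_edge_km` ≈ ρ/3, `extension_km` ≈ ρ, so
  Neumann boundary effects stay outside the data);
* the projector matrix carries barycentric weights (rows sum to one);
  since centroids are vertices, its rows are unit vectors;
* accuracy is resolution-limited: on a regular grid at spacing ρ/6.7
  the precision-implied correlations match the closed-form Matérn
  within 0.05 at distances ρ/4 … 2ρ (dense-inversion oracle in the
  tests); at spacing ρ/4 the error at short range slightly exceeds
  0.05. On a *coarse centroid-only* mesh the finite-element marginal
  variance can sit well below nominal (we measured ratios near 0.73 on
  a 20-point toy); with interior fill the ratio is within half a
  percent. Parameter recovery on a shared simulation/fitting mesh is
  unaffected, but nominal-variance statements require an adequately
  fine mesh — the stationarity tests therefore use filled meshes.

## Likelihood and the Laplace approximation

Records are aggregated to binomial design rows (municipality × year ×
covariate pattern) — lossless for the likelihood and an order of
magnitude smaller. The marginal likelihood integrates the latent field
out of

$$-\log p(y, u \mid \theta) = \tfrac12 u^\top Q u - \tfrac12\log\det Q
+ \sum_r \left[n_r \log(1 + e^{\eta_r}) - k_r \eta_r\right] + \text{const}$$

by a Gaussian approximation at the conditional mode $\hat u$:
$-\log p(y\mid\theta) \approx f(\hat u) + \tfrac12 \log\det H -
\tfrac{d}{2}\log 2\pi$, $H = Q + A^\top W A$. The mode is found by
sparse Newton iterations (supernodal Cholesky with a reused symbolic
analysis); with no data the approximation is exactly zero, a useful
self-test. Against brute-force oracles the implementation agrees to
1e-8 (dense 5-vertex/3-year toy) and to the O(1/n) Laplace bias
against 1-D adaptive quadrature on a scalar model — at one million
trials the gap is ~4e-7, and it scales visibly as 1/n at smaller
counts, which is the approximation, not the code.

## Optimisation design

Automatic-differentiation stacks optimise all parameters in the outer
loop. With finite-difference gradients that design costs ~2 Laplace
evaluations per parameter per gradient, and at the recovery-study
scale we measured ~800 evaluations (≈2.5 minutes) per fit. The default
here instead *profiles* the fixed effects into the inner problem: the
inner Newton solves jointly for (field, β, ω) — a sparse system
bordered by the dense fixed-effect block, solved by block elimination
with the same cached factorisation — and only
$(\log\sigma_\epsilon, \log\rho, \operatorname{atanh-type}(\alpha))$
remain outer. This is the standard "profile" device of mixed-model
software. It is not free: the joint mode neglects the
$\partial(\log\det H)/\partial\beta$ term of the exact marginal, and
for covariates that push $p$ far from $\tfrac12$ the displacement of
$\hat\beta$ is comparable to its standard error at registry sample
sizes (we measured ≈1 SE on a log-OR of 2.6 at 300k births). A final
refinement stage therefore re-optimises $(\beta, \omega)$ against the
*exact* Laplace marginal at the converged hyperparameters — cheap,
because the prior assembly is cached and each evaluation is a single
warm inner Newton over the field — after which the estimates coincide
with the all-parameter outer loop to well within a tenth of a standard
error. A fit then takes ~160 evaluations (≈6 s at the recovery-study
scale, versus ≈2.5 min for the all-parameter loop), and a test
confirms the two strategies land on the same optimum.

Numerical choices, stated once:

* transformed scales: $\log \sigma_\epsilon$, $\log \rho$, scaled
  logit of $\alpha$ onto $(-1, 1)$ (negative values implausible but
  admissible; unconstrained scales behave better than hard bounds);
* outer: `nlminb`, relative tolerance 1e-5, central finite differences
  with step 1e-4;
* inner Newton: gradient max-norm 1e-8 at the reported optimum; 1e-6
  during outer iterations (the induced NLL error, ~1e-9, is far below
  the finite-difference resolution and saves one factorisation per
  evaluation); at most 100 iterations, step-halving line search;
* initial values: β, ω from a plain fixed-effects logistic fit; α from
  the lag-1 correlation of cell-level residual logits; σ from their
  noise-corrected excess variance; ρ from the residual correlogram's
  0.14 crossing (fallback: half the median inter-centroid distance);
* standard errors: hyperparameters from the inverse numerical Hessian
  of the profiled marginal NLL, delta-mapped to natural scales;
  fixed effects from the inverse Schur complement of the joint
  curvature at the mode (this neglects the fixed-effect ×
  hyperparameter cross-information; replicate studies show empirical
  coverage of 92–98% at nominal 95%, so the omission is not material
  at these scales). A non-positive-definite curvature yields `NA`
  standard errors and a warning, never a crash.

Empirical-Bayes field estimates are the inner mode at the maximum
likelihood hyperparameters; reference-profile rate surfaces are
$\operatorname{logit}^{-1}(\hat\beta_0 + \hat\omega(t - t_0) +
\text{projected field})$, and the delta method maps a logit-scale SD
σ to the probability scale as $\sigma\, p\,(1-p)$.

## The synthetic registry

Real registry data cannot be redistributed, so every downstream stage
is exercised against a generator with known ground truth. The stated
world: ~440 municipalities placed uniformly (minimum separation 5 km —
isotropy makes the true clustered geography irrelevant to
correctness) on a 420 km × 1752 km planar domain; 14 annual cohorts
(2001–2014); per-municipality mean annual births log-normal
(meanlog 4.6, sdlog 1.1, spanning below 50 to the thousands) with
Poisson year-to-year variation; default field and trend parameters at
the published main-analysis estimates (σ_ε = 0.125, ρ = 114 km,
α = 0.92, ω = 0.024) and fixed effects at the published odds ratios.
The intercept is centred so the covariate-averaged rate matches the
~16% national level. One master seed expands into independent
per-stage streams, so enlarging one stage never shifts another.

Covariate prevalences are **placeholders**: the source tables report
odds ratios, not prevalences. The defaults (e.g. smoking in early
pregnancy 15%, breech 4%, multiple pregnancy 1.7%, nulliparous 42%)
were chosen once for plausibility and are not calibrated to any
registry. Covariates draw independently apart from consistency rules
(previous CS forces multiparity; breech and cephalic exclusive;
smoking at end implies smoking at beginning). The generator does not
emulate within-mother correlation across births, migration, or true
Norwegian geography — a green recovery test therefore establishes
correctness of the estimation machinery under the model, not realism
of the world.

## Cohort filter and Robson classification

The exclusion rules: home deliveries; maternal age outside [15, 45];
gestational age below 24 completed weeks (168 days, half-open — 168
survives); municipality outside the geographic domain; missing values
in any of municipality, age, GA, sex, birthweight, birth unit,
presentation; and municipalities averaging 49 or fewer births per
year, removed wholesale (the source removed 17 municipalities as
units, which points to a per-municipality decision rather than a
per-year one). A record failing several rules is counted once, at the
first rule in that order; the surviving set is order-invariant. The
low-volume average is taken over the records that pass all other
rules, which is what makes the filter idempotent. Abortions carry no
separate code in the synthetic schema and are captured by the GA rule
only.

Robson groups follow the standard WHO precedence — multiples (8),
transverse/oblique lie (9), breech (6 nulliparous / 7 multiparous, no
gestational-age restriction), preterm cephalic singleton (10,
including previous CS), then term cephalic singletons 1–5 by parity,
previous CS and onset — with term = 259 days. Group 5 includes all
onsets. Stratified fits for groups 1, 3, 5, 6 drop parity, GA class,
induction and breech from the design, since they define the strata.

## Known limitations

* Outer derivatives are finite differences, not automatic
  differentiation: optimiser trajectories can differ from AD stacks in
  the last significant digits, though the optimum does not.
* Wald intervals for ρ inherit the well-known skewness of range
  parameters; profile intervals would behave better and are not
  implemented.
* The Laplace approximation's O(1/n) bias is invisible at registry
  scales but measurable in cells with a handful of births.
* The mesh is planar; geographic projection from longitude/latitude is
  assumed done upstream, and road-network ("driving-distance")
  metrics are out of scope.
* Absolute rate levels depend on the intercept/reference-year
  convention; published tables omit the intercept, so reproductions
  are convention-dependent by nature.
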