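---
title: "Models, discretisations and design choices in detomo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, discretisations and design choices in detomo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

detomo reconstructs the scattering coefficient $\sigma(x)$ of a tissue-like
medium from light measurements on its boundary, in a Bayesian framework, and
accelerates the sampling with a delayed-acceptance ("two-level") scheme in
which a cheap diffusion solver filters proposals before the expensive
transport solver is consulted. This vignette records the models, the
discretisations, and every design choice that was genuinely open, together
with its rationale.

## Forward models

**Radiative transfer.** The photon phase-space density $f(x, v)$ on
$\Omega \times S^{1}$ satisfies the scaled transport equation

$$ v \cdot \nabla f = \frac{\sigma(x)}{\varepsilon}\,\big(\langle f
\rangle_v - f\big), \qquad f\big|_{\Gamma^-} = \phi, $$

where $\langle \cdot \rangle_v$ is the average over the unit circle
(normalised measure), $\varepsilon$ is the Knudsen number (mean free path
over domain size), and $\Gamma^-$ is the incoming part of the boundary
phase space ($v \cdot n < 0$). The collision operator
$Lf = \langle f \rangle_v - f$ annihilates angle-independent functions and
conserves particles ($\langle Lf \rangle_v = 0$); both properties are
asserted to machine precision in the test suite.

**Diffusion limit.** As $\varepsilon \to 0$, $f \to \rho(x)$ with
$\nabla \cdot (\sigma^{-1} \nabla \rho) = 0$ and $\rho|_{\partial\Omega} =
\xi$. The dimensional constant $C_d = \langle (v\cdot n)^2 \rangle = 1/2$
in front of the operator cancels in the Dirichlet problem and is kept only
where transport and diffusion boundary data are compared.

## Discretisation

Both solvers share one tensor grid with spacing `dx = 0.05` (21 nodes per
dimension) and, for transport, 16 cell-centred angles
$\theta_m = (m - \tfrac12)\,2\pi/16$ with equal weights $1/16$.
Cell-centring keeps $\cos\theta$ and $\sin\theta$ away from zero, so the
first-order upwind stencil is always well defined; a node-centred set with
the same spacing would place $\theta = \pi/2$ on the grid and break the
sweep direction.

* Transport uses first-order upwinding per direction component; inflow
  boundary rows enforce $f = \phi$ on incoming directions. The assembled
  sparse system (7056 unknowns on the square) is solved by a sparse LU
  factorisation reused across all source vectors of a design. Assembly is
  split into a fixed pattern plus a value update in $\sigma$, because one
  MCMC chain assembles thousands of matrices on one grid.
* Diffusion uses the conservation-form five-point (three-point in 1-D)
  scheme with $1/\sigma$ sampled at **face midpoints**. For
  piecewise-constant media this equals lowest-order finite elements with
  element-wise coefficients and is nodally exact in 1-D whenever coefficient
  jumps align with grid nodes — which is why it, and not the
  harmonic average of node samples, is the package default. The
  Dirichlet-to-Neumann flux uses the second-order one-sided stencil
  $(3\rho_b - 4\rho_1 + \rho_2)/(2\,dx)$; note it degrades where a
  coefficient jump sits within two cells of the boundary (the reconstruction
  examples place all inclusions in the interior).
* Media are point-sampled at grid nodes. Interval membership is closed
  (with a $10^{-12}$ tolerance, so a node at $3 \times 0.05$ still belongs
  to $[0.05, 0.15]$ despite floating-point representation); disk membership
  is strict ($|x - c| < r$). Admissibility of a medium (bounds on
  $\sigma$, $\sigma^{-1}$, $\nabla\sigma^{-1}$) is reported on the discrete
  grid as a diagnostic only: characteristic-function media are not
  $W^{1,\infty}$, so no solver gates on it.

**A known limitation: the upwind scheme is not asymptotic-preserving.**
At fixed `dx`, as $\varepsilon \to 0$ the numerical diffusion of the upwind
stencil (effective diffusivity $\sim dx\,\langle|v\cdot n|\rangle /
(2\varepsilon)$ relative to the physical one) dominates, and the discrete
transport density tends to a nearly homogeneous-medium profile rather than
the discrete diffusion solution. Two practical consequences are documented
by the tests: the slab error ladder of the forward study flattens near
$0.099$ instead of decaying to zero, and the $1/(C_d\varepsilon)$-normalised
boundary current amplifies an $O(dx)$ boundary defect without bound as
$\varepsilon \to 0$. Resolving the mean free path or using an
asymptotic-preserving discretisation removes both effects but is outside
the package's scope.

## Measurement model

A design consists of $K = 20$ Kronecker-delta sources on the left edge (one
per $y$-node except the top corner, matching the stated count of twenty
experiments) and $J = 80$ detectors at every distinct boundary node.
Sources have unit amplitude: isotropic over incoming directions for
transport, the same nodal value as Dirichlet data for diffusion.
Measurement vectors are detector-fastest.

The measured datum is the **physical outgoing current**,

$$ G_{\mathrm{RTE}}(j, k) = \sum_m w_m\,(v_m \cdot n)\,f_k(x_j, \theta_m),
\qquad G_{\mathrm{DE}}(j, k) = -\,C_d\,\varepsilon\,\frac{1}{\sigma}
\frac{\partial \rho_k}{\partial n}(x_j), $$

the minus sign because the outgoing Fick flux is minus the
Dirichlet-to-Neumann normal derivative. Both maps then carry the same units
and converge to each other in the diffusion limit
($\lVert G_{\mathrm{RTE}} - G_{\mathrm{DE}} \rVert$ falls from 47 to 0.30
over $\varepsilon = 1 \to 2^{-6}$ on the single-disk medium). The
analytical normalisation that divides both by $C_d \varepsilon$ is available
(`current_scaling = "normalized"`), but it is not the default for two
reasons: physically, a detector reads the actual outgoing light, and the
additive noise level $\gamma^2 = 10^{-4}$ belongs on that scale; and
numerically, the $1/\varepsilon$ factor amplifies the upwind boundary
defect discussed above, which at $\gamma = 0.01$ would make the likelihood
implausibly sharp (posterior spreads of order $10^{-3}$ in a radius, where
the reference posteriors have prior-scale spread).

Synthetic data are $b = G(\sigma_{\mathrm{truth}}) + \eta$ with
$\eta \sim N(0, \gamma^2 I)$ from a seeded generator; data and solver share
one grid (the usual inverse crime, accepted deliberately for method
verification). What the generator emulates is therefore *model-consistent
noisy measurements*; it does not emulate discretisation mismatch between
data and solver, detector physics, or model error against real tissue —
passing tests certify the sampler and the surrogate logic, not robustness
to those effects.

## Posteriors and samplers

The unnormalised log posterior is $\log \mu_0(\theta) - \lVert b -
G(\theta)\rVert^2 / (2\gamma^2)$ (the standard Gaussian form; a factor
$1/\gamma^2$ without the 2 appears in some asymptotic arguments but the
likelihood itself fixes the 2). Out-of-support proposals are rejected
without touching a solver, and all Metropolis ratios are computed in log
space.

* **Single-disk example.** Parameters $(r, h)$, truth $(0.4, 10)$, uniform
  prior $r \in [0, 0.5]$, $h \in [8, 12]$ (as in the reference study); chains start at the
  prior midpoint.
* **Five-disk example.** Parameters $(h_1..h_5, r_1..r_5)$ with fixed
  centres; truth heights $(5, 1, 7, 4, 10)$ and radii
  $(0.19, 0.10, 0.09, 0.13, 0.04)$. The reference prior is unstated; the
  package uses independent uniforms on $[0, 2\,\theta_i^{\mathrm{true}}]$.
  This is pinned by the reference posterior moments: the diffusion-posterior
  means sit essentially at the truth while the variances are prior-scale
  (e.g. $0.0078$ against the $[0, 0.38]$-uniform variance $0.012$ for
  $r_1$); for weakly-identified radii only a prior centred at the truth can
  produce that pattern. Chains start from the componentwise perturbation
  $(0.6 + 0.4\,u_i)\,\theta_i^{\mathrm{true}}$.
* **Proposal.** Componentwise Gaussian random walk. The reference proposal
  is unstated, but the one-level acceptance rates it produced are reported
  (0.735 for the single-disk and 0.818 for the five-disk runs in the
  diffusive regime), and the acceptance rate of a random walk pins its step
  scale given the posterior. The default widths are therefore calibrated,
  once per example, so that one-level sampling of the transport posterior
  reproduces those rates: `(0.08, 0.8)` for `(r, h)` (giving 0.72), and
  0.01 / 0.1 for radii / heights (giving 0.78). No burn-in is discarded by
  default (raw chains are reported).
* **Two-level scheme.** Level 1 applies the Metropolis test under the
  diffusion posterior (rate $\alpha$); pre-accepted proposals meet the
  transport posterior through the closed-form second-stage probability
  $\beta = \min\{1, \mu_{\mathrm{DE}}(x)\,\mu_{\mathrm{RTE}}(y) /
  (\mu_{\mathrm{DE}}(y)\,\mu_{\mathrm{RTE}}(x))\}$ — never through the
  integral form of the effective proposal, which the closed form provably
  equals. Both densities of the current state are cached, so the transport
  map is evaluated exactly once per pre-accepted proposal plus once at the
  start; the test suite asserts this count. Discrete-state adapters of both
  samplers exist so that detailed balance and stationarity can be verified
  exactly against hand-built transition kernels.
* **Data-generating model per run.** The two-level studies use
  transport-generated data at the run's $\varepsilon$ (regenerated per
  $\varepsilon$ with the run seed). The diffusion-posterior recovery study
  generates its data with the diffusion map instead: because the upwind
  scheme is not asymptotic-preserving, transport-generated data carry a
  systematic model gap that displaces the weakly-identified diffusion
  posterior by several posterior standard deviations, conflating solver
  bias with the recovery question the study asks.

## Analysis choices

* **KDE.** Product-Gaussian kernels on the cell centres of a regular grid
  over the prior box, 100 cells per dimension by default, renormalised to
  unit mass on the box; bandwidth per dimension by Silverman's rule,
  overridable. Ten-parameter chains are compared through named marginals
  (e.g. $(r_1, r_4)$), matching the reference comparisons.
* **Distances.** Hellinger on the shared grid (bounded in $[0, 1]$,
  symmetric, refinement-stable for smooth densities); KL with a $10^{-30}$
  floor under the logarithm so empty tails penalise finitely. Reference
  Hellinger values depend on the unstated smoothing bandwidth, so the
  package asserts their ordering in $\varepsilon$, not their values.
* **Cost model.** For $k$ accepted samples,
  $\mathrm{Cost}_1 = (k/r_1) C_R$ and $\mathrm{Cost}_2 = (k/(\alpha\beta))
  C_D + (k/\beta) C_R$, with ratio $\to r_1/\beta$ as $C_D \to 0$ (asserted
  exactly). $C_D$ and $C_R$ are measured as median wall-clock solve times
  over repeated evaluations rather than from asymptotic operation counts.

## Tolerances and problem sizes

Linear solves are direct and checked at relative residual $10^{-10}$
(transport) and $10^{-10}$ (diffusion). Oracle-equivalence tests run dense
loop-assembled references on grids up to $5$ nodes per dimension and 4
angles at $10^{-10}$; property tests (maximum principles, conservation,
constant preservation) use 10–20 randomised cases under fixed seeds. The
test suite runs the reconstruction studies at 300 sampler steps (the
full-scale figure is $10^3$), which keeps the whole suite within a normal
check budget while leaving the acceptance script to run the full-scale
chains; empirically the second-stage rate at 300 steps sits within a few
hundredths of its full-scale value. Posterior means estimated from a
$10^3$-step raw chain carry a Monte Carlo error of a few hundredths in the
radius components (the chains are short relative to their autocorrelation
time); the long-run moments are stable, as an 8000-step diffusion-posterior
chain confirms.

## Known limitations

* The forward transport discretisation is not asymptotic-preserving (see
  above); the package documents, rather than hides, the consequences.
* Delta sources violate the boundary smoothness under which the
  transport-to-diffusion convergence of the measurement maps is proved;
  entries at and next to the source node are the noisiest part of the gap.
* At $\varepsilon = 1$ the diffusion surrogate is a poor filter: the
  posteriors are far apart and the second-stage rate is near zero. This is
  the expected failure mode of delayed acceptance outside the surrogate's
  validity regime, and the rate ladder in the tests shows it directly.
* Scattering is isotropic and absorption-free by scope; anisotropic
  kernels and absorption are not modelled.
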