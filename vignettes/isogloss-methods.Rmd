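---
title: "Surface-tension dynamics of dialect boundaries: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface-tension dynamics of dialect boundaries: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isogloss)
```

## The model

The package tracks the spatial usage of a binary linguistic variable
(variants A and B) over a population landscape. Each location carries a
*memory* field $m(\mathbf r, t) \in [0,1]$, the exponentially weighted
historical average (timescale $\tau$, the unit of time throughout) of the
frequency of variant A that speakers there have heard. Current usage is
the conformity map

$$f = p(m) = \frac{m^{\alpha\beta}}{m^{\alpha\beta} + (1-m^\alpha)^\beta},$$

where $\beta \ge 1$ measures conformity to the local majority and
$\alpha$ an inherent bias between the variants ($\alpha = 1$: none;
$\alpha > 1$ disfavours A). What speakers hear is the *spatial average*
$\bar f$ of $f$ under a two-kernel interaction density: a short-range
Gaussian of scale $\sigma$ between ordinary speakers and a long-range
Lorentzian (Cauchy) of scale $\gamma$ between *metropolitan* speakers,
each weighted by the population density $\rho$ of the listened-to
location and normalized per listener. Memory then relaxes as
$\dot m = \bar f - m$.

An *isogloss* is the level set $f = 1/2$: crossing it changes the locally
modal variant. For $\beta > 1$ isoglosses feel surface tension and the
system coarsens; the Lorentzian term reproduces the gravity law of
long-range social contact (inter-city weight $\propto P_1 P_2 / r^2$),
which lets a variant jump between city cores before spreading as a wave —
hierarchical diffusion on top of wave-like spread.

Three reductions of the full nonlocal equation are implemented, each with
its own module:

* **Local reduction** (`stepLocal`): where $\rho$ varies slowly on the
  scale $\sigma$, the nonlocal average reduces to
  $\dot m = f - m + \tfrac{\sigma^2}{2}\nabla^2(\rho f)/\rho$.
* **City-network ODEs** (`simulateCityOdes`): cities reduced to point
  cores of population $P_i$ coupled by gravity weights
  $P_j / (1 + r_{ij}^2/\gamma^2)$, row-normalized. Exact in the limit
  $\sigma \to 0$, $\gamma \to \infty$.
* **Agent lattice** (`sampleLattice`, `simulateAgents`): one speaker per
  occupied site of an integer lattice, linked by an embedded random
  network with Gaussian link probability; adds stochastic population
  mixing (memory swaps at rate $\epsilon$) and immigration (memory
  resets at rate $\nu$).

## Isogloss velocity laws

A front of the local dynamics moves with normal velocity

$$v = -\frac{\sigma^2}{\beta}\left(\frac{\kappa}{2} +
  \frac{\nabla\rho\cdot\hat{\mathbf g}}{\rho}\right) - v_{\text{bias}},$$

with $\kappa$ the signed curvature (positive bowing into the A-domain)
and $\hat{\mathbf g}$ the outward normal of the A-domain: curvature
shrinks domains, population gradients push isoglosses downhill, and
inherent bias $\alpha > 1$ pushes against A. For weak conformity the
stationary front has frequency slope
$|f'| = \sqrt{(4\ln 2 - 1)(\beta-1)/6}\,/\,\sigma$, and expanding the
travelling-wave balance to linear order in $(\alpha - 1)$ gives
$v_{\text{bias}} \approx 0.6376\,\beta^2\sigma(\alpha-1)/\sqrt{\beta-1}$.
The dimensionless constant is computed at run time from the derivative of
the conformity map at $m = 1/2$ combined with $|f'|$
(`biasVelocityCoefficient`), not hard-coded; it evaluates to
$\ln 2 / (2\sqrt{(4\ln 2 - 1)/6}) = 0.63763$.

`biasVelocity` offers two routes. The `"linear"` route is the printed
linear-response coefficient above. The `"expansion"` route evaluates the
travelling-wave balance at the actual $\alpha$, keeping the finite
offset $p(1/2) - 1/2$ and the curvature $p''(1/2)$ of the conformity map
at the isogloss. The two differ by a fixed fraction (about 7% at
$\beta = 1.1$) even as $\alpha \to 1$, because the $p''$ term is itself
linear in $(\alpha - 1)$. `stableRadius` defaults to the expansion
route, which tracks the simulated equilibria more closely (see below).

### The stable-radius worked example

The headline check of the velocity law is a city
$\rho(r) = \omega e^{-r^2/R^2} + \rho_0$ with $R = 30\sqrt 2$,
$\omega/\rho_0 = 2$, $\sigma = 5$, $\beta = 1.1$. A pure Gaussian city
(no background) admits **no stable radius**: its log-density gradient
$2r/R^2$ grows with $r$, so the balance point is repelling. With the
constant background the gradient force decays beyond the city and a
stable circular isogloss exists. Without bias the analytic balance gives
radius 75.19; with $\alpha = 1.01$ the expansion route gives 62.6 and
the full nonlocal simulation equilibrates at 63.8 (grid $\sigma/2$,
121×121 cells, disc initial condition). The local reduction is *not*
reliable for this configuration: the front width
$\sigma/\sqrt{\beta-1} \approx 16$ is comparable to the city scale, and
its equilibrium radius overshoots by roughly 20%. The package therefore
reports the simulated radius from the nonlocal dynamics and provides
both analytic bias routes.

### Validity of the thin-interface law

The curvature law $v = -\sigma^2\kappa/(2\beta)$ is a weak-conformity
(β → 1) asymptotic. Measured shrink rates of circular domains exceed it
by a factor $\approx 1 + 1.65(\beta - 1)$ (e.g. 2.9× at $\beta = 2$),
because the exact front-profile weighting of $p'$ enters the effective
mobility. The shrink-rate agreement test therefore runs at
$\beta = 1.04$, where the combined weak-conformity and finite-width
corrections stay below 10% for radii of 5–20 interaction lengths.
Similarly, the local and nonlocal equilibrium radii agree only when the
front is thin relative to the density scale: their gap decreases
monotonically as the front sharpens (9.4% at $\beta = 1.2$ to 5.0% at
$\beta = 2$ on the test configuration) and the nonlocal equilibrium
matches the analytic balance to well under 1%.

## Numerical choices

* **Discretization.** Fields live on a regular square grid with cell
  area $h^2$; masked sums replace integrals. The default cell size is at
  most $\sigma/2$, resolving the $O(\sigma)$ front width.
* **Operator application.** The interaction operator is applied by FFT
  convolution (padded for closed boundaries, minimum-image for periodic
  ones), so a 200×200 landscape costs a handful of FFTs per step; the
  dense row-stochastic matrix (`denseWeights`) is kept for small grids
  and as a brute-force oracle. The Gaussian kernel is truncated at
  $5\sigma$ (error < 1e-5); the Lorentzian is never truncated. Closed
  coastlines are implemented as zero density off land plus per-row
  renormalization, which is what makes stable isoglosses meet coasts at
  right angles.
* **Time stepping.** Forward Euler. The nonlocal update is a convex
  relaxation toward $\bar f \in [0,1]$, hence unconditionally stable and
  bounded for $dt \le 1$; equilibria are fixed points of $\bar f = m$
  and therefore independent of $dt$, so equilibrium runs may use
  $dt = 0.5$. The local (Laplacian) step needs
  $dt \lesssim h^2/(2\sigma^2\beta)$; its default is $dt = 0.1$ with a
  [0,1] clip guarding round-off. Equilibrium is declared when
  $\max|\dot m| < 10^{-6}$ for 10 consecutive steps; hitting the time
  cap flags the run as non-converged rather than erroring.
* **Contours.** Isoglosses are extracted by marching squares with linear
  interpolation (`grDevices::contourLines`); contours are closed when
  their endpoints coincide; discrete curvature uses central differences
  with the sign fixed by which side of the contour is A-modal. The modal
  variant of a cell is A iff $f \ge 1/2$ (ties to A).
* **ODE integration.** City networks and the mean-field equation use a
  classical fixed-step 4th-order Runge–Kutta scheme (`deSolve`),
  cross-checked against a fine forward-Euler oracle.
* **Stochastic scheme.** Mixing and immigration are Bernoulli-thinned
  per step (probabilities $\epsilon\,dt$, $\nu\,dt$), an $O(dt)$
  approximation of the continuous-time rates. Mixing swaps are applied
  sequentially as exchanges, conserving the multiset of memories
  exactly. Isolated speakers (no network neighbours) relax toward their
  own $p(m)$. Each experiment draws occupancy, network, and event
  randomness under separate seeds so components are independently
  reproducible.
* **Label alignment.** Map overlap (OL, and population-weighted WOL)
  maximizes agreement over label assignments via maximum-weight
  bipartite matching (`igraph`), verified against brute-force
  permutation search on small label sets.
* **Ward clustering.** `hclust(method = "ward.D2")` on Euclidean
  distances between the binary modal vectors; merge ties are resolved by
  `hclust`'s ordering, which only matters on degenerate fixtures.

## The synthetic-data generator

`makeFixture` reproduces the standard experiment configurations: the
four-city hierarchical-diffusion landscape (large cities
$\omega = R = 10$, satellites $\omega = R = 5$, hinterland radius $5R$,
$\sigma = 2\sqrt2$, $\gamma = 25$, $\beta = 1.1$), the line of 20 cities
(spacing 50, $P_1 = 30$, $P_{i>1} = 5$, $\gamma = 25$), the two-lobed
coastline (lobe diameter 80, $\omega = 10$, $R = 10$, $\sigma = 4$), the
400×400 two-city stochastic geographies (radii 100/100 with a mixing
ramp $\epsilon(t) = 5\times10^{-4} t$ at $\beta = 1.1$, and 100/50 with
fixed $\epsilon = 0.1$ at $\beta = 2$; background occupancy 0.1,
$\sigma = 3$), an island with sector-shaped domains, and a randomized
archipelago for regionalization tests. City positions for the four-city
landscape are the package's own choice (the configuration is specified
only up to sizes): the source and the second large city sit on opposite
corners (separation ≈ 212, far enough that the distant city's inbound
gravity weight stays below the adoption threshold of the ODE reduction)
with the two satellites near the source. Fixture parameters are recorded
verbatim in a serializable manifest, and every randomized component is
reproducible from the fixture seed.

The generator emulates gridded population landscapes, not real
geography: real census rasters have heavy-tailed density, anisotropic
coastlines, and correlated settlement patterns that these Gaussian
cities do not. Passing tests therefore demonstrate the mechanics of the
model and pipeline — coarsening, hierarchical diffusion, extinction
thresholds, regionalization — on controlled landscapes, not predictive
accuracy for any real dialect atlas, whose reproduction additionally
requires external population and dialect-map data that the package does
not bundle.

## Test problem sizes

The test-suite and acceptance computations are sized for a single CPU:
equilibrium worked-example runs use a 121×121 grid at cell $\sigma/2$
covering 302×302 length units; shrink-rate measurements use up to
160×160 cells; the fully connected mean-field comparison uses 2025
agents and 10 seeds; stochastic-geography experiments run on 120×120
lattices with the caption parameters scaled to a quarter of the printed
400×400 system (radii scaled with the domain). The mean-field
consistency check runs at $\beta = 1.02$, $\nu = 0.05$, $dt = 0.05$: the
mean-field replacement $\overline{p(m)} \to p(\bar m)$ is exact only for
a linear usage map, and for stronger conformity the immigrant-induced
spread of memories produces a systematic (Jensen) gap that no amount of
averaging removes, so the quantitative comparison belongs in the weakly
nonlinear regime; stronger conformity is exercised qualitatively through
the extinction-threshold experiments at $\beta = 1.5$.

## Known limitations

* The travel distance is Euclidean; there is no road/terrain metric and
  no time-varying population.
* The $\beta$-dependence of the printed curvature and bias coefficients
  is leading-order in $\beta - 1$; quantitative use at $\beta \gtrsim
  1.2$ should rely on the simulation routes.
* The local reduction requires the front width to be small against the
  density scale; the package does not switch automatically — choose the
  nonlocal dynamics when in doubt.
* No automatic choice of the number of dialect clusters: `nC` is a user
  input, normally the reference map's count.
* The agent model's mixing is memory exchange between fixed home sites;
  speakers do not relocate, and demographic turnover beyond the
  immigration rule is not modelled.
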