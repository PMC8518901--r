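---
title: "Models and methods behind dihi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dihi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models the package implements, the assumptions
behind them, the numerical choices that matter, and the places where the
design was genuinely open and a decision had to be made. It states no
numbers that the test suite or `scripts/acceptance.R` do not themselves
compute.

## The question

After a first epidemic wave and a lockdown of fixed duration, is the
residual susceptible population below the threshold that can sustain a
second wave? The cumulative infected fraction at the end of the lockdown
in the *best* such intervention — best meaning the final epidemic size is
minimised subject to the post-lift epidemic being subcritical — is the
disease-induced herd immunity level (DIHI). In a homogeneous SIR model this
is the classical `1 - 1/R0`; in structured populations the first wave
preferentially immunises high-contact individuals, and DIHI can be
substantially lower. The package provides four mean-field models resolving
different structure, one shared lockdown-experiment layer, and a stochastic
simulator on explicit networks used to validate the most intricate of the
mean-field constructions.

## Contact structure

Degree distributions are shifted, truncated negative binomials
`P(k) ∝ C(k - m + n - 1, n - 1) p^n (1-p)^(k-m)` for `k = m..M`. At fixed
mean the free parameter tunes the variance, which is the axis along which
degree heterogeneity is explored. Three named configurations ship with the
package (delta-like `n=1, p=0.99, m=9`; normal-like `n=3.86, p=0.31, m=1`;
scale-free-like `n=1.07, p=0.107, m=1`, all with `tau = 0.016`/day); their
`(n, p, m)` values are authoritative and their nominal mean/variance labels
are approximate (the delta-like mean is 9.0101, not 10). Truncation: `M` is
the smallest degree with upper-tail mass below `1e-9` (capped at 2000), so
truncation error is far below integrator tolerances; moments are computed
from the truncated pmf by direct summation.

Age-structured mixing is a set of four square per-capita contact
components (home, school, work, other; entry (i, j) = mean daily contacts
of an individual of group i with group j) plus a population vector.
`equalize()` removes the two confounders of scenario comparisons —
demography and per-component contact volume — by uniformising populations
and rescaling every component to a common sum (by default that of the
*other* component).

### The synthetic mixing fixture

`synthetic_mixing_components()` emulates the qualitative anatomy of
empirical contact-diary matrices: home, school and other are assortative
(diagonally dominant kernels `exp(-a|i-j|/w)`), school contacts are
confined to the four youngest bands, and work is an approximately constant
plateau over the working-age bands; populations are mildly heterogeneous.
It is deterministic given a seed, and `assortativity_strength = 0`
degrades every component to (noisy) uniform. It does **not** emulate
inter-generational off-diagonals of home contacts, reciprocity corrections,
or any country's absolute contact rates — so tests that pass on the fixture
demonstrate that the *machinery* and the *qualitative orderings* behave
correctly, not that any country-specific number is reproduced. Reproducing
published scenario R0s requires the published UK components (see README).

## The four models

**Degree-based mean field (annealed closure).** Expected counts per degree
class; the infection pressure on a degree-k susceptible is `tau k pi_I`
with `pi_I` the degree-weighted prevalence. The denominator of `pi_I` is
the initial stub count, fixed along the trajectory (class sizes are
constant in SIR). Exact on networks whose partners are re-drawn faster than
the epidemic ("annealed"); an upper envelope on real networks because it
ignores pair correlations.

**Heterogeneous pairwise with clustering.** Adds ordered-pair edge counts
`[A_k B_l]`; triples are closed through the centre node. The closure's
clustered (triangle) term admits two readings, both implemented behind
`pairwise_model(closure=)`:

* `"printed"` — `phi * [AB][BC][CA] / ([A][B][C])`, weighted `(1-phi)` /
  `phi` against the standard term. As a count this term is O(1) in the
  population size while the unclustered term is O(N), so at realistic N the
  weighting acts essentially as a `(1-phi)` damping of transmission through
  triples.
* `"normalized"` (default) — the triangle correction in ratio form: the
  standard closure `[AB][BC]/[B]` multiplied by
  `(1-phi) + phi [CA]/E[CA]`, where
  `E[CA] = d_A d_C [A][C] / (<k> N)` is the closing pair's expectation
  under proportional mixing. This is the Keeling-style clustered closure
  generalised to degree classes; it is dimensionally consistent (triples
  scale with N) and equals the printed form when the correction ratio is 1.

Under the normalised reading, clustering lowers and delays the epidemic
peak and reduces the final size, with the effect saturating between
`phi = 0.25` and `0.5` at high degree variance; under the printed reading
the damping is much stronger and the final size can *increase* with `phi`
because the slower epidemic burns more completely. The test suite pins both
kernels against brute-force triple-sum oracles; the qualitative
clustered-epidemic properties are asserted for the default reading. This
divergence between the two readings is a known limitation to keep in mind
when comparing against other clustered-closure implementations.

`phi = 0` recovers the standard unclustered heterogeneous pairwise model,
and a single degree class recovers the classical five-equation homogeneous
pairwise SIR (both tested against independent implementations).

**Household EBCM.** Households of size 4 with complete internal mixing at
per-pair rate `beta_h`/day; community contacts drawn from a degree
distribution and wired by the configuration model, transmitting at
`beta_c`/day; recovery at `gamma`/day. The construction is a cavity
(test-node) argument: `theta(t)` is the probability a random community
partner has not yet transmitted to the test individual, with the usual
Volz-style flow `theta' = -beta_c Phi_I`, where `Phi_I` is the probability
that partner is infectious and the edge intact; the household enters
through a 10-state master equation `f(s, i)` — the joint probability that
the test individual's three housemates have `s` susceptible and `i`
infected members *and* none has yet transmitted to the test individual.
Housemates acquire community infection at the pgf-averaged hazard
`beta_c Phi_I psi'(theta)/psi(theta)`. The test individual is susceptible
with probability `S = (1-rho) psi(theta) h`, `h = sum f`. Two properties
anchor the construction: with no community contacts it is *exact* for
isolated 4-person households (verified against exact continuous-time
enumeration), and with households and community combined it reproduces the
stochastic simulation's final size within Monte Carlo error (below). The
approximation it does make is using the degree-averaged community hazard
for housemates rather than tracking their degrees jointly with the
household state. Initial conditions: a fraction `rho = 1e-4` infected
uniformly at random (configurable). Intervention targets: `global` scales
both rates; `community_only` scales `beta_c` alone. Shipped configurations
keep `beta_h/beta_c` in the band [3, 5] and warn outside it.

**Age-structured SEIRD.** Standard force of infection
`beta * S_i * sum_j C_ij I_j / N_j` with age-independent `beta`
(calibrated exactly, by linearity, so the baseline R0 is a target value —
2.5 in the shipped experiments), `gamma_E = 1/7`/day (inverse incubation),
`gamma_I = 1/14`/day (inverse disease duration), and age-specific mortality
probabilities `m_i` that split the I-exit flow into R and D. Mortality does
not feed back into transmission; the packaged `default_mortality()` profile
is an explicitly user-replaceable placeholder (a logistic-in-age curve),
because any substantive mortality analysis should supply externally
sourced rates. Seeding: 100 exposed spread proportionally to group sizes,
configurable. Scenario windows switch the mixing matrix discontinuously
(instantaneous lockdown convention). The "social distancing" block in the
combined school scenario halves the *other*-component contacts on the
first-four-by-first-four block only — the narrow reading of "contacts at
other locations between school-going individuals", since both endpoints
are named.

## Reproduction numbers

* Degree-based mean field: `R0 = tau <k^2> / (gamma <k>)`.
* Pairwise: `R0 = tau/(tau+gamma) * (<k^2> - <k>)/<k>`.
* Household EBCM: leading eigenvalue of the 4x4 generation matrix with
  community factors `mu~_c = beta_c/(beta_c+gamma) E[D~]`,
  `mu_c = beta_c/(beta_c+gamma) E[D]`, and household generation sizes
  `mu_0..mu_3`. `E[D~]` is the mean *excess* degree `<k^2>/<k> - 1` (the
  left-over edges of a node reached along a random edge) — chosen over the
  size-biased mean `<k^2>/<k>` because the quantity describes the
  remaining edges after arrival. The `mu_g` come from exact enumeration of
  the generation-based (Reed–Frost) household epidemic with per-pair escape
  probability `phi_I = gamma/(beta_h + gamma)`; enumeration over the
  ≤4-person outcome tree is unambiguous and is cross-checked against a
  chain-binomial Monte Carlo with a million replicates.
* Age model: leading eigenvalue of `(beta/gamma_I) K`,
  `K_ij = (N_i/N_j) C_ij` (linearisation about the fully susceptible
  state). Matched uniform scalings are exact R0 ratios by linearity.

Leading eigenvalues are computed densely; for these nonnegative matrices
the spectral radius is attained by a real eigenvalue (Perron–Frobenius),
so the maximum real part is returned.

## The lockdown experiment layer

A policy is one lockdown window: a trigger (cumulative-incidence fraction,
located by root-finding on the integrated trajectory, not grid snapping; or
a fixed start day), a duration in days, a strength `alpha ∈ [0, 1]`, and a
target. "Cumulative incidence" counts ever-infected (I+R, plus E and D
where present); the prevalence-threshold trigger used in the variance-scan
protocol (`I + R >= 0.025`) is read as a fraction of N.

**Second-wave detection** is prevalence-based and model-agnostic: a run has
a second wave iff post-lift prevalence exceeds the prevalence at lifting by
more than a relative tolerance (`1e-6`); equivalently, the post-lift
epidemic is subcritical iff prevalence is non-increasing after lifting. An
R-effective diagnostic on residual susceptibles would be model-specific and
is deliberately not the criterion.

**Optimal alpha**: a coarse grid (step 0.05 over [0, 1]) is evaluated
first; among subcritical runs the final-size minimiser is selected and the
subcriticality boundary just below it is refined by bisection to `1e-3`.
The coarse step suffices because final size is smooth in `alpha` away from
the boundary and the minimum sits at the boundary, which the bisection
recovers regardless of the coarse resolution; every evaluation is retained
in the scan table, so the unimodality of the response is inspected, not
assumed. When no grid point is subcritical the unconstrained minimum is
reported and flagged (the short-lockdown regime).

**Horizons.** After lifting, integration continues to at least the greater
of three pre-lockdown durations and ten mean infectious periods, then
extends adaptively until prevalence is below `1e-9 N` *and* falling.
Deterministic compartmental trajectories never reach zero; prevalence
below `1e-9 N` — well under a hundredth of an individual at the default
population size of 6.65 million — is treated as extinction, which is also
what would happen in any finite population. A consequence worth knowing:
a sufficiently long, sufficiently strong intervention can legitimately
eradicate the epidemic in this semantics, ending the run below the herd
immunity threshold with no second wave.

## Numerical choices

* **Integrators**: `deSolve::lsoda` (HMF, EBCM, SEIRD; rtol `1e-8`–`1e-10`)
  and the non-stiff Adams method for the pairwise system, whose dimension
  (3M + 3M² and optionally 6M²) makes Jacobian-based stiff solvers
  impractical and whose dynamics are only mildly stiff.
* **Pairwise class reduction**: the truncated support is pruned of classes
  below `1e-9` mass and collapsed to ~48 classes (exact degrees up to 30,
  log-spaced tail bins represented by their mass-weighted mean degree).
  Binning preserves total mass and the mean exactly; the DIHI of the
  highest-variance scan cell changes by less than `1e-4` when the class
  count is increased to 70 (tested as second-moment convergence).
* **Closure regularisation**: inside the pairwise closure every count is
  clamped at zero, susceptible-class denominators use the floored inverse
  `1/max(S, eps)` and infected/recovered denominators the smooth inverse
  `D/(D² + eps²)`, with `eps = 1e-9 N`. The floor keeps the
  pair-destruction terms active while a class burns out (so pair counts
  cannot outlive their nodes — without this the tail classes overshoot
  negative and stall the integrator); the smooth form suppresses terms
  whose numerators vanish with the compartment instead of amplifying
  rounding noise by `1/eps`. Completed-epidemic outcomes are insensitive
  to `eps` across two decades (tested).
* **Degenerate inputs**: empty mixing components are rejected by
  `equalize`; a zero community degree reduces the EBCM to isolated
  households; degree-1 centres close no triples; an unreachable trigger is
  reported as a no-lockdown run rather than an error.
* **Determinism**: the stochastic oracle consumes R's RNG stream (so
  `set.seed` makes runs bitwise reproducible) in documented order; network
  cleanup discards rather than rewires self-loops and multi-edges (an
  O(1/N) bias, kept for determinism). Oracle comparisons condition on
  major outbreaks (final size at least five times the seed count), since
  mean-field models describe major outbreaks.

## Study conditions of the shipped experiments

The variance-scan protocol uses mean degree 6 (shift-1 negative
binomials), `tau = 0.04`/day, `gamma = 1/14`/day, a 100-day lockdown
triggered at 2.5% cumulative incidence, clustering coefficients
{0, 0.25, 0.5}, and variances {7, 12, 20, 33, 55, 90} — log-spaced from
near-Poisson to strongly heterogeneous, the regime in which the first wave
is concentrated on high-degree nodes. Seeding places 5 infected in the
degree-10 class. The household experiments use community mean degree 4
with variance 7.5, `beta_h = 0.045`, `beta_c = 0.015`, `gamma = 1/14`, and
5000 households (20 000 individuals) with 50 replicates in the oracle
comparison — sizes at which the full scan and the oracle run in minutes on
one CPU while Monte Carlo error stays small enough for three-standard-error
checks to be meaningful.

## Known limitations

* The pairwise model fixes proportional (degree-weighted) mixing at t = 0
  and has no degree–degree assortativity or rewiring; the two closure
  readings diverge at high clustering (above).
* The EBCM averages the community hazard over housemates' degrees; its
  household size is fixed at 4.
* The stochastic simulator targets correctness, not performance beyond
  ~10^5 nodes.
* Deterministic trajectories cannot represent fluctuation-driven extinction
  or resurgence near the extinction threshold; conclusions within an order
  of magnitude of `1e-9 N` prevalence are artefacts of the cutoff
  convention.
* Mixing matrices are used as published (per-capita, no reciprocity
  correction), and mortality never feeds back into transmission.
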