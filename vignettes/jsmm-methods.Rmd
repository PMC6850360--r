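---
title: "Methods: the joint species movement model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the joint species movement model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jsmm)
```

## The model and its assumptions

Movement studies that cover many species usually face severely unbalanced
data: a handful of common species with hundreds of observed movements, and a
long tail of species seen a few times. Fitting each species separately
wastes the commonality between species; pooling them ignores real
differences. `jsmm` takes the hierarchical middle road: each species keeps
its own movement parameters, but those parameters are draws from a
community-level distribution structured by traits and phylogeny.

Writing `Θ` for the `n_s × n_p` matrix of transformed species parameters
(rows are species), the community layer is the matrix normal

$$\mathrm{vec}(\Theta) \sim N\!\big(\mathrm{vec}(TZ),\;
\Sigma \otimes W\big), \qquad W = \rho C + (1-\rho) I .$$

The assumptions this encodes:

- **Linearity in traits.** The expectation of each transformed parameter is
  a linear combination of the trait design columns. Nonlinear responses are
  not modelled (they can be approximated by adding transformed trait
  columns).
- **Transformability to the real line.** Each movement parameter has a fixed
  transformation (`log` for positive rates and lengths, `logit` for
  probabilities, identity otherwise) under which a normal residual is
  plausible.
- **Separable covariance.** Residual dependence factorises into a
  species part (`W`) and a parameter part (`Σ`). The phylogenetic weight
  `ρ` interpolates between independent species (`ρ = 0`) and fully
  phylogenetically structured residuals (`ρ = 1`); under a Brownian model of
  trait evolution the entries of `C` are the proportions of shared
  evolutionary history, which is how `phylo_correlation()` computes them
  from an ultrametric tree. Taxonomies become trees with four equal-length
  levels (`taxonomy_tree()`), giving correlations 0.75/0.5/0.25/0 for
  congeners down to different families.

The vectorisation convention is column-major — species index varies fastest
within each parameter block — so `W` acts on species. All density
evaluations and prior draws use the eigendecompositions of `C` (done once)
and `Σ`, at cost `O(n_s^3 + n_p^3)`; the `n_s n_p` dense covariance is never
formed, and the identity `W(ρ) = U(\rho Λ + (1-\rho) I)U'` makes the grid
sweep over `ρ` essentially free.

Non-ultrametric trees are rejected rather than rescaled: the proportion of
shared history is not well defined when tips sit at different depths, and
silently normalising would change the model. Eigenvalues of `C` are floored
at `1e-12` before mixing because taxonomic trees with tied species produce
exactly singular matrices.

## Priors and the sampler

The per-species likelihood is a plug-in (`new_jsmm_likelihood()`); the
sampler only requires `log p(y_s | Θ_{s\cdot})`. One iteration cycles:

1. **`Θ` rows, Metropolis.** Each species' row receives a Gaussian
   random-walk proposal and is accepted with the usual ratio, combining the
   species log-likelihood with the *conditional* of the community prior for
   that row given all other rows (available in closed form from the
   Kronecker precision: mean `M_{s\cdot} - \sum_{s'\neq s} W^{-1}_{ss'}(\Theta-M)_{s'\cdot}/W^{-1}_{ss}`,
   covariance `Σ / W^{-1}_{ss}`). Proposal scales adapt towards an
   acceptance rate of 0.25 during burn-in only (Robbins–Monro on the log
   scale, plus an empirical diagonal covariance once enough history exists),
   so the post-burn-in chain is a fixed Markov kernel.
2. **`Z`, exact Gibbs.** With prior `ζ_{kp} ~ N(0, σ_ζ^2)` the full
   conditional is the Bayesian generalised-least-squares regression of `Θ`
   on `T` with error covariance `Σ ⊗ W`; a dense draw in the small
   `n_t n_p` dimension.
3. **`Σ`, exact Gibbs.** Inverse-Wishart conjugacy:
   `Σ | · ~ IW(ν_0 + n_s, Ψ_0 + R' W^{-1} R)` with `R = Θ − TZ`.
4. **`ρ`, grid Gibbs.** The conditional density is evaluated on an
   equispaced grid over `[0, 1]` and one point is drawn by inverse CDF,
   with ties broken by the accumulation order.

Default priors — chosen by this package, weakly informative and conjugate
where possible, all overridable through `jsmm_prior()`:
`ζ_{kp} ~ N(0, 10)`; `Σ ~ IW(n_p + 2, I)` (prior mean `I`);
`ρ` uniform on a 101-point grid. Because the grid prior is discrete,
"`Pr(ρ > 0)`" is reported as `1 − Pr(ρ = 0)`, alongside the better-behaved
`Pr(ρ > 0.5)` and the posterior mean.

Initialisation: `Θ` rows at a ridge-stabilised per-species maximum
likelihood (prior mean if optimisation fails), `Z` by least squares from the
initial `Θ`, `Σ = I`, `ρ` at the grid point nearest 0.5. Chains are seeded
`seed + chain − 1` and runs are bit-reproducible.

The conditionals were validated two ways: `update_z_gibbs` against a dense
conditional mean/covariance oracle, and all three Gibbs updates by the
successive-conditional (Geweke-style) simulator — alternating exact prior
redraws of `Θ` with one conditional update must leave the prior invariant,
which is checked by rank tests against direct prior draws. That test uses a
loading prior variance of 1: with the very diffuse default the
successive chain for `Z` mixes so slowly (effective sample size ~1/150 per
iteration) that rank tests receive strongly dependent draws; the code paths
exercised are identical.

## The redistribution likelihood

One observed step from cell `i` lands in cell `j` with probability
proportional to `exp(−d_{ij}/α_s)\,e^{β_{s1} h_{j1}}\,e^{β_{s2} h_{j2}}`,
normalised over **all** grid cells, including `j = i` at distance zero — a
bird may resettle within its current cell, and no truncation radius is
applied. Distances are Euclidean between cell centres; open habitat is the
reference class; there is no temporal component (the data are ordered steps,
not timed fixes). Track log-likelihoods are sums of log single-step
probabilities; per species the implementation caches the distance matrix
from that species' observed origin cells to all cells, so one likelihood
evaluation is a single vectorised exponential plus a matrix–vector product.

## The diffusion capture–recapture likelihood

Movement is modelled as diffusion with coefficient `D` (m²/day) plus
edge-mediated habitat selection: the stationary density is `k` times higher
in open than in forest habitat. The solver discretises this on the landscape
grid as a continuous-time jump process between 4-neighbour cells with rates
`(D/h^2)\,2w(b)/(w(a)+w(b))` (`w = k` in open cells, `1` in forest; harmonic
weighting makes the stationary density exactly proportional to `w`),
reflecting boundary, and mortality `m` draining every cell. Movement and
mortality rates are the same in both habitats; semi-open cells are mapped to
forest by default (the moth model distinguishes forest from open only). This
regular-grid finite-volume scheme replaces a finite-element solution on a
triangulated landscape: it is equivalent in the diffusion limit, far simpler
to test, and its two continuum limits (mean squared displacement `4Dt`;
stationary open:forest ratio `k`) are verified in the test suite.

Propagation over a night uses uniformisation — the matrix exponential as a
Poisson mixture of powers of `I + Q/Λ`, truncated at a `1e-14` tail — which
is exact to truncation error and preserves nonnegativity.

The observation layer: each active trap, each night, captures the
individuals inside a 30 m attraction radius with probability `q_s`.
Radius and efficiency are not separately identifiable, so the radius is
fixed and `q_s` estimated (on the logit scale). Overlapping attraction
zones are partitioned by nearest *active* trap, ties to the lower trap
index, so capture mass is never double-counted. A capture history
alternates one-day propagation with an instantaneous nightly capture
operator; each observed recapture contributes the log of its capture
probability and resets the density to a point mass at the trap (animals are
re-released where caught); the interval after the last observation
contributes `log(1 − Σ capture probabilities)`. On enumerable instances the
probabilities of all possible histories sum to one to `1e-8`, which the
tests exploit.

## The synthetic-data generator

`generate_dataset()` draws a complete study from the model's own generative
process, which is what the recovery tests require:

- **Landscape**: random forest disks on an open matrix until the forest
  fraction reaches its target (default 0.4, matching a fragmented
  forest–pasture mosaic), then scattered semi-open cells (default 0.1).
- **Community**: standardised continuous traits and a categorical trait
  drawn at random; a phylogeny of configurable shape (random coalescent by
  default, balanced, or a random four-level taxonomy); `Θ` drawn exactly
  from the community prior at the scenario's true `Z`, `Σ`, `ρ`.
- **Data**: tracks simulated step by step from the redistribution kernel,
  or a full capture–recapture study simulated as the jump process with
  nightly trapping (alternating halves of a trap grid active on odd/even
  nights, as in a paired-night field design).

Default scenario sizes follow the direct-observation case the model was
built around: 40 species, a 60 × 60 grid of 10 m cells, ~15 observed steps
per species (5 tracks × 3 steps), one continuous and one two-level
categorical trait, intercepts at field-typical values (25 m step length;
positive affinity to wooded habitat), residual standard deviation 0.5 per
transformed parameter, and `ρ = 0.5`. The diffusion default uses
`D = 2000` m²/d, `k = 1`, `m = 0.1`/d, `q = 0.3` on a 25 m grid. What the
generator does **not** emulate: real landscape geometry (roads, patch shape
autocorrelation), observation error in locations, temporal structure within
tracks, and trait measurement error — so passing recovery tests demonstrate
correctness of the inference machinery under the model, not robustness to
model misspecification on field data.

## Numerical choices and simulation sizes

- Eigenvalue floor `1e-12` on `C`; `Σ` draws symmetrised after each
  inverse-Wishart draw; Cholesky-based conditional densities throughout.
- `ρ` grid of 101 points; categorical draw by inverse CDF on accumulated
  normalised weights.
- `duration = 0` propagation returns its input bit-exactly; negative
  densities beyond `−1e-12` abort.
- The built-in recovery study runs 3 replicates of 40 species with 2 chains
  × 2000 iterations (600 burn-in), a size at which split-R̂ for this model
  is ≤ 1.1 and the full study completes in minutes on one CPU; per-replicate
  posterior means of `ρ` at a true value of 0 scatter around 0.2–0.3
  (a bounded parameter's posterior mean is biased away from its boundary),
  so recovery of `ρ` is judged on the replicate average, the usual bias
  measure in simulation studies.
- The single-species baseline used in the shrinkage comparison is a
  separately coded adaptive random-walk Metropolis sampler with independent
  `N(0, 2.5^2)` priors on each transformed parameter — diffuse enough to be
  dominated by even a handful of steps, which is the relevant no-pooling
  reference.

## Known limitations

- The redistribution kernel normalises over the full grid each evaluation;
  for grids far larger than ~10⁴ cells a truncation radius or FFT-based
  convolution would be needed.
- The diffusion solver's accuracy is governed by the cell size; `h` should
  be small relative to the nightly diffusion length `\sqrt{4D}` and the
  trap radius. The 30 m attraction zone is resolved as the set of cells
  whose centres fall inside the circle.
- `ρ` is weakly identified unless the residual spread of `Θ` around `TZ` is
  well resolved for many species; with few species or very noisy
  per-species estimates its posterior stays close to the prior, and the
  reported `Pr(ρ > 0.5)` should be read accordingly.
- Tree uncertainty (posterior sets of phylogenies) is not propagated; `C`
  is computed from a single supplied tree.
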