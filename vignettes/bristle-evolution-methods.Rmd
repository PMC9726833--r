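---
title: "Models and methods for facial-bristle comparative analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for facial-bristle comparative analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models, the choices made
where the methodology was genuinely open, and what the synthetic-data
validation does and does not establish. It states no empirical result that
the test suite or `scripts/acceptance.R` does not itself compute.

## Character evolution: the Mk model

Presence/absence of a bristle region is a 2-state continuous-time Markov
chain running along a rooted, ultrametric, time-calibrated phylogeny
(branch lengths in millions of years). The instantaneous rate matrix `Q`
has non-negative off-diagonals and zero row sums, constrained as

* **ER** — one rate for every transition;
* **SYM** — one rate per unordered state pair (identical to ER for 2
  states, which is why those two rows of any binary-character comparison
  table coincide);
* **ARD** — one rate per ordered pair (for presence/absence: a gain rate
  and a loss rate).

The likelihood of tip data is computed by Felsenstein pruning
(`tip_likelihood()`), with per-edge transition probabilities `exp(Q t)` —
closed form for 2 states, eigendecomposition otherwise — and a root prior
`pi`. Partial likelihoods are rescaled whenever their maximum drops below
1e-4, so deep trees do not underflow.

**Root prior.** The default is equal weights over states, matching the
convention of the mapping tools this workflow descends from; a
stationary-distribution option is available (`pi = "stationary"`). Root
reconstructions — in particular root-state confidence — are conditional on
this choice.

**Optimisation.** `fit_mk()` maximises over log rates with L-BFGS-B
(bounds 1e-9 to 1e6 on the natural scale), from a heuristic start of
roughly one expected change on the tree plus 5 random restarts drawn from
a private RNG stream keyed by `seed` (the caller's RNG state is never
disturbed). On pathological data the ML sits on a boundary — a monomorphic
character has no interior optimum and is rejected outright
(`trait invariant`), and a 2-tip cherry is always boundary-optimal — so
tests compare achieved likelihoods, not boundary rates. AIC counts only
free rates (ER/SYM: 1 for binary; ARD: 2); the root prior carries no
parameters and is not counted.

**Model choice.** `compare_models()` turns AICs into Akaike weights
`exp(-Δ/2)` renormalised. A fingerprint of the data (tip states + edge
lengths) is stored on each fit and comparison refuses to mix fits made on
different data.

## Stochastic character mapping

`run_simmap()` samples full character histories conditional on the tip
data, with `Q` fixed at its ML estimate (the "empirical" approach —
resampling `Q` across maps is out of scope). Each map is drawn in two
stages:

1. **Node states** (`sample_node_states()`): the root is drawn
   proportionally to `pi_i * L_i` (partial likelihood), then each child
   pre-order from `P(parent_state -> j, t_edge) * L_child(j)`. On trees
   of up to 6 tips these draws are validated against exact marginals
   obtained by brute-force enumeration of all internal-state assignments.
2. **Branch histories** (`sample_branch_history()`): an exact
   endpoint-conditioned path by uniformization, with dominating rate
   `mu = max(-diag(Q))`. The number of candidate jumps is drawn from its
   endpoint-conditioned distribution (Poisson(mu t) weighted by powers of
   the jump-chain matrix), jump states from the conditioned jump chain,
   and virtual self-jumps are discarded. Uniformization was chosen over
   naive forward-rejection because rejection stalls when the endpoints
   differ on short branches; the rejection view survives as a test oracle
   (a fine-grid discrete-time conditioned simulation must reproduce the
   mean change count at 3 sigma).

Summaries (`summarize_maps()`) report mean changes, gains
(absent→present) and losses (present→absent) — "gain" is defined on the
presence character, `present_state` defaulting to the second state label
— mean time-in-state proportions, per-node posterior probabilities, and
the confidence of the modal root state. `density_map()` discretises each
edge into bins (default 100) and reports the fraction of maps in the
present state at each bin midpoint, exported as a table and as annotated
Newick with `[&state_prob=...]` edge comments.

## Phylogenetic signal for a binary character

Pagel's λ is defined here through the tree transform: internal branches
are multiplied by λ ∈ [0, 1] and each terminal branch is extended so all
root-to-tip depths are preserved (λ = 1 identity, λ = 0 star-like). The
classic λ estimator targets continuous traits; applying it to binary data
needs a discrete-coherent analogue, so `fit_lambda()` jointly maximises λ
and the Mk rate(s) (ER by default) on the transformed tree. Significance
is a likelihood-ratio test of λ̂ against λ = 0 with a χ²(1) reference.
Because λ = 0 sits on the parameter boundary this reference is
anticonservative; a 50:50 mixture reference (`p_reference = "mixture"`)
is provided. The optimiser profiles from three λ starts (0.99, 0.5, 0.1)
and falls back to the λ = 0 profile fit whenever that is not beaten, so
the invariant `loglik(λ̂) >= loglik(0)` holds by construction.

## Tree handling

Input trees (Newick or Nexus; quoted and underscore names normalised to
underscores) are repaired in the order: floor strictly negative branch
lengths at 1e-6 (consensus trees built by clade-age averaging can carry
small negative terminals), then coerce to ultrametric. Coercion refits
all edge lengths by non-negative least squares against the tree's own
patristic distances subject to equal tip depths (`phangorn::nnls.tree`,
the very method this workflow's lineage cites); a fast
`method = "extend"` mode only lengthens terminal edges. The root age is
the crown root-to-tip depth — whether the original workflow's utility
returned a crown or stem variant is not documented, so the crown reading
is implemented and flagged here. `phylo_correlation()` returns shared
path length divided by root age (unit diagonal), the correlation a
Brownian trait accrues, used by the mixed models.

## Sensitivity analyses

**Taxonomic downsampling.** Each family's sampling fraction is the number
of sampled species over the number known in that family. Species are
removed sequentially without replacement with probability proportional to
their family's fraction, so overrepresented families are thinned first;
the normalisation across remaining species is the simplest scheme
consistent with that idea (the source procedure states the weighting but
not the normalisation). Retention targets (90/80/70 %) apply to the
species count. Per subsample the tree is pruned, `Q` refitted (the subset
changes the data; a fixed-Q fast mode exists) and maps drawn; per-map
statistics are pooled across subsamples. Node posteriors other than the
root do not pool across differing tip sets and are dropped from pooled
summaries.

**Tree uncertainty.** Maps are pooled over trees sampled from a
posterior (or pseudo-posterior) set, refitting `Q` per tree; per-tree
root confidences are also reported so topology-induced dispersion is
visible. Alternative-topology hypotheses are handled generically by
supplying constraint trees; no clades are hard-coded.

## Phylogenetic mixed models

For specimen `i` of species `s(i)`:

```
liability/length_i = x_i' beta + u_s(i) + w_i + e_i
u ~ N(0, sig2_a C),  w ~ N(0, sig2_i I),  e ~ N(0, sig2_e I)
```

with `C` the species correlation from the unit-depth tree. The threshold
(probit) family observes `y_i = 1{liability_i > 0}` and fixes
`sig2_e = 1` for identification — the model family states the residual is
fixed without printing the constant, and 1 is the probit convention.
Priors: inverse-Gamma `IG(nu/2, nu V/2)` with `V = 1`, `nu = 0.002` on
every sampled variance; diffuse zero-mean normals (variance 1e10) on
fixed effects.

**Sampling.** A Gibbs sampler with conjugate updates. `beta` and `u` are
drawn as one joint Gaussian block: the intercept and the phylogenetic
effects are strongly correlated a posteriori, and one-at-a-time updates
mix them an order of magnitude more slowly at no saving in cost (the
block Cholesky is the same size as the `u` update alone). The threshold
family adds truncated-normal liability draws that always respect the
observation's sign. Chains are bit-reproducible given the master seed.

**Identifiability.** With unreplicated individuals (one measurement per
specimen — the common case, mirrored by the generator) the individual and
residual variances are confounded: only their sum is identified, and the
two chains correctly random-walk along that ridge. The sampler therefore
also records `var_units = var_individual + var_residual`; the convergence
gate (all PSRF < 1.1) covers the fixed effects, the phylogenetic variance
and this identified total, while the split's own PSRF values stay visible
in the summary table. For the threshold family the fixed residual makes
`var_units` duplicate the (prior-identified) individual variance, so it
is not gated there either.

**Deviance and DIC.** The recorded deviance is conditional on
`(beta, u, variances)` but marginal over the individual effects —
Gaussian: `N(x'beta + u, sig2_i + sig2_e)`; threshold:
`Phi((x'beta + u)/sqrt(1 + sig2_i))` — which keeps it off the unidentified
ridge. DIC uses the half-variance estimate of the effective parameter
count, `DIC = mean(D) + var(D)/2`. Backward elimination drops the least
significant factor (smallest coefficient-level pMCMC above 0.10,
factor-wise) and keeps the reduction only if DIC decreases; the source
procedure names "improved fit" without naming its criterion, and DIC is
the assumption made here. The intercept is never a candidate. pMCMC is
twice the smaller tail proportion, floored at 2/N so it is never exactly
zero.

**Diagnostics.** PSRF uses the classic formula
`sqrt(((n-1)/n W + B/n)/W)` without the small-sample df adjustment, so
identical chains give exactly `sqrt((n-1)/n)` ≈ 1; ESS wraps
`coda::effectiveSize`. The default plan (20 000 iterations, 4 000
burn-in, thinning 8, 3 chains) is a desk-scale choice that the validation
suite exercises; the production-scale plan of 800 000 / 80 000 / 40 is a
one-line configuration change.

## The synthetic-data generators

Every analysis input can be generated with recorded truth:
`simulate_tree()` (Yule/birth-death, rescaled to a crown age, default 108
to echo the depth of a large avian phylogeny), `simulate_tree_posterior()`
(Poisson-many NNI moves plus log-normal edge jitter, re-ultrametrised),
`simulate_binary_trait()` (forward Gillespie on the λ-transformed tree,
truth history mapped back to the original branch lengths), and
`simulate_ecological_dataset()` (categorical ecology, phylogenetically
correlated species effects, individual effects, residuals; presence =
liability > 0; lengths returned raw and floored at zero to mimic
non-negative measurements with positive skew — a modelling decision, not
a claim about any particular dataset; family labels follow contiguous
clades with sampling fractions spread over [0.1, 1] for the downsampling
tests).

What the generators emulate: the statistical structure each analysis
assumes (Markov character evolution, λ attenuation, the animal-model
covariance, heterogeneous family sampling, topology noise). What they do
not: measurement error on museum specimens, real taxonomies and their
richness tables, missing data patterns, or correlated ecological traits.
A green suite therefore establishes that the estimators recover what they
model, not that any real dataset satisfies the model.

## Problem sizes and numerical conventions

The validation suite runs at desk scale, chosen as the package's own
test-design decision: 500-tip trees for rate/λ recovery (20 replicates),
10⁴–10⁵ draws for sampler-versus-oracle comparisons, 300 species × 2
specimens for mixed-model recovery (10 seeded replicates per family), and
a few hundred maps per summary. Ultrametricity is asserted at relative
tolerance 1e-8 (1e-6 where repaired trees are accepted); dwell times sum
to edge lengths within 1e-9; correlation eigenvalues are allowed down to
−1e-10; transition-probability entries are clamped at 0 against rounding.
Species-level trait aggregation uses OR for presence across specimens,
the mean of specimen means for length, and the modal non-Absent shape
with ties broken by the precedence Unbranched > Branched > Base
(most-derived reporting; the source is silent). A missing measurement
side contributes nothing to a specimen mean. The rank-sum statistic
follows the `W = rank-sum − n(n+1)/2` convention with tie-corrected
normal approximation and continuity correction; a zero-variance
comparison is reported as degenerate with p = 1.

## Known limitations

* Threshold-family chains inflate variance components on short runs (the
  classic binary-probit behaviour); parameter expansion, the usual
  remedy, is an explicit non-goal, so threshold models should be run with
  long plans and judged by their convergence flag — which is reported
  honestly, never suppressed.
* The χ²(1) LRT for λ is anticonservative at the boundary; use the
  mixture reference when calibrated p-values matter.
* Root-state confidence is conditional on the equal root prior.
* The categorical bristle-shape response (a model the source workflow
  abandoned for non-convergence) is out of scope, as are covarion/hidden
  rate models and continuous-trait λ.
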