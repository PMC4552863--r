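---
title: "Modeling brain network evolution by information flow capacity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling brain network evolution by information flow capacity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(bdnflow)
```

## The model

`bdnflow` studies brain dynamical networks (BDNs): graphs whose nodes carry
Hindmarsh-Rose (HR) neural dynamics and whose links are of two biologically
distinct kinds.  Each neuron `i` evolves as

$$
\begin{aligned}
\dot p_i &= q_i - a p_i^3 + b p_i^2 - n_i + I_{ext}
  - g_n (p_i - V_{syn}) \sum_j B_{ij} S(p_j)
  - g_l \sum_j G_{ij} p_j,\\
\dot q_i &= c - d p_i^2 - q_i,\\
\dot n_i &= r [s (p_i - p_0) - n_i],\\
\dot \phi_i &= \frac{\dot q_i p_i - \dot p_i q_i}{p_i^2 + q_i^2},
\end{aligned}
$$

where `p` is the membrane potential, `q` the fast current, `n` the slow
current and `phi` an unwrapped phase built from the fast variables.
Electrical (gap-junction) synapses couple diffusively through the graph
Laplacian `G = K - A` of the electrical adjacency `A`; chemical synapses act
through the sigmoidal activation
`S(p) = 1 / (1 + e^{-\lambda(p - \theta_{syn})})` on the chemical adjacency
`B`, and are excitatory because `(p_i - V_{syn})` stays negative on the
attractor (`|p| < 2 < V_{syn}`).  The defaults
(`a = 1, b = 3, c = 1, d = 5, s = 4, p_0 = -1.6, I_{ext} = 3.25,
r = 0.005`; `\theta_{syn} = -0.25, \lambda = 10, V_{syn} = 2`) put each
neuron in the chaotic spike-bursting regime.

Integration is forward Euler with `dt = 0.01`, the reference protocol for
all quantitative results in the package (higher-order integrators reproduce
the same behavior at this step size; the step-halving test in the suite
verifies the first-order error scaling).  All statistics start after a
transient `t_t = 300`, which is short because the seeded initial state —
the base point `(-1.30784489, -7.32183132, 3.35299859)` jittered per neuron
by `eta_i ~ U[0, 0.5]` — already lies near the attractor.  The same jitter
draw is shared by `p_i, q_i, n_i` by default (an `"independent"` option
exists).  Phases are integrated as a fourth state equation from
`phi_i(0) = 0` rather than reconstructed by arctangent; only phase
*differences* enter any measure, so this convention is benign.  If
`p_i^2 + q_i^2` vanishes at a sample the phase derivative is set to zero
for that sample — an arbitrary but inert choice, since the fast variables
never feed on `phi`.

## Information flow capacity

The mutual information rate (MIR) between any two nodes of a connected
network is bounded above by `I_c = \lambda_1 - \lambda_2`, the difference
of the two largest Lyapunov exponents.  `bdnflow` estimates these by the
tangent-space (Benettin) method: two tangent vectors in the
`3N`-dimensional `(p, q, n)` space evolve under the analytic Jacobian of
the coupled system (including the sigmoid derivative and the
`(p_i - V_{syn})` product rule) and are Gram-Schmidt re-orthonormalized
every `renorm_interval = 10` Euler steps.  Exponents are time-averaged log
stretch factors accumulated after the transient, with the interval
straddling the transient cutoff discarded.  Design choices worth knowing:

* The phase coordinates are excluded from the variational system.  They
  never influence `(p, q, n)`, so including them would only add a spurious
  neutral direction that could displace `\lambda_2`.
* Initial tangent vectors are the first two columns of the identity,
  orthonormalized — the estimate is therefore seed-independent given the
  trajectory.
* The analytic Jacobian is cross-checked in the test suite against a
  finite-difference Benettin reimplementation in R, and the whole machinery
  against linear systems with known eigenvalue real parts (recovered within
  1%).
* Estimates at a given `t_f` are finite-time quantities.  Convergence can
  be inspected through the returned `history`; the estimator is insensitive
  to `renorm_interval` in `{5, 10, 20}` at the 5% level.

```{r, eval = FALSE}
set.seed(1)
net <- ring_of_clusters(6, 10)
est <- lyapunov_exponents(net, syn = synapse_params(g_n = 0.9, g_l = 1.5),
                          cfg = sim_config(t_f = 2500))
est$ic
plot(est)   # running estimates
```

## Synchronization measures

The Kuramoto order parameter uses the population phasor
`z(t) = (1/N) \sum_j e^{i\phi_j(t)}`; its modulus is averaged over
post-transient samples to give `rho` in `[0, 1]`.  The `1/N` normalizer is
included so that `rho = 1` means complete synchronization — the stated
range requires it.  Pairwise synchronization
`rho_{ij} = |\langle e^{i(\phi_i - \phi_j)} \rangle_t| C_{ij}` is a
finite-window surrogate for an infinite-time average (the window,
`t_f - t_t`, is reported with every simulation) and is masked by the
combined adjacency `C`.  Cluster-level averages
`\langle rho_{ij} \rangle_{c_l}` run over *connected* intra-cluster pairs
only; a cluster without internal links yields `NA` rather than zero, so
degenerate clusters cannot masquerade as desynchronized ones.

## The evolution model

The starting topology is a closed ring of `N_c` equally sized clusters:
electrical links only within clusters (each cluster a Watts-Strogatz
small-world graph by default; Erdos-Renyi, Barabasi-Albert and
20%-perturbed-star variants are provided), and a single cycle of chemical
links joining one hub per cluster (the maximum-degree node, ties to the
smallest index).  Evolution then visits every unordered inter-cluster pair
not yet chemically linked, exactly once, in uniformly random order; a
candidate synapse is retained iff it strictly increases `I_c`.  Electrical
topology and both coupling strengths never change, links are never
deleted, and rejected pairs are not revisited.  The capacity of the final
network is the `mMIR`, by construction no less than the starting `I_c`.

Two choices the procedure leaves open were fixed as follows:

* **Shared initial conditions.**  Every candidate evaluation within one
  run reuses the same seed-derived initial state.  Finite-time `I_c`
  estimates carry initial-condition noise comparable to the effect of a
  single synapse; sharing the state makes the accept/reject comparison a
  paired one and prevents the greedy search from chasing noise.  The same
  device is available for parameter-space scans (`shared_state = TRUE`),
  and the suite's grid-property check uses it for the same reason.
* **Strict inequality.**  Ties reject, so neutral links cannot accumulate.

After each acceptance the global `rho` and the per-cluster
`\langle rho_{ij} \rangle` are recorded from the accepted run's phases;
`sync_slopes()` fits ordinary least squares against the acceptance index
and labels each trend `hebbian_like` (positive slope: synapse addition
accompanies synchronization growth) or `no_hebbian_like` (the opposite),
the same classification used to read the growth curves.

## Structure comparison

Evolved networks are compared to empirical connectomes structurally:

* **Small-worldness** `sigma = gamma / mu` with
  `gamma = C / \langle C_r \rangle_{100}`,
  `mu = L / \langle L_r \rangle_{100}`: the clustering coefficient is the
  mean of local clustering coefficients, and the 100 surrogates preserve
  the degree sequence exactly (connected configuration-model draws, with
  degree-preserving rewiring as fallback).
* **Communities and modularity**: walktrap with 6-step walks, dendrogram
  cut at maximum Newman-Girvan modularity; singleton communities are
  reported so callers can drop them as trivial.
* **Degree profiles** `pdf(kbar)`, `CC(kbar)`, `knn(kbar)` over exact
  normalized-degree classes `kbar = k / k_{max}` (no histogram binning).
* **Normalized-Laplacian spectra**: eigenvalues of the operator with unit
  diagonal and `-1/k_i` off-diagonal entries lie in `[0, 2]` for any graph,
  making differently sized networks comparable.  Densities are Gaussian
  smoothings (width `sigma = 0.015`) evaluated on the frozen grid
  `0, 0.001, ..., 2` and normalized to unit sum.  The spectral distance is
  the average-Euclidean form with squared terms and raw grid indices, kept
  exactly as defined — it depends on the axis scaling and is a comparison
  tool on the frozen grid, not an invariant metric.
* **Coupling rescaling**: to transfer a coupling range from a reference
  network to one with a different spectrum, the chemical maximum scales
  with the ratio of average chemical degrees and the electrical maximum
  with the ratio of smallest positive electrical-Laplacian eigenvalues
  `omega_m`.

## Study sizes and what the tests show

The reference protocol of the full study (`t_f = 5000` for empirical
connectomes, `t_f = 2500` for evolution runs, networks of 60-998 nodes,
coupling grids of ~10^4 cells) is available through the same functions, but
the packaged test suite and acceptance script run scaled-down versions
chosen to exercise every mechanism at desk scale:

* boundedness and capacity checks on the full 60-neuron, 6-cluster model
  at `t_f = 1000`;
* the synchronization/capacity anti-correlation on an 18-neuron, 3-cluster
  network over a 5x5 coupling grid at the reference `t_f = 2500`, with a
  shared initial state across cells;
* evolution runs on the 18-neuron network, likewise at the reference
  `t_f = 2500`, with the high-capacity and high-synchronization coupling
  pairs obtained by applying the rescaling rules to the 60-neuron
  reference values (`(0.9, 1.5)` and `(0.2, 1.8)` map to `(0.54, 0.71)`
  and `(0.12, 0.86)`).

The reference window matters: at much shorter windows (a few hundred time
units) the finite-time `I_c` fluctuations from a single added link are
comparable to the link's true effect, and both the grid anti-correlation
and the retention asymmetry sink below the noise floor.  At `t_f = 2500`
the anti-correlation is strong and seed-stable, while link-retention
counts remain noisy enough that the suite asserts *paired* and
*aggregate* comparisons (shared initial states; link totals summed over
five paired seeds) rather than cell-wise values.  What passing tests show
is that the implementation reproduces the
mechanisms — bounded chaotic bursting, a positive largest exponent, the
inverse synchronization/capacity tendency, capacity-monotone growth with
more retention in the high-capacity regime.  They do not certify the
quantitative parameter-space structure of the full-scale study, nor
anything about empirical connectomes beyond what the optional external-data
checks cover.  The synthetic generators emulate the model's idealized
starting topologies (equal cluster sizes, binary undirected links); real
connectomes are weighted, directed, and far from block-structured, and no
test here speaks to those features.

## Known limitations

* Forward Euler at `dt = 0.01` is the reference integrator by design;
  stiff parameter regions far outside the defaults may need smaller steps
  (the step-halving diagnostic applies).
* `I_c` is an upper bound for the MIR, not the MIR itself; the package
  deliberately does not estimate finite-size MIR.
* Only excitatory chemical synapses and deterministic (noise-free)
  dynamics are modeled.
* Evolution evaluates each candidate once; whether re-testing previously
  rejected pairs after later acceptances would change outcomes is not
  explored.
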