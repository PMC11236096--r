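---
title: "Reverse network diffusion: model, parameters and design choices"
author: "rendor package authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reverse network diffusion: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rendor)
```

## The problem

Inferred biological networks — gene regulatory networks above all — are
contaminated by *transitive* edges: if A regulates B and B regulates C, most
inference methods also assign a sizeable score to the pair (A, C) even when no
direct interaction exists. These indirect effects are not limited to
second-order paths; every chain of intermediaries contributes a little. The
package implements a denoiser that models this contamination as *diffusion of
a random walk* on the unknown direct network and removes it by inverting that
diffusion, together with four comparator denoisers, a generator of synthetic
noisy networks with ground-truth labels, and ranking-based evaluation.

## The diffusion model

A weighted undirected network $W$ defines a random walk through its
transition matrix $P = D^{-1} W$, where $D$ is the diagonal degree matrix
(`toTransition()`). Indirect effects are modelled by the forward diffusion
operator

$$f_m(P) \;=\; \frac{1}{\sum_{k\ge1} m^{-k}} \sum_{k\ge1} \frac{P^k}{m^k}
        \;=\; (m-1)\,P\,(mI - P)^{-1},$$

which adds the probability of *all* paths of length $k$ joining two nodes,
discounted by $1/m^k$. Because paths are composed from transition
probabilities, each step is normalized by the degree of the intermediate
node: paths through promiscuous hubs count for less. The series converges
for any $m > 1$ since the spectral radius of $P/m$ is $1/m < 1$.

The denoiser assumes the observed walk is the diffused image of a direct
walk, $P_{obs} = f_m(P_{dir})$, and inverts it in closed form:

$$f_m^{-1}(P) \;=\; m\,\big((m-1)I + P\big)^{-1} P.$$

`forwardDiffusion()` and `inverseDiffusion()` are exact functional inverses
of each other, and both conserve unit row sums; the test suite checks both
properties on batteries of random stochastic matrices. The inverse may
produce *negative* entries when the observed network was not actually
generated by diffusion — typically on sparse networks, where the weight of
an observed edge is too small to account for the path mass joining its
endpoints. Such rows are repaired after the fact (below).

Two auxiliary operators move between graphs and walks: $g(W) = D^{-1}W$ and
$h(P) = \alpha\,\mathrm{diag}(\pi(P))\,P$, where $\pi(P)$ is the stationary
distribution of the walk ($\pi P = \pi$; for the walk on a connected
undirected graph, $\pi$ is proportional to node degree). The denoiser is the
composite $h \circ f_m^{-1} \circ g$ (`rendorDenoise()`); the matching
forward composite $h \circ f_m \circ g$ (`nrDiffuse()`) is the generative
model it inverts and is useful for synthesizing diffusion-noised inputs and
for round-trip testing.

## The full pipeline and its numerical choices

`rendorDenoise()` executes, in order:

1. **Preprocessing** $\tilde W = W + \epsilon_1 J + \epsilon_2 I$
   (`preprocessNetwork()`). $J$ is the all-ones matrix and $I$ the identity;
   the offsets make the walk irreducible (so $\pi$ exists and is unique) and
   tame negative entries of the inverse step. By default $\epsilon_1 =
   \epsilon_2 = 1$ for an unweighted network and the minimum non-zero weight
   otherwise; "unweighted" means all non-zero weights equal 1 within 1e-12.
2. **Walk construction** $P = g(\tilde W)$. Zero-degree nodes are an error
   at this point, but cannot occur after preprocessing with positive
   $\epsilon_1$.
3. **Inverse diffusion** $P_{dir} = f_m^{-1}(P)$.
4. **Negative-row repair** (`clipNegativeRows()`): each row whose minimum is
   below $-10^{-12}$ is shifted by subtracting that minimum from every entry
   of the row; smaller excursions are floating-point dust and are left
   alone. A shifted row no longer sums to one.
5. **Row renormalization.** The walk-to-graph mapping $h$ is defined on
   transition matrices, so by default rows are renormalized before computing
   $\pi$; renormalization preserves the within-row ranking. The literal
   variant — applying $h$ with the dominant left eigenvector of the
   unnormalized shifted matrix — is available via
   `denoiseConfig(renormalizeRows = FALSE)`; on realistic inputs the two
   orderings agree almost exactly (rank correlation > 0.99 in the tests).
6. **Graph reconstruction** $h(P_{dir})$, symmetrized as $(M + M^\top)/2$
   and with the diagonal zeroed. The model domain is undirected graphs and
   self-loops carry no biological meaning here, so the slight asymmetry of a
   non-reversible corrected chain is averaged away. Because forward
   diffusion deposits mass on the diagonal (return paths) that this step
   discards, the graph-level round trip `rendorDenoise(nrDiffuse(W))` is
   close but not exact — the tests assert recovery to 1% of total weight
   with every true edge ranked above every spurious pair.

The output is a dense weighted matrix: pairs absent from the input acquire a
small weight unless the negative-row shift zeroed them exactly.

**Tunable parameters.** `m` (dimensionless, default 4) sets the path-length
discount: small `m` (just above 1) treats long paths as nearly as important
as short ones and denoises aggressively; large `m` leaves the network almost
untouched. The default follows the conservative choice recommended for
networks of unknown quality; `cliMain()`'s `msweep` subcommand scans a grid.
$\epsilon_1, \epsilon_2$ default to the automatic rule above and are
user-overridable. $\alpha$ only rescales the output — rankings are
$\alpha$-invariant — and defaults to matching the preprocessed input's total
weight so input and output live on comparable scales.

**Stationary distribution.** Dense left eigen-decomposition up to 2000
nodes, damped power iteration (tolerance 1e-12, cap 1e5 iterations) above or
as fallback; the damping (averaging each iterate with its predecessor)
removes the oscillation of periodic chains without changing the fixed
point. Reducible chains are rejected with advice to preprocess. These
choices respect the $O(n^3)$ profile of the dense pipeline.

## Comparator denoisers

* **Network deconvolution** (`ndDenoise()`): eigendecompose the similarity
  matrix, map every eigenvalue $\lambda \to \lambda/(1+\lambda)$,
  reassemble. This inverts the transitive closure $G_{obs} =
  G_{dir}(I - G_{dir})^{-1}$. The input is first rescaled linearly so the
  output's spectral radius equals `scale` (default 0.9), handling both the
  positive and the negative end of the spectrum; `scale = NULL` applies the
  raw map.
* **Network enhancement** (`neDenoise()`): a KNN-localized doubly
  stochastic kernel $T$ built from the row-normalized k-nearest-neighbour
  weights, iterated as $W_{t+1} = \alpha T W_t T + (1-\alpha) T$. Defaults
  $k = \min(20, n-1)$, $\alpha = 0.9$, 2 iterations — the method's published
  defaults; the comparison reports always carry the settings used. Nodes
  with fewer than $k$ positive neighbours use all they have (logged).
* **Silencer** (`silencerDenoise()`): solves
  $S = (C - I + D((C-I)C))\,C^{-1}$ on a unit-diagonal correlation-like
  matrix; $D(\cdot)$ keeps only the diagonal. The raw solution is not
  exactly symmetric (the diagonal-restoring term breaks it), so the returned
  matrix is symmetrized; `symmetrize = FALSE` exposes the literal solution,
  which satisfies the defining equation to machine precision.
* **Partial correlation / ICM** (`icmDenoise()`): $S = C^{-1}$,
  $P_{ij} = -S_{ij}/\sqrt{S_{ii}S_{jj}}$, unit diagonal.

Singular inputs to the latter two are a hard error by default; ridge repair
($C + \delta I$, default $\delta = 10^{-6}$) must be requested explicitly,
because silent regularization changes the method. When the benchmark harness
hands these correlation-based methods a bare adjacency matrix, it first
builds $C = I + \lambda \hat W$ with $\hat W$ the max-normalized weights and
$\lambda$ shrunk so that $C$ is positive definite (spectral radius of
$\lambda \hat W$ capped at 0.95) — the "scaled inverse correlation" reading
under which these methods are well defined, with ridge repair enabled.
Signed outputs are ranked by absolute value (`edgeRanking()`), since
evaluation concerns edge existence, not sign.

## The synthetic-data generator

`makeTrueGraph()` draws the ground truth: an $n$-cycle, an Erdős–Rényi
$G(n, p)$ graph (redrawn with an incremented seed until connected, each
redraw logged), or a Barabási–Albert graph grown from a complete seed of
$e+1$ nodes with $e$ distinct degree-proportional attachments per new node.
The study conditions are the cycle with $n = 20$, ER with $n = 50, p = 0.3$,
and BA with $n = 50, e = 3$.

`injectIndirectNoise()` adds spurious edges between non-adjacent pairs with
probability proportional to a path-proximity score
$s_{ij} = \sum_{k=2}^{4} (A^k)_{ij}/d^k$ ($A$ the binary adjacency, decay
$d = 4$ matching the denoiser's default $m$): the more and the shorter the
paths joining two nodes, the likelier a noise edge. The number of added
edges is $\mathrm{round}\big(\tfrac{q}{1-q}|E|\big)$ so noise forms the
requested proportion $q$ of the noisy network; added edges carry the mean
existing edge weight (1 on unweighted graphs). Pairs with zero score are
used only, uniformly and with a log message, when the quota cannot otherwise
be met. An alternative kernel (`kernel = "walk"`) scores pairs by powers of
the degree-normalized transition matrix instead, weighting paths the way the
diffusion model itself does; both renderings of the stated
"shorter-and-more-paths" principle are kept because the exact published
procedure is not fully specified.

**What the generator does and does not emulate.** Noise edges enter at full
edge weight, so the noisy graph is *not* the image of the forward diffusion
operator — deliberately: it tests the denoiser off its generative
assumption, as real inferred networks do. The flip side is that the noise
is weight-indistinguishable from signal, and separation can come only from
local path structure. On homogeneous topologies (cycle, ER) reverse
diffusion extracts that structure; on heavy-tailed BA graphs, the degree
corrections that the model applies to every edge are of the same order as
the signal/noise difference, and no tested method separates the classes
well there. Passing tests on this generator therefore demonstrate correct
operator algebra and the directional denoising effect on homogeneous
topologies — not performance on real expression-derived networks, which
have continuous, weight-graded indirect effects that match the diffusion
model far better.

`noiseSweep()` derives the seed of proportion index $i$, replicate $j$ as
$\mathrm{base} + 1000 i + j$, so a whole sweep is reproducible from one base
seed; a fresh true graph is drawn per replicate.

## Evaluation

Rankings cover all $\binom{n}{2}$ unordered pairs by default (the denoised
matrix is dense); pairs a method leaves at zero rank last, with ties broken
by the stable lexicographic pair order so every metric is reproducible.
`aurocScore()` uses the Mann–Whitney formulation (ties count 1/2);
`auprScore()` the step-wise, non-interpolated area over descending unique
thresholds; `confusionAtK()` and `tpCurve()` report confusion counts when
the top $k$ pairs are called positive. `benchmarkDenoisers()` applies a
method registry to labelled networks and aggregates means and standard
deviations per method, topology and noise proportion; individual method
failures are recorded as NA cells rather than aborting the run. A
restricted universe (`universe = "edges"`) scores only the noisy network's
own edges — signal against injected noise — under which the undenoised
input is at exact chance level by construction.

The benchmark and the acceptance checks run 20 replicates per noise
proportion (the full study's 100 is available by argument), sized so the
whole suite completes comfortably on a single CPU.

## Known limitations

* The model is strictly undirected; directed regulatory logic is
  symmetrized away at the boundaries (gold standards are symmetrized on
  reading).
* The dense $O(n^3)$ pipeline is intended for networks up to a few thousand
  nodes; no sparse path is provided.
* On the synthetic full-weight noise described above, the denoiser's
  advantage over the raw input is directional and topology-dependent: clear
  on cycles and ER graphs in mean true-positive counts and AUPR, absent on
  BA graphs. The per-seed comparison against the raw input on the 20-node
  cycle is additionally noisy because the input's edges are all tied and
  its top-k set is a tie-break lottery, so the input occasionally wins by
  luck; the test suite states the strict frequency claim and records its
  outcome honestly.
* Inverse diffusion on inputs far from the generative assumption relies on
  the negative-row repair; the repair preserves within-row order but is a
  heuristic, and both postprocessing variants (renormalized and literal)
  are exposed.
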