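---
title: "Detecting community modules in weighted brain networks with upsonet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting community modules in weighted brain networks with upsonet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(upsonet)
```

## The problem

Resting-state fMRI studies summarize a brain as a weighted, undirected
network: vertices are regions of interest (ROIs) and edge weights are
(Fisher z-transformed) Pearson correlations between regional time series.
Community modules — groups of ROIs more strongly connected among themselves
than with the rest of the network — carry functional meaning, and finding
them is typically cast as *modularity maximization*: over all partitions
$C$ of the vertex set, maximize

$$Q(C) = \frac{1}{2m} \sum_{ij} \left( a_{ij} - \frac{k_i k_j}{2m} \right)
  \delta(i, j),$$

where $a_{ij} \ge 0$ is the edge weight, $k_i = \sum_j a_{ij}$ the weighted
degree, $m$ the total edge weight, and $\delta(i,j) = 1$ when $i$ and $j$
share a community. Maximizing $Q$ is NP-hard, which motivates heuristic
search. `upsonet` implements **UPSO**, a particle swarm optimizer (PSO)
hybridized with *uniform experimental design*, together with a plain-PSO
ablation that differs only by the removal of the uniform-design components.

Partitions are also scored by **conductance**: for a cluster $C$,
$\phi(C) = \mathrm{cut}(C) / \min(\mathrm{vol}(C), \mathrm{vol}(\bar C))$,
averaged over nonempty clusters; lower is better. The defining formula sums
over all $K$ clusters, although its textbook prose is sometimes phrased in
terms of $K - 1$ cuts; we implement the formula, averaging $\phi$ over the
nonempty clusters, and use edge *weights* throughout (consistent with the
weighted modularity above). Empty clusters are excluded, zero-volume
clusters score 0 (the 0/0 convention), and the single-cluster partition
scores 0.

## Preprocessing

Raw connectivity matrices (CMs) hold z-transformed correlations, may be
negative, and may carry arbitrary diagonals. `preprocess_cm()` applies, in
order:

1. *reverse z-transform* (optional): $x' = (e^{2x}-1)/(e^{2x}+1) = \tanh x$;
2. *negative clamping*: negative correlations become 0;
3. *zero diagonal*: self-correlations are discarded — the source data do not
   state what the diagonal holds, and the modularity accounting above
   assumes no self-loops, so we zero it;
4. *symmetrization* by averaging $(a_{ij} + a_{ji})/2$; asymmetry beyond
   $10^{-6}$ is treated as a data error and rejected;
5. *thresholding*: weights strictly below $\theta$ (default $0.2$) are
   removed; the boundary value is kept, following the rule "if
   $x < \theta$ then $x = 0$" literally.

A graph with no surviving edge weight is rejected rather than silently
propagated, since $Q$ is undefined at $m = 0$.

## Position coding and decoding

A candidate solution with $K$ communities is encoded as the concatenation of
$K$ community centroids, each a length-$N$ vector in $[0,1]$, giving a
$K \cdot N$-dimensional particle. A position decodes to a partition by
assigning vertex $i$ to the centroid closest to its adjacency row $a_i$.
The source description measures distance "between $a_{ij}$ and each
centroid", which is dimensionally ambiguous; we use the Euclidean distance
between the full row $a_i$ and each centroid, the only reading consistent
with the centroid-update rule $\overline{CC}_k = n_k^{-1} \sum_{i \in C_k}
a_i$ (the mean of member rows). Ties go to the lowest community index, and
communities are allowed to decode empty: the reported `effective_K` counts
nonempty ones, which lets the $K$ sweep self-prune overshooting $K$.

## The optimizer

For each $K$ in `kmin..kmax` the swarm runs:

* **Uniform-design initialization.** The box $[0,1]^{K N}$ is split into
  $S$ sub-boxes and a $Q_0$-level good-lattice-point array places $Q_0$
  candidates per sub-box; the best `npop` of the $S \cdot Q_0$ candidates
  form the initial swarm. The reference for the original sub-interval
  construction is not specified in detail, so we use recursive bisection
  along the leading coordinates (cycling when $\log_2 S$ exceeds the
  dimension), with $S$ restricted to powers of two. The level-to-coordinate
  map is the affine map placing levels $1$ and $Q_0$ on the sub-box faces.
* **Centroid regulation.** Each particle's decoded communities are averaged
  into a candidate position $KC$; it replaces the particle only on strict
  fitness improvement, but is always kept as the third velocity attractor.
* **Velocity/position update.**
  $s' = \omega s + c_1 r_1 (P_{best} - x) + c_2 r_2 (G_{best} - x)
  + c_3 r_3 (KC - x)$, $x' = x + s'$, with $\omega$ decreasing linearly
  from `wmax` to `wmin` over `tmax` iterations. The stochastic factors
  $r_1, r_2, r_3$ are scalars per particle per update (matching the
  formula's notation); a per-dimension variant is available via
  `r_per_dimension`. The source bounds neither velocities nor positions;
  since adjacency weights live in $[0,1]$, centroids must too, so we clamp
  positions to $[0,1]$ and velocities to $[-1,1]$ componentwise.
  Velocities and personal bests are initialized at the particle positions.
* **Uniform-design crossover.** For each particle, the box spanned by
  $(x, P_{best})$ and by $(x, G_{best})$ is quantized into $Q_1$ levels per
  dimension and a $Q_1$-level uniform array selects $Q_1$ offspring from
  each; the best of the $2 Q_1$ offspring replaces $x$ *and* $P_{best}$
  when it strictly improves on $P_{best}$, and $G_{best}$ when it strictly
  improves on $G_{best}$. The quantization formula's middle branch is
  printed with a sign that would order levels decreasingly when
  $x_1 < x_2$; we use ascending levels from the componentwise minimum to
  the maximum, which is what the two endpoint branches force. Offspring of
  one generation are produced against the global best as it stood at the
  start of the crossover phase (the synchronous variant); replacements are
  then applied sequentially.
* **Termination.** A run stops when $t > t_{max}$ or when the global best
  has not improved (change $\le 10^{-12}$) for
  $\lceil \texttt{stall\_fraction} \cdot t_{max} \rceil$ consecutive
  iterations (default 30%).

The plain-PSO ablation (`run_pso()`) replaces the uniform-design
initialization by uniform-random positions and skips the crossover step;
everything else is identical, so UPSO − PSO isolates the uniform design's
contribution.

All acceptance comparisons are strict (`>`), as specified: a candidate
equal in fitness never replaces an incumbent.

### Uniform arrays

`uniform_array(n, q)` builds the good-lattice-point array
$U_{l_1 l_2} = (l_1 \sigma^{l_2 - 1} \bmod q) + 1$ with the generator
$\sigma$ taken from the tabulated $(q, n)$ ranges for the primes
$q \in \{5, 7, 11, 13, 17, 19, 23, 29, 31\}$. Powers of $\sigma$ are
reduced modulo $q$ iteratively, so arrays with hundreds of factors (the
particle dimension is $K \cdot N$) neither overflow nor lose balance:
multiplication by a nonzero residue modulo a prime is a bijection, hence
every column is a permutation of $\{1..q\}$ for *any* factor count. Factor
counts above the tabulated maximum ($q - 1$) reuse the generator of the
widest tabulated range.

### Default parameters

| parameter | default | meaning |
|---|---|---|
| `npop` | 100 | swarm size |
| `tmax` | 100 | iteration cap per fixed-K run |
| `wmin`, `wmax` | 0.1, 1.0 | linear inertia range |
| `c1`, `c2`, `c3` | 2 | attractor accelerations |
| `S` | 4 | initializer sub-boxes (power of two) |
| `Q0` | 31 | design points per sub-box ($S Q_0 \ge$ `npop`) |
| `Q1` | 5 | crossover offspring per parent pair |
| `theta` | 0.2 | preprocessing edge threshold |
| `stall_fraction` | 0.3 | stall terminator, fraction of `tmax` |
| `kmax` | `min(N, 20)` | top of the K sweep |

These are the standard operating values for ~264-ROI functional networks.
The full sweep to $K = N$ costs $O(t_{max} N_{pop} N)$ evaluations and is
rarely informative past moderate $K$ (decoding self-prunes empty
communities), so `kmax` defaults to `min(N, 20)`; set `kmax = N` to sweep
exhaustively.

## The synthetic benchmark generator

`generate_planted_pcm()` draws a symmetric, zero-diagonal weight matrix
with planted block structure: within-block weights from
$\mathcal N(0.7, 0.05)$ and between-block weights from
$\mathcal N(0.1, 0.05)$ by default, clipped to $[0,1]$. Gaussians (rather
than, say, Beta draws) keep the parameters transparent; with sd
$\le 0.1$ and means well inside $[0.1, 0.9]$ the clipping bias on the block
means is below 0.01. The defaults emulate what the preprocessing chain is
designed for: thresholding at $\theta = 0.2$ removes nearly all
between-block weight while blocks stay intact. `generate_z_cm()` applies
the forward Fisher z-transform (entries clipped to 0.999 first so the
transform stays finite) to produce raw-CM-like input, making the whole
chain round-trip testable to machine precision.

What the generator does **not** emulate: heavy-tailed or spatially
autocorrelated noise, degree heterogeneity inside blocks, overlapping or
hierarchical communities, negative-correlation structure beyond what
clamping removes, and any BOLD-level artifact. Passing the planted-recovery
tests therefore demonstrates correctness of the optimizer and pipeline on
clean block structure, not performance on real connectomes.

## Numerical choices

* Strict `<` at the threshold boundary; strict `>` in every acceptance
  comparison of the optimizer.
* Stall detection treats $|\Delta Q| \le 10^{-12}$ as "unchanged".
* Decoding drops the per-vertex constant $\|a_i\|^2$ from the squared
  distance (it does not change the argmin); ties go to the lowest index.
* Empty communities keep their previous centroid during regulation.
* Symmetry tolerances: $10^{-6}$ for accepting and averaging input
  asymmetry, $10^{-9}$ for the `weighted_graph` invariant.
* Whole swarm phases are decoded and scored in single batched
  matrix products; the modularity kernel works on the nonzero edge list.

## Worked example

A 36-vertex network with three planted blocks, thresholded at
$\theta = 0.2$, then the full UPSO sweep over $K = 1..6$:

```{r example, eval = FALSE}
sp <- planted_spec(c(12, 12, 12), seed = 7)
pl <- generate_planted_pcm(sp)
g <- preprocess_cm(pl$graph$adjacency, theta = 0.2)
res <- run_upso(g, upso_config(npop = 40, tmax = 60, kmin = 1, kmax = 6,
                               seed = 11))
res
nmi(res$best_partition, pl$partition)
```

With these study sizes the sweep recovers the planted three-block partition
exactly (NMI 1, effective K 3) in a few seconds. The same sizes are used by
the shipped test suite and by `scripts/acceptance.R`: graphs of 6–7
vertices (where the global optimum is verified by enumerating all set
partitions), 24-vertex graded-difficulty ablation graphs, and the 36-vertex
recovery benchmark above.

## Known limitations

* The optimizer is stochastic; only the seeded runs are reproducible.
* Nearest-centroid decoding can only express partitions induced by a
  Voronoi diagram of the adjacency rows; pathological optima outside that
  family are unreachable by construction (we have not observed this on
  block-structured or small dense graphs).
* Runtime grows as $O(t_{max} N_{pop} N)$ over the K sweep; for large
  networks prefer a pre-estimated or bounded K range.
* Conductance is reported for the modularity-optimal partition; the two
  criteria need not agree on the best partition.
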