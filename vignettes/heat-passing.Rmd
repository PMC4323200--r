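---
title: "Heat passing: diffusion geometry and exemplar discovery on networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heat passing: diffusion geometry and exemplar discovery on networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatpass)
```

## The model

A dataset is represented as a weighted undirected network $G = (V, E, W)$
with $W_{ij} \ge 0$, $W_{ii} = 0$.  Heat applied at a node flows along
edges at rates proportional to their weights.  With the degree matrix
$D_{ii} = \sum_j W_{ij}$, the package works with the normalized Laplacian

$$L_N = D^{-1/2} (D - W) D^{-1/2},$$

whose eigenvalues $0 = \lambda_1 \le \dots \le \lambda_n \le 2$ and
orthonormal eigenvectors $\phi_k$ define the heat kernel

$$H_t(i,j) = \sum_k e^{-\lambda_k t}\, \phi_k(i)\, \phi_k(j)
           = \big[e^{-t L_N}\big]_{ij}.$$

$H_t(i,j)$ — the *heat affinity* — is the amount of heat accumulated at
$j$ after time $t$ when a unit of heat is applied at $i$.  It aggregates
all paths between the two nodes and is therefore far more robust to
individual noisy edges than the raw weights.  Three derived quantities
serve the three analysis tasks:

* **ranking** — the heat distance
  $D_t(i,j) = H_t(i,i) + H_t(j,j) - 2 H_t(i,j)$;
* **embedding** — the heat coordinates
  $\mathrm{Cor}_t(i) = (e^{-\lambda_1 t/2}\phi_1(i), \dots,
  e^{-\lambda_k t/2}\phi_k(i))$, whose squared Euclidean distances
  reproduce $D_t$ exactly at $k = n$;
* **clustering** — the heat-passing procedure below.

Either Laplacian can be used (`laplacian = "unnormalized"` is exposed
everywhere); the normalized one is the default because it bounds the
spectrum, which makes one diffusion time roughly comparable across
networks of different densities.

## Heat passing

Clustering is posed as exemplar selection: choose an assignment
$g$ maximizing $\sum_i H_t(i, g_i)$ subject to the consistency constraint
that a chosen exemplar must select itself.  Every node starts with a
*heat-center preference value* (hcpv), its average temperature
$\mathrm{Temp}_t(i) = \sum_{j \ne i} H_t(i,j)$ — nodes from which heat
spreads efficiently make good centers.  Two message families are then
iterated over all ordered pairs (sink $s$, candidate center $c$):

* heat absorption
  $ha(s,c) = H_t(s,c) - \max_{c' \ne c}\{he(s,c') + H_t(s,c')\}$,
* heat emission
  $he(s,c) = \min\{0,\ ha(c,c) + \sum_{s' \notin \{s,c\}}
  \max(0, ha(s',c))\}$, with
  $he(c,c) = \sum_{s \ne c} \max(0, ha(s,c))$,

with the self-absorption pinned to
$ha(c,c) = \mathrm{hcpv}(c) - \max_{c' \ne c} H_t(c,c')$.  After
convergence the *normalized heat transfer coefficient*
$ht(s,c) = he(s,c) + ha(s,c)$ determines the result: $c$ is a heat
center iff its own column attains its row maximum, and every other node
joins the center maximizing $ht(s,\cdot)$.  The number of clusters is an
output, not an input.

Two readings of the self-absorption rule are possible (the
responsibility-style alternative subtracts
$\max_{c'}\{he + H_t\}$ instead).  The package uses the fixed form above:
across every benchmark we ran it yields the cleaner center sets, and on
the karate-club network it is the only reading that produces the
two-center result at $t = 4$; the alternative produces four.

### Numerical choices

* **Damping.** Undamped synchronous updates oscillate on symmetric
  inputs; each sweep therefore mixes old and new messages with factor
  0.5 (configurable).  Results were insensitive to the factor in
  $[0.3, 0.9]$.
* **Stopping.** Iteration stops when the largest absolute message change
  drops below `tol = 1e-6` (cap 20 000 sweeps).  A "center set stable
  for $w$ sweeps" early exit is available but *disabled by default*: the
  center set routinely freezes long before the sink assignments settle,
  and exiting early can return a provably suboptimal partition.
* **Ties.** All argmax ties break toward the lowest node label, making
  every result bit-for-bit reproducible.
* **Degenerate inputs.** A single node is its own center without message
  passing; an empty center set (possible mid-stream on adversarial
  input) falls back to the best self-coefficient with a warning.

### Choosing the diffusion time

$t$ is the resolution knob: $e^{-\lambda_k t}$ suppresses eigenmodes
with $\lambda_k \gg 1/t$, so small $t$ reads local structure and large
$t$ global structure.  There is no universally correct value.  Defaults
used by the package's own experiments:

| setting | $t$ | why |
|---|---|---|
| karate club (34 nodes, sparse) | 4 | two-community scale resolved |
| planted partition (60 nodes, 2 blocks) | 8 | blocks of 30 need deeper mixing |
| image networks (80 nodes, dense) | 6 | calibrated noiseless: 4 over-segments into view groups, 8 merges all |

The pattern is consistent: the sharper the intra-cluster mixing required
(larger, denser clusters), the larger $t$ must be.  On a new network,
sweeping $t$ over a small grid and watching the center count is the
intended workflow.

## Preferences and the cluster-count scale

The raw temperature sums $n-1$ kernel entries, so it grows with $n$ and
would drive every node to self-exemplar status.  The default preference
is therefore the *mean* heat received, $\mathrm{Temp}_t(i)/(n-1)$, which
lives on the same scale as the individual affinities while preserving
the temperature ranking.  `pref_scale` multiplies it: large values give
many singleton clusters, strongly negative diagonals give one; the
defaults sit in between and let the network decide.  Modes
`raw-temperature` and `median-similarity` are provided for comparison.

## Distance matrices and images

Non-network data enters through $W_{ij} = \exp(-d_{ij}^2/\sigma^2)$ with
$\sigma$ = median off-diagonal distance (configurable, optional mutual
$k$-NN sparsification).  The source never states its conversion; this is
the standard Gaussian-affinity construction.

For projection images the pairwise distance is the common-line
discrepancy: by the Fourier slice theorem two projections of the same
3-D object share a line in their 2-D transforms.  Each image is
mean-subtracted, its DFT re-phased so the phase origin sits at the image
center (without this every ray carries an angle-dependent phase ramp and
true common lines would not match), and sampled along `n_lines = 200`
rays (1.8° steps) at integer radii.  The distance between two rays is
the mean per-sample modulus of the difference; between two images, the
minimum over all ray pairs.  As printed, the source formula places the
modulus outside the sum, under which any two rays with equal sums
compare as identical; the package reads it as the per-sample form and
ships the printed variant as `mode = "literal"` for comparison.  A
`magnitude` mode compares only sample moduli: random center shifts add
linear phase ramps along rays, and discarding phase trades
discrimination for shift invariance.  `complex-shift` instead keeps the
phase and minimizes each line comparison over a table of candidate 1-D
shifts (the standard shift search along the common line) at a
proportional compute cost.  DC is always excluded (it is the
shift-invariant total mass); `r_min` optionally drops the lowest radii,
which are dominated by the projection envelope common to all views.

## What the synthetic generators emulate

* `karate_graph()` ships the classic 34-member, 78-edge social network
  with its observed post-split factions.
* `planted_partition_graph()` draws independent Bernoulli edges
  (within-block $p_{in}$, between $p_{out}$), resampling an edge for any
  isolated node so the normalized Laplacian stays defined.
* `make_two_state_dataset()` emulates a cryo-EM conformational
  heterogeneity experiment at desk scale: a Gaussian-blob phantom in two
  conformations differing by one blob displaced 8% of the box,
  projected at uniformly random orientations (volume rotation by
  trilinear resampling, then summation along one axis), shifted by a
  random integer up to 6% of the image size per axis, and corrupted by
  zero-mean Gaussian noise with $\mathrm{var(noise)} =
  \mathrm{var(signal)}/\mathrm{SNR}$ computed per image before shifting.
  SNR is nowhere defined in the source; this variance ratio is the
  declared stand-in.  Blob widths are 1.5–2.5 px so that the spectrum
  carries orientation information into the radial band the common-line
  comparison samples.

What the phantom does *not* emulate: contrast transfer functions,
detector statistics, structured background — and, critically, the
*scale* of the original experiment.

## What a green test does and does not establish

The deterministic criteria (kernel = matrix exponential, distance =
embedding identity, message-passing optimum = exhaustive optimum, the
karate regression) validate the implementation itself.

The scaled-down heterogeneity experiment is different.  At 40 images per
state on a 64-px box, the view sphere is sampled an order of magnitude
more sparsely than in the original 400-per-state, 130-px experiment.
The common-line distance is strongly view-dependent, and the clustering
signal travels through chains of similar views within a state; at this
sampling density those chains break.  Empirically (measured by this
package's own pipeline): the noiseless experiment resolves the two
conformations (K = 2, accuracy ≈ 0.89 at the calibrated $t = 6$), but by
SNR 0.5 the within/between distance contrast has collapsed to a few
percent and no parameter regime we tested (comparison modes, radial
bands, masks, binning, affinity bandwidths, $k$-NN graphs, diffusion
times, phantom redesigns) recovers state-level sorting.  The acceptance
suite keeps the full-strength assertions and lets the unattainable ones
fail, because reporting an honest failure at desk scale is more
informative than a criterion quietly tuned until it passes.  The
common-line *angle-error* trend (error falling, fraction of correct
lines rising with SNR) is robust at desk scale and is asserted as such;
it is measured on unshifted images, because the random center shifts
degrade line detection at every noise level (including noiseless) and
would bury the noise trend the measurement is about.

## Known limitations

* Full dense eigendecomposition: fine to a few thousand nodes; beyond
  that use the `k` truncation (the discarded modes decay like
  $e^{-\lambda_k t}$, affecting fine structure first).
* The silhouette-based quality index is computed on heat distances with
  the standard distance orientation; the source text mixes "similarity"
  and "distance" vocabulary, and our choice is declared rather than
  inferred.
* The accuracy index matches clusters to classes by exact
  maximum-weight one-to-one assignment (bitmask dynamic program), which
  caps at 20 clusters on the smaller side.
* MRC support covers mode-2 (float32) stacks only.
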