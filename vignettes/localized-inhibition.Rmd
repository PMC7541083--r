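---
title: "Modeling localized feedback inhibition on the APL skeleton"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling localized feedback inhibition on the APL skeleton}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aplspread)
```

## The model

The APL neuron inhibits Kenyon cells through reciprocal synapses spread
over its entire arbor, but it does not spike: depolarization spreads
passively and decays roughly exponentially with distance. `aplspread`
formalizes the consequence for feedback inhibition. If Kenyon cell k1
drives APL at its output synapses and APL inhibits Kenyon cell k2 at its
input synapses, the predicted strength of k1's inhibition of k2 is

$$ s(k_1,k_2) \;=\; \sum_i \sum_j e^{-d(x_{i,k_1},\,y_{j,k_2})/\lambda}, $$

a weighted count over every (KC1→APL, APL→KC2) synapse pair, where $d$ is
the distance between the two synapses measured along APL's neurite
skeleton and $\lambda$ is the space constant. Every synapse record
contributes one term, even when several records share a skeleton
location (APL presynaptic densities are polyadic); unique-location counts
are reported separately by `count_unique_locations()`.

### Electrotonic distance

Passive decay depends on neurite caliber: $\lambda \propto \sqrt{r}$. We
therefore measure distance in *electrotonic space*, dividing each length
element by $\sqrt{r(x)}$. Skeleton radii live on nodes, so roughly half
the segments taper; each edge is treated as a truncated cone, with
closed-form electrotonic length $2d(\sqrt{r_2}-\sqrt{r_1})/(r_2-r_1)$ and
the analogous partial form for two positions on one cone
(`segment_electrotonic_length()`, `partial_electrotonic_distance()`).
Decay in this space is $e^{-d_e/k}$ with $k = \sqrt{R_m/2R_a}$. The
whole-skeleton quotient (total real length / total electrotonic length,
`skeleton_totals()`) converts between $k$ and the radius-normalized
$\lambda$, so published estimates of $R_m/R_a$ translate directly into
space constants (`cable_to_space_constant()`, `lambda_to_cable()`).

Three distance conventions are available through `distance_mode()`:
electrotonic (truncated-cone), real (equivalent to assuming uniform
radius), and 1D backbone projection. Branch-point current division is
deliberately ignored everywhere — decay depends only on shortest-path
distance — matching the phenomenological scope of the model.

### Exact distances

Mapped synapses are inserted as vertices that split their host edges, and
all pairwise distances come from multi-source Dijkstra on that augmented
graph (`igraph::distances`). On a tree this is exactly the unique-path
length, which is what the brute-force oracles in the test suite check.
This replaces the two-stage nearest-neighbor staging a performance-minded
implementation might use: single-stage exact search is provably correct
and still fast at every scale exercised here.

## Parameters that matter

* **`lambda_um`** — space constant in µm. The analysis grid is
  {25, 50, 75} µm (bracketing the imaging-constrained best fit of 50 µm),
  plus the cable-derived 95.4 µm ($R_m/R_a$ = 0.0907 m) and 447.9 µm
  ($R_m/R_a$ = 2.0 m), and ∞ as the no-decay control. λ = ∞ forces every
  pair weight to 1, making $s(k_1,k_2)$ the product of synapse counts and
  the imbalance exactly 1 when input counts are equal.
* **Calyx filter** — `filter_synapses(..., "calyx")` restricts APL→KC
  synapses to y < 160 µm (20,000 hemibrain pixels at 8 nm/pixel) and
  region ≠ `PED(R)`, the convention for "dendritic-input-only"
  inhibition; KC→APL synapses are never filtered.
* **Imbalance denominator** — `self_other_ratio()` uses the arithmetic
  mean of $s(k_1,k_2)$ over $k_2 \ne k_1$ (off-diagonal only). This is
  the reading of "self vs. average of others" in which the diagonal is
  compared against its own column's off-diagonal mean; singleton subtype
  groups are excluded with a warning and counted, never silently dropped.
* **Node spacing** — 20 µm for across-recording comparisons (reduces
  inter-individual variability), 10 µm for the higher-resolution
  skeleton-registered analyses.
* **ΔF/F conventions** — background is subtracted before the baseline;
  $F_0$ is the pre-stimulus mean; boxcar smoothing (5 frames or 1 s) is
  applied only for trace display and peak finding, never for window
  averages; exclusion thresholds are pre-stimulus ΔF/F SD > 1.0 (green)
  and > 0.7 (red). The normalized inhibitory effect divides by the peak
  rather than the mean odor response because the peak is robust when the
  odor response is small.
* **TPM floor** — log₁₀ of zero TPM is set to −2 (TPM = 0.01), below the
  smallest nonzero value in the reference dataset, so screens are
  NaN-free; the floor is a named argument, not a hidden constant.

## The synthetic generators

The generators produce every input the analysis consumes, at sizes that
keep the full test suite within minutes on one CPU (≤ 50 KCs, ≤ 5,000
synapses, ≤ 64³ voxels):

* `make_toy_skeleton()` builds a Y-shaped skeleton — peduncle/calyx
  branch (160 µm) plus vertical (100 µm) and horizontal (90 µm) lobe
  branches, so the vertical tip sits ~260 µm from the dorsal calyx in
  the distance-from-calyx coordinate — with parallel neurite chains and
  log-normal radii around 0.25 µm (diameters ~0.5 µm, clamped at 3 µm
  diameter), echoing the caliber statistics of the real arbor.
* `make_synthetic_synapses()` gives each KC ~50 input and ~50 output
  synapses (the observed per-KC means are 49.6 and 52.6) placed around a
  per-KC anchor with along-route displacements from a truncated normal of
  scale σ (default 10 µm). This is the minimal mechanism that produces
  self-inhibition imbalance from spatial clustering; shuffling synapse
  identities (`shuffle_synapse_identities()`) removes it. The truncated
  normal is sampled by inverse CDF so no probability mass piles up at
  route ends, and σ → ∞ tends to uniform mixing along a route.
* `make_dye_profile()` and `fit_stimulus_decay()` close the loop on the
  stimulus model: exponential decay from the ejection site (half-strength
  at ℓ·ln 2; ℓ ≈ 14–36 µm matches the observed 10–25 µm half-decay),
  fitted per branch with overlapping branch fits averaged on shared
  trunks.
* `make_synthetic_movie()` emits 4D movies with known per-node ΔF/F,
  background, noise and optional integer shifts, so the volumetric
  pipeline's round trips (ΔF/F to 1e−10, shift recovery, exclusion
  thresholds, effect fields) are exact.

What passing these tests does *not* show: the generators are not
statistically faithful to the hemibrain synapse distribution (no
compartment structure, no polyadic geometry, no subtype-specific
innervation), the movies contain no motion or optical artifacts, and the
headline magnitude of the real-data imbalance (~40% median at λ = 50 µm)
depends on the full connectome synapse tables and is not asserted at
desk scale — only its qualitative structure (imbalance > 1, decreasing
in λ, vanishing at ∞ and under shuffling) is.

## Numerical choices

* Geometry is held in nm; electrotonic lengths in nm^1/2 with a single
  named constant (√10⁻⁹ m^1/2 per nm^1/2) for conversion; 1 hemibrain
  pixel = 8 nm.
* The cone formula switches to the cylinder form when |r₂ − r₁| is below
  a 1e−12 relative epsilon, so it is continuous through equal radii.
* Radii ≤ 0 or missing are clamped to the smallest positive radius in
  the file (SWC exports carry sentinel radii; the electrotonic integrand
  diverges at r = 0).
* Synapse mapping targets the nearest point on any edge (perpendicular
  foot clamped to the segment), not the nearest node; ties break to the
  lowest edge in canonical (sorted endpoint id) order, so a synapse
  equidistant from two nodes maps to the lower node id. Sub-edge mapping
  can shift unique-location counts slightly relative to node-resolution
  mapping.
* Voxel indices are 0-based with physical positions at voxel centers;
  Voronoi ties go to the lower node index; alignment searches integer
  shifts exhaustively (default ±10 voxels), with no subvoxel refinement.
* Quantification windows (the stimulus-period shading of the imaging
  figures) are configuration inputs: they are defined graphically in the
  source experiments, so the package never hard-codes them.
* Degenerate inputs fail fast: non-tree skeletons report components and
  cycles; constant dye profiles are rejected as non-decaying rather than
  returned with ℓ = ∞; F₀ ≤ background yields NaN nodes with a warning.

## Simulation scales

The activity-spread acceptance runs use a 300 µm uniform cable with
10,000 sampled points against a single stimulated end point — at that
size the normalized profile matches $e^{-x/\lambda}$ within 5% per 10 µm
segment and the simulate→fit loop recovers λ within 10%. The inhibition
analyses use the 20-KC default population (2,000 synapses). These sizes
were chosen so each property is measured well inside its tolerance while
the whole suite stays desk-sized; all randomness is seeded.

## Known limitations

* No compartmental dynamics: no time course, no active conductances, no
  synaptic-weight heterogeneity, no gap junctions.
* Branching effects on passive spread (impedance mismatch at branch
  points) are ignored by design.
* The backbone registration of a connectome skeleton is a configured
  landmark mapping, not an inferred alignment.
* The expression screen compares per-type means; per-replicate
  comparisons would be stricter and can change counts near ties.
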