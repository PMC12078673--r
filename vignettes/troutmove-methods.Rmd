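---
title: "Methods: hydraulics, habitat suitability and movement bias in troutmove"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hydraulics, habitat suitability and movement bias in troutmove}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup}
library(troutmove)
```

## Scope and model chain

`troutmove` models how flow-dependent habitat quality biases the movement of
brown trout between adjacent reaches of a dendritic river network. The chain
is deliberately simple: one scalar per reach at each stage, so a whole
catchment is evaluated in milliseconds.

1. **Topology.** The network is a rooted binary tree: sources (no upstream
   links), junctions (exactly two upstream links), one outlet. Discharge is
   routed by continuity — each junction carries the sum of its two branches,
   so discharge at any node equals the summed inflow of all sources above it.
2. **Hydraulics.** Every reach is a rectangular channel in normal flow; depth
   inverts the Manning resistance law, velocity follows from continuity.
3. **Habitat.** Depth and velocity feed one suitability curve each per age
   class; the compound index is their geometric mean.
4. **Movement.** Habitat ratios between adjacent reaches rescale a base
   movement bias through a Verhulst logistic, producing a per-node probability
   triple (two upstream moves, one downstream) that assembles into a Markov
   transition kernel.

## Assumptions and their consequences

* **Rectangular sections, normal flow.** Real reaches have compound sections,
  backwater effects and structures. Both simplifications are standard at
  catchment scale when per-section geometry is unavailable; they mean computed
  H and U are reach-scale averages, not local microhabitat values.
* **Attributes by Strahler order.** Width, slope and roughness default to a
  lookup by stream order (wider, milder, smoother downstream) unless the node
  table supplies per-reach values, which always take precedence. This mirrors
  hydraulic-geometry practice for ungauged basins.
* **Reach length is carried but unused**: the bias acts between adjacent
  nodes regardless of distance, and no movement cost is modelled.
* **Time is unitless** in the movement kernel: one application is one
  movement decision. No demography (birth, death, carrying capacity) is
  included — the kernel is the interface through which this model would plug
  into a fuller metapopulation model.

## Parameters

| parameter | meaning | units | default | why |
|---|---|---|---|---|
| `Q0` | inflow per source node | m³/s | 0.2 | low-flow scenario scale; sweeps use 0.2–0.6 |
| `B, S, n` | reach width, slope, roughness | m, –, s·m^–1/3 | by Strahler order: B = 2·1.6^(SO−1) m, S = 0.02·0.6^(SO−1), n = 0.04 | field-plausible headwater values with geometric downstream widening/flattening; configuration, not hard-coded |
| `tol` | Manning residual tolerance | relative | 1e-8 | far below any ecological signal; cheap |
| `|b0|` | base bias magnitude | – | 0.1 | halved-per-branch form of the constant-bias literature value 0.2 |
| `b_min, b_max` | bias envelope | – | |b0|/2, 2|b0| | multipliers of |b0| so rescaling b0 rescales the envelope |
| `a` | habitat-contrast sensitivity | – | 2 | quadratic response; no evidence for class-specific values, so shared |
| `hsi_floor` | floor on compound HSI before ratios | – | 1e-6 | a zero HSI makes the ratio undefined; the floor keeps the bias computable while leaving the habitat signal intact |

The four default suitability-curve coefficient sets (adult/juvenile ×
depth/velocity) ship both as code defaults and as a YAML file
(`inst/extdata/hsc_default.yaml`). Depth curves take centimetres and velocity
curves centimetres per second: the velocity data ranges quoted with the
curves (tens of cm/s) and depth optima near 50 only make sense in those
units, so SI-to-curve conversion (×100) happens exactly once, inside
`network_hsi()`.

## Numerical choices

* **Normal-depth solver.** Conveyance is strictly increasing in depth, so the
  root is unique. The initial bracket starts at the wide-channel estimate
  `(nQ/(B√S))^(3/5) × 10` and expands geometrically (error beyond 10⁶ m —
  inconsistent inputs). Root finding uses Brent's method (`stats::uniroot`),
  which is bracketed and unconditionally convergent like plain bisection but
  faster; a bisection fallback guards the residual tolerance `|ΔQ| ≤ tol·Q`.
* **Curve evaluation.** The gamma kernel is evaluated in log space so large
  velocities underflow cleanly to the offset instead of overflowing; outputs
  are clamped to [0, 1] because refitted coefficients need not satisfy
  `c + A ≤ 1` exactly.
* **Bias evaluation.** `k^(ratio^a)` is computed in log space; below
  exp(−690) it is treated as exactly 0, yielding `b_max`. Analytically `|b|`
  is strictly increasing in the ratio, but in double precision it saturates
  at `b_max` once the decay term underflows (ratio ≳ 40 with defaults) — the
  tests check strict monotonicity on moderate ratios and the limits
  separately.
* **Curve fitting.** `fit_hsc()` uses Levenberg–Marquardt
  (`minpack.lm::nlsLM`) from a method-of-moments start plus four
  deterministically jittered restarts, keeping the best residual sum of
  squares. The restarts are a fixed table, not RNG draws, so fitting never
  perturbs the caller's random stream. The gamma family is multimodal in
  `(λ, u0, θ)`; the restarts are what make noiseless round-trips recover all
  four shipped coefficient sets to 1e-6. `R²` is reported as
  `1 − SS_res/SS_tot` on the fitted samples.
* **Stationary distribution.** An unbiased walk on a tree is bipartite
  (period 2), so plain power iteration oscillates. Iteration therefore runs
  on the lazy chain `(P + I)/2` — same fixed point, guaranteed aperiodic —
  to a fixed-point residual of 1e-12. Irreducibility of the sparsity pattern
  is checked first; reducible chains are reported, never silently solved.
* **Degenerate inputs.** Single-node networks are valid (source = outlet,
  unit self-loop kernel). Zero compound HSI at a junction is an error unless
  the floor is enabled (the default). Constant suitability samples are a
  degenerate-data error in fitting.

## Open design points and how they were decided

* **Sign convention of the bias.** The probability rule `P_up = (1 − b)/4`
  applied to a signed bias gives adults (negative `b`) *higher* upstream
  probabilities, which conflicts with the stated adult preference for
  downstream movement. The package implements the formula as printed
  (`sign_convention = "printed"`, the default) and exposes
  `"narrative"`, which flips the sign inside the probability rule so that
  negative bias depresses upstream movement. The directional sanity check in
  the test suite (adult stationary mass accumulating toward the outlet
  relative to juveniles) holds under `"narrative"`.
* **Outlet boundary.** The model chain does not define what happens to
  downstream mass at the outlet. Two policies are provided:
  `"reflect"` (default; the outlet's downstream mass is renormalized onto its
  upstream probabilities, keeping the chain irreducible so stationary
  analysis is well-defined) and `"absorb-self"` (downstream mass becomes a
  self-loop).
* **Per-class sensitivity.** The exponent `a` is shared between age classes;
  nothing in the underlying analysis distinguishes them.

## What the synthetic generators emulate — and what they do not

`generate_binary_network()` grows random or balanced binary trees by seeded
recursive splitting of the source count, giving varied Strahler-order
distributions cheaply; `generate_so_table()` applies geometric downstream
widening and slope decay; `generate_hsc_samples()` draws suitability samples
from a known curve with additive truncated-Gaussian noise. These reproduce
the *structure* the pipeline needs (valid topology, realistic attribute
monotonicity, curve-shaped samples), not real catchments: no optimal channel
network statistics, no DEM-derived geometry, no empirical noise model for
field suitability data, and no spatial correlation of attributes beyond the
Strahler trend. Passing tests therefore demonstrate correctness of the
computations and their invariants, not predictive accuracy for any specific
river.

Test and example problem sizes — networks up to 64 sources (127 nodes),
10⁴ walkers over 10³ steps, 1000 random hydraulic instances against a
bisection oracle — were chosen so the full suite exercises every invariant in
well under a minute; the pipeline itself scales linearly in nodes and the
kernel solver in nonzeros.

## Known limitations

* Normal flow cannot represent backwater, weirs or energy-slope effects;
  composite cross-sections are out of scope.
* Temperature and substrate suitability are not modelled; only depth and
  velocity curves for adults and juveniles ship by default (other curves can
  be supplied via the YAML library).
* The movement kernel has no demography, density dependence or seasonal flow
  alternation; stationary occupancies describe the movement process alone.
* Networks must be strictly binary trees: confluences of three or more
  tributaries and braided topologies are rejected by validation.
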