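---
title: "Lesion-aware connectome estimation with an explicit damage compartment"
author: "mcconnectome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lesion-aware connectome estimation with an explicit damage compartment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcconnectome)
```

## The problem

Microstructure-informed tractography turns a tractogram into a weighted
structural connectome by assigning each streamline $s_i$ an effective
intra-axonal cross-sectional area $c_i$. In the simplified intra-axonal-only
setting used throughout this package, the data are a voxelwise intra-axonal
signal-fraction map $y$ ("fiber density"), and the weights solve the
non-negative least-squares (NNLS) problem

$$x = \arg\min_{x \ge 0} \lVert A x - y \rVert_2^2,$$

where $A_{v i} = l(i, v)$ is the length of streamline $i$ inside voxel $v$.
The connection strength of an edge $b$ is $C_b = \sum_{i \in I_b} c_i$ with
$c_i = x_i$.

This model assumes that $c_i$ is constant along the streamline. A focal
white-matter lesion breaks the assumption: the local signal deficit cannot be
explained by any constant weight, so the global fit compensates by shifting
weights — including weights of bundles that never touch the lesion. The
package's crossing phantom makes this concrete: a 50% signal loss in a single
voxel of one bundle (0.14 to 0.07) drags that bundle's estimate to 0.115
(−18% instead of the true −50%), pushes the crossing bundle from 0.16 up to
0.165, and a third bundle two crossings away from the lesion down to 0.138.

## The lesion compartment

The remedy implemented here augments the operator with one column per
pathological voxel (from a binary lesion mask): $\tilde A = [A \mid L]$,
where each $L$ column is zero except for a single $-1$ at its voxel's row.
Solving

$$\tilde x = \arg\min_{\tilde x \ge 0} \lVert \tilde A \tilde x - y \rVert_2^2,
\qquad \tilde x = [x \mid x^L],$$

lets the nonnegative coefficient $x^L_{k(v)}$ absorb the *absolute* signal
loss in lesion voxel $v$ (the $-1$ makes a nonnegative coefficient reduce the
prediction). Every voxel in the mask gets its own column; no within-lesion
aggregation is performed. With the deficit explained locally, the streamline
block recovers the healthy weights and the error-compensation cascade never
starts.

The fitted losses are converted into a relative reduction per lesioned voxel,

$$R(v) = \frac{\sum_{i \in I_v} x_i\, l(i,v) - x^L_{k(v)}}
              {\sum_{i \in I_v} x_i\, l(i,v)},$$

with $R(v) = 1$ outside lesions, and the weights are modulated by the
weakest-link rule: the locally modulated area is $c_i'(t) = c_i R(s_i(t))$
and the adjusted weight is $\hat c_i = \min_t c_i'(t)$. Because $R$ is
piecewise constant per voxel, the continuous minimum equals the minimum over
the discrete set of voxels the streamline visits, which is how
`adjustWeights()` evaluates it. Connectomes built from $\hat c$ are the
*multi-compartment* variant; built from $c$ they are the *standard* variant.

```{r worked-example}
ph <- makeCrossingPhantom(lesion = TRUE)
segs <- segmentTable(ph$phantom)

# lesion-blind fit: biased estimates
round(streamlineWeights(fitWeights(lesionOperator(segs), ph$signal)), 3)

# augmented fit: unbiased weights, explicit loss, weakest-link adjustment
op <- lesionOperator(segs, ph$lesionMask)
fit <- fitWeights(op, ph$signal)
streamlineWeights(fit)
lesionLosses(fit)
adjustWeights(streamlineWeights(fit), segs, reductionMap(fit, op))
```

## Numerical choices

* **Solver.** `nnlsSolve()` is a deterministic active-set (Lawson–Hanson)
  method on the normal equations; the default gradient tolerance is
  `1e-10` relative to $\max(|A^\top y|, 1)$. No regularization is applied by
  default; a `ridge` argument exists as an escape hatch for degenerate
  systems and defaults to 0. Voxel rows with neither streamline coverage nor
  a lesion column only add a constant to the objective, so they are carried
  through the residual but cannot influence the solution.
* **Geometry.** Voxel $k$ (0-based) owns the half-open interval $[k, k+1)$
  in continuous voxel coordinates; world coordinates map through a full
  4×4 affine (default: isotropic scaling with the grid corner at the world
  origin). Each polyline segment is clipped at the integer planes it
  crosses, and each sub-segment is assigned to the voxel containing its
  midpoint — equivalent to the half-open rule for interior points and a
  deterministic tie-break (boundary points belong to the higher-index
  voxel). Repeated points are skipped silently; per-streamline lengths sum
  exactly to the arc length.
* **Clamping.** $R$ is clamped into $[0, 1]$ after the ratio above;
  a loss overshooting the predicted signal (possible under noise) maps to
  $R = 0$. A lesioned voxel with zero predicted signal (no streamline, or
  only zero-weight streamlines) gets $R = 1$ with a warning, since there is
  no weight to modulate there.
* **Node assignment.** Endpoints map to the parcellation label of their
  containing voxel; endpoints exactly on the outer grid boundary belong to
  the boundary voxel. Background endpoints (label 0) and self-loops are
  dropped. This is the simplest deterministic rule; no radial search is
  attempted.
* **Density thresholding.** `thresholdDensity()` keeps the strongest edges
  up to the target edge density and keeps *all* edges tied with the cutoff
  weight, accepting an overshoot in exchange for determinism.
* **Metrics.** Edge length for global efficiency is $1/\text{weight}$;
  disconnected pairs contribute zero. Modularity is the weighted
  Newman–Girvan $Q$ of the best partition found by a seeded multi-restart
  Louvain search (10 restarts, resolution 1). Mean strength is linear in a
  global weight factor, efficiency scales linearly with it, and $Q$ is
  invariant to it.

## What the synthetic data emulate — and what they do not

The phantoms emulate the *inputs* of the pipeline directly: straight bundles
through voxel centers on a unit grid, so intersection lengths are 1 and
voxel signals share units with bundle weights, making the worked-example
numbers exactly reproducible. Lesions are unions of spheres seeded uniformly
in the white matter and dilated in one-voxel radius steps until they cover
the target fraction (default 5% of WM, the coverage typically reported for
multiple-sclerosis cohorts); the stopping rule may overshoot by one dilation
increment. Damage multiplies the signal inside the mask by $1-d$ with the
five canonical grades $d \in \{0, 0.25, 0.5, 0.75, 1\}$.

No diffusion signal is simulated — no b-values, gradient schemes, noise
floors, or tensor models — because the simplified forward model consumes the
intra-axonal fraction map itself. Passing tests therefore demonstrate the
estimator's algebraic behaviour (bias without the compartment, exact
recovery with it, weakest-link propagation), not robustness to acquisition
noise, tractography errors, or partial-volume effects present in real data.

The cohort generator draws per-subject bundle weights as
$w_b (1 + \varepsilon)$, $\varepsilon \sim N(0, \sigma)$ truncated at zero,
with $\sigma = 0.1$ by default — a typical between-subject coefficient of
variation for intra-axonal fraction estimates — plus a fresh lesion mask per
subject that is shared across damage levels, mirroring a within-subject
damage-grading design.

## Design choices in the sensitivity experiment

The group comparison is deliberately literal: in each outer iteration the
cohort (default 44 subjects) is split at random into two halves (controls
take the healthy-variant metric, patients the damaged-variant one; the
larger half goes to controls when the cohort is odd), an inner two-sided
difference-in-means permutation test (Monte-Carlo, 1000 resamples, add-one
correction) yields a p value, and the reported statistic is the proportion
of iterations with $p > 0.05$ — approximately 0.95 under the null, falling
toward 0 as sensitivity grows. `permTestMeans()` switches to exact
enumeration whenever $\binom{n_a+n_b}{n_a} \le 10^5$.

The default cohort phantom has 12 nodes and 46 straight bundles on a
$12^3$ grid. The bundle count is chosen so the resulting graphs have an edge
density near 70%, matching the density of the whole-brain connectomes this
phantom stands in for; at much sparser densities a focal lesion hitting a
few of the bundles moves modularity in a subject-specific direction and the
group effect averages away, whereas mean strength and efficiency respond at
any density. The generator also guarantees every bundle at least one
exclusive voxel (a voxel it shares with no other bundle), which makes the
noiseless system identifiable: an exclusive healthy voxel pins each bundle's
weight, so the augmented fit recovers the truth exactly and the fitted
$R$ in a voxel carrying a single bundle equals $1-d$.

## Problem sizes

The shipped tests and the acceptance script run at desk scale by choice:
the 9-voxel crossing phantom for the worked example; random phantoms of up
to 10 bundles for recovery properties; 100 random systems of at most 6
columns against an exhaustive active-set oracle; 8-node graphs against a
Floyd–Warshall oracle; all 203 partitions of 6 nodes for the modularity
oracle; and the full cohort procedure with 44 subjects, 5000 outer
iterations for null calibration and 1000 for the damage-response pattern.

## Known limitations

* Only WM lesions are modeled; gray-matter lesions are out of scope, and a
  binary lesion mask must be supplied — voxels outside it, such as
  surrounding edema, are treated as healthy unless added to the mask.
* The extra-axonal and isotropic compartments of the full multi-compartment
  signal model are not implemented; the operator is intra-axonal-only, with
  the lesion block as the single additional compartment. The
  `LesionOperator` layout (column blocks over a shared voxel grid) is the
  extension point.
* Tractogram I/O supports TCK only; TRK files must be converted upstream.
* The weakest-link minimum is evaluated on the discrete visited-voxel set,
  which is exact for piecewise-constant $R$ but would under-resolve a
  sub-voxel damage model.
* Louvain is a heuristic: the multi-restart search is deterministic under a
  seed and matches the exhaustive optimum on the small graphs tested, but
  carries no global-optimality guarantee on larger graphs.
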