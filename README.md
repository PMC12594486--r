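# mcconnectome

Lesion-aware structural connectome estimation for brains with focal
white-matter damage.

## The problem

Microstructure-informed tractography estimates one nonnegative weight per
streamline — its effective intra-axonal cross-sectional area — by fitting
the tractogram to a voxelwise intra-axonal signal-fraction map:

    x = argmin_{x >= 0} || A x - y ||^2,        A[v, i] = l(i, v)

where `l(i, v)` is the length of streamline `i` inside voxel `v`. Edge
weights of the connectome are sums of streamline weights. The fit assumes
each weight is constant along the streamline, and a focal lesion breaks
that: the unexplained local signal deficit triggers global error
compensation that biases weights of bundles far from the lesion.

This package augments the forward operator with an explicit lesion
compartment — one column per pathological voxel carrying a single `-1`
entry — so a nonnegative coefficient absorbs the absolute local signal
loss:

    [x | xL] = argmin_{x,xL >= 0} || [A | L] [x | xL] - y ||^2

The fitted losses give a per-voxel relative reduction
`R(v) = (sum_i x_i l(i,v) - xL_k(v)) / sum_i x_i l(i,v)` (1 = healthy,
0 = complete axonal damage), and each streamline weight is modulated by the
weakest link along its path, `c_hat_i = c_i * min_v R(v)`, before the
connectome edges are summed ("multi-compartment connectome").

The package also ships synthetic phantoms (crossing bundles with known true
weights, random spherical lesions, five damage grades, multi-subject
cohorts), graph metrics (mean strength, global efficiency, Louvain
modularity), a permutation-based group sensitivity procedure, NIfTI/TCK/CSV
I/O and a small CLI — so the whole pipeline runs and is testable without any
imaging download.

## Worked example

The canonical crossing phantom has a horizontal bundle (true weight 0.16,
5 voxels) crossed by two vertical bundles (0.14 each, 3 voxels each); a
focal lesion halves the signal in one voxel of Bundle 2 (0.14 -> 0.07).

```r
library(mcconnectome)

ph   <- makeCrossingPhantom(lesion = TRUE)
segs <- segmentTable(ph$phantom)

# Lesion-blind fit: the lesion biases every bundle, including healthy ones
round(streamlineWeights(fitWeights(lesionOperator(segs), ph$signal)), 3)
#> [1] 0.165 0.115 0.138

# Augmented fit: true weights recovered, loss isolated in its own coefficient
op  <- lesionOperator(segs, ph$lesionMask)
fit <- fitWeights(op, ph$signal)
streamlineWeights(fit)   #> [1] 0.16 0.14 0.14
lesionLosses(fit)        #> [1] 0.07

# Relative reduction and weakest-link adjustment
rmap <- reductionMap(fit, op)
rmap@R[2, 3, 1]          #> [1] 0.5
adjustWeights(streamlineWeights(fit), segs, rmap)
#> [1] 0.16 0.07 0.14
```

The biased fit understates the lesioned bundle (0.115 instead of
reflecting the true 50% loss), overstates the crossing bundle (0.165) and
understates a bundle two crossings away (0.138). The augmented fit returns
the healthy weights exactly, measures the absolute loss (0.07) in its own
coefficient, and the weakest-link rule propagates the 50% reduction to the
lesioned bundle's edge weight (0.14 * 0.5 = 0.07) while leaving the others
untouched.

Cohort-level analysis:

```r
res <- sensitivitySimulation(nSubjects = 44, nIterations = 1000, seed = 1)
```

returns, per connectome variant, metric and damage grade, the proportion of
random cohort splits whose permutation test stays non-significant — about
0.95 with no damage, dropping as the multi-compartment connectome picks up
the simulated pathology.

A thin CLI wraps the same functions
(`Rscript inst/cli/mcconn.R simulate|fit|connectome|metrics|permtest ...`).

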