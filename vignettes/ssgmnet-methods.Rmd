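---
title: "Single-subject gray-matter networks: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-subject gray-matter networks: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssgmnet)
```

## The model

A single-subject gray-matter network (SSGMNet) treats one subject's
gray-matter density volume as a graph. The volume is tiled with
non-overlapping 3x3x3-voxel cubes; each cube with nonzero density variance
is a node. Two nodes are connected when their density patterns are
statistically similar: the edge weight candidate is the Pearson correlation
between the 27-voxel patterns, maximized over a set of within-cube
transforms - rotations in multiples of 45 degrees about each axis combined
with reflections over all axes - because the cortex is a curved sheet and
two genuinely similar patches may sit at an angle to each other.

On a 3x3x3 grid, a 45-degree rotation about an axis is realized exactly as
a one-step cyclic shift of the 8-voxel perimeter ring of each plane
perpendicular to that axis, with plane centers fixed; 90-degree multiples
coincide with the rigid rotations of the cube. Composing the 24 single-axis
ring rotations with the 8 axis reflections and removing duplicates gives 80
distinct index permutations, including the identity. Similarity is computed
in both orderings (transforming either cube of a pair) and the larger value
kept, which makes the matrix symmetric by construction.

Which correlations count as edges is decided per subject. A permutation
null is built by repeatedly drawing random pairs of cubes, scrambling the
within-cube voxel order of one of them (destroying its spatial structure),
and recording the transform-maximized correlation. Each observed pair gets
an upper-tail empirical p-value against this null using the (b+1)/(m+1)
estimator (so p is never exactly zero), and Benjamini-Hochberg is applied
across all N(N-1)/2 pairs at q = 0.05, bounding the expected proportion of
spurious connections at 5%. An edge requires a correlation strictly higher
than the realized threshold: pairs tied with the largest non-retained
correlation are not edges.

## Graph attributes

From the binarized graph G = [N, K] the package computes:

* **Clux** - mean Watts-Strogatz local clustering (nodes with degree < 2
  contribute 0);
* **CharPath** - mean shortest-path length over ordered pairs; on a
  disconnected graph the mean is over reachable pairs only and the result
  carries a `disconnected` flag (the reachable-pairs convention is the
  default; unreachable pairs are never imputed);
* **Eglobal** - mean inverse shortest-path length, unreachable pairs
  contributing 0;
* **GConnect** - the mean off-diagonal entry of the *unthresholded*
  similarity matrix (the binary matrix no longer contains correlations);
* **sparsity** - 100 x 2K / (N(N-1)), the ordered-pair convention.

Clux and CharPath are normalized against 20 degree-preserving randomized
reference networks (Maslov-Sneppen double-edge swaps, 10 x K attempted
swaps per reference, implemented in C++). `gamma = Clux/Clux_rand`,
`lambda = CharPath/CharPath_rand`, and the small-world coefficient
`sigma = gamma/lambda`; sigma > 1 indicates small-world topology. The
scalar `Clux_rand` is also the denominator for the nodal normalized
clustering, which is averaged per atlas region (cube-to-region assignment
by the region label of the cube's center voxel; regions without cube
centers are reported missing, not zero).

Shortest paths are computed by successive Boolean matrix products (BLAS),
falling back to BFS for graphs that have not converged after 12 products;
for the dense, small-diameter graphs this pipeline produces the two agree
exactly and the former is several-fold faster.

## Longitudinal and group statistics

The rate of change of any variable over two visits is
`RoC = (Y(t2) - Y(t1)) / (t2 - t1)`, a per-year slope surrogate that makes
subjects with different inter-visit intervals comparable.

Group analyses use a 2x2 ANCOVA (ApoE4 carriage x MCI-to-AD progression
plus their interaction) with covariates (age, sex, education, scanner field
strength, handedness, gray-matter volume by default) and type-III sums of
squares under sum-to-zero contrasts - the convention that matters in
unbalanced covariate-adjusted designs. Outcomes pass a normality gate
first: Lilliefors at alpha = 0.05 decides whether to keep the raw scale,
log10-transform (positive data only), or rank-transform; if Levene's test
(mean-centered) across the four design cells still rejects homogeneity on
untransformed data the same fallback is applied. Effect sizes are
`omega^2 = (SS_eff - df_eff * MS_err) / (SS_tot + MS_err)`, clamped at
zero. Network size, connection density and mean degree are first tested for
group effects at alpha = 0.05 and added as covariates to the metric
ANCOVAs only when they differ - otherwise they would soak up the variance
the analysis is about.

Regional analyses run the same ANCOVA on nodal normalized clustering per
region, with regional gray-matter volume and mean nodal degree as extra
covariates, and correct across regions with Benjamini-Hochberg. The
family is all regions with data (the package does not restrict to a kept
subset). Associations between metrics and phenotypes use partial
correlations (residualize both variables on age, sex, education and TIV,
then correlate; t test on n - q - 2 df), and carrier-vs-noncarrier
differences in those correlations use the Fisher transform
`z = ln((1+r)/(1-r))/2` with
`Z = (z1 - z2) / sqrt(1/(n1-q-3) + 1/(n2-q-3))`.

Reliability is ICC(2,1): two-way random effects, absolute agreement,
single measure, with the Shrout-Fleiss F-based confidence interval. This
form penalizes systematic session shifts, which is the behavior wanted for
test-retest data; the package fixes this form rather than offering the
full ICC menu.

## The synthetic-data generator

The generator exists so that every stage is testable without any imaging
download. It emulates the two properties of segmented gray matter that the
cube-similarity method actually consumes:

1. **A curved tissue sheet.** Density is a Gaussian ribbon profile
   `exp(-(phi/tissue_width)^2)` around the zero level set of a smooth
   Gaussian random field `phi` (kernel SD = `smoothness` voxels, default 2;
   `tissue_width` 0.6 on the standardized field scale). Cubes on the sheet
   carry sharp, high-detail interface patterns that continue smoothly into
   neighboring cubes - the regime in which rotation-maximized similarity is
   informative. A plain smoothed-noise field does not work: every cube is
   then a near-linear gradient, the transform search aligns any two
   gradients, and the resulting graph is nearly complete with sigma = 1.
2. **Segmentation noise and background.** Multiplicative voxel noise
   (SD 3%) keeps distant cube pairs genuinely dissimilar, and densities
   below 0.02 are set to exactly zero so that tissue-free cubes are
   excluded by the zero-variance rule, exactly as off-brain cubes are in
   real data. `smoothness = 0` yields i.i.d. voxels - the pure-noise null
   volume used to verify false-positive control.

With the defaults, 30x30x30 volumes yield networks of ~950-990 nodes
(the package works at roughly 7x fewer nodes than clinical-resolution
volumes produce, preserving the topology regimes at desk scale), connection
densities around 30-40%, and sigma in the 1.1-1.4 range.

Cohorts cross ApoE4 carriage with progression (default 2 x 2 with equal
cells). Visit-2 volumes are visit-1 volumes times per-region atrophy
factors `1 - rate x weight x delta_t` plus fresh retest noise inside the
tissue mask (background stays zero), so the ground-truth rate of change is
known exactly. Atrophy defaults: 0.5%/year density loss for non-converters,
1.5%/year for converters, a 1.3x multiplier for carriers, with half the
atlas regions carrying the full rate and the rest half rate. The
carrier-linked covariance effect is an additive shift (+0.5 voxels) in
field smoothness, which measurably moves GConnect, sparsity and clustering.
Phenotypes (MMSE, a memory composite, CSF Abeta42/T-tau/P-tau) are drawn
around literature-plausible means, truncated to their assay ranges
(Abeta42 200-1700, T-tau 80-1300, P-tau 8-120 pg/ml), and linearly coupled
(default r = 0.4) to each subject's latent network driver - the
standardized smoothness deviation - so partial-correlation recovery is
testable. `effect_spec(zero = TRUE)` removes every group difference and
coupling while keeping the noise structure, for null calibration.

What the generator does *not* emulate: real cortical geometry and folding
statistics, MRI acquisition physics, segmentation bias, atrophy that
deforms rather than scales, and realistic inter-regional covariance
structure. Passing tests therefore demonstrate that the implementation is
correct and calibrated on data with known ground truth - not that the
scientific findings transfer to any particular clinical dataset.

## Numerical choices and degenerate inputs

* Empirical p-values use (b+1)/(m+1); the permutation null requires at
  least 100 draws (the default is 10,000) because the upper tail is
  unstable below that.
* Threshold ties are broken against the edge (strict inequality).
* `variance_eps = 0` exactly: only strictly constant cubes are excluded.
* Cube coordinates are 0-based with the cube grid anchored at the volume
  origin; trailing voxels that do not fill a cube are ignored.
* The transform set is not closed under composition of its 45-degree
  ring shifts (the generated group would be combinatorially huge), so
  exact similarity invariance under cube-wise relabeling holds for its 32
  rigid-symmetry members (90-degree rotations composed with reflections);
  this is the scope the test suite verifies.
* A degenerate permutation null (all values identical) is an error; an
  all-rejected BH family yields a complete graph; an empty rejection set
  yields an empty network.
* `icc()` flags constant data as undefined rather than returning 0/1.
* ANCOVA with a perfectly explained outcome (zero residual variance)
  reports F = 0, p = 1, omega^2 = 0 for all factor effects.
* Every stochastic step takes an explicit seed; one pipeline seed fans out
  to per-stage seeds through a fixed integer scheme, and the analysis
  stage of a retest comparison is seeded identically for both sessions, so
  reliability estimates reflect measurement noise rather than analysis
  Monte-Carlo noise.

## Problem sizes used by the test suite

The acceptance-grade checks run at: 50 pure-noise 30^3 volumes for
false-positive control; 20 structured 30^3 subjects for small-worldness;
15 subjects at 24^3 with 2%-noise retest volumes for reliability (ICC does
not depend on network size, so the smaller grid is used there); 500 null
simulations at n = 50/cell for ANCOVA calibration; 20 pipeline replicates
at 15^3 with n = 10/cell for power; and n = 50/cell at 12^3 for
rate-of-change recovery. These sizes are the package's desk-scale choices
and are stated here so results are interpreted at the scale they were
computed.

## Known limitations

Weighted-network variants, modularity and local efficiency are out of
scope. Volumes are assumed grid-aligned (no reorientation or reslicing).
The networks produced by the synthetic ribbon are denser than typical
clinical SSGMNets; the false-positive and small-world regimes are
preserved, but absolute attribute values should not be compared against
clinical cohorts. The two-visit rate of change is a local slope surrogate,
not a mixed-effects longitudinal model.
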