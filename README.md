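# ssgmnet

Single-subject gray-matter networks (SSGMNets) and the statistics that go
with them, for researchers studying how structural brain organization
changes in mild cognitive impairment and with ApoE4 genetic risk.

A SSGMNet is a graph built from one subject's gray-matter density volume:
the volume is tiled with non-overlapping 3×3×3-voxel cubes (the nodes), and
two cubes are connected when their density patterns are statistically
similar. Because the cortex is curved, the similarity of a cube pair is the
Pearson correlation maximized over rotations by multiples of 45° about each
axis combined with reflections over all axes. Edges are decided per subject
by a permutation null (random cube pairings with scrambled voxel order)
with Benjamini–Hochberg control at q = 0.05 over all N(N−1)/2 pairs, so
that at most 5% of connections are expected to be spurious.

From the binarized graph G = [N, K] the package computes the clustering
coefficient (Clux), characteristic path length (CharPath), global
efficiency (Eglobal), global connectivity (GConnect, the mean unthresholded
similarity), sparsity, and their normalizations against 20 degree-preserving
randomized reference networks:

    gamma = Clux / Clux_rand,  lambda = CharPath / CharPath_rand,
    sigma = gamma / lambda            (sigma > 1: small-world topology)

plus nodal normalized clustering aggregated over atlas regions. Two-visit
change is analyzed as a rate of change, RoC = ΔY/Δt, and group effects with
a 2×2 ANCOVA (ApoE4 × progression, type-III sums of squares, ω² effect
sizes, normality-gated transforms, Levene checks, post hocs), FDR across
regions, partial correlations with Fisher-z comparison between groups, and
ICC(2,1) test–retest reliability. A synthetic-data module generates
cortex-like density volumes, atlases, and two-visit cohorts with injected
group effects so the whole pipeline runs end to end with known ground
truth — no imaging downloads required.

## Worked example

```r
library(ssgmnet)

vol <- generate_gm_volume(c(30, 30, 30), smoothness = 2, seed = 1)
ex  <- extract_network(vol, n_perm = 10000, seed = 1)
ex$network
#> <binary_network> G=[N=974, K=188249], threshold 0.6525 (FDR q=0.05), sparsity 39.73%

m <- normalized_metrics(ex$network, sim = ex$similarity, n_rand = 20, seed = 1)
round(unlist(m[c("clux", "charpath", "eglobal", "gconnect",
                 "sparsity", "gamma", "lambda", "sigma")]), 3)
#>     clux charpath  eglobal gconnect sparsity    gamma   lambda    sigma
#>    0.722    1.680    0.686    0.590   39.727    1.311    1.047    1.252
```

Of the 1000 candidate cubes, 974 had nonzero density variance and became
nodes; the permutation-null FDR threshold landed at r = 0.6525. Clustering
is 31% above the degree-matched random reference (gamma = 1.311) while path
length is only 5% longer (lambda = 1.047), giving sigma = 1.252 > 1 — the
small-world signature expected of gray-matter networks.

Comparing two partial correlations (e.g. a metric–phenotype association in
carriers vs non-carriers):

```r
cc <- compare_correlations(0.5, 103, 0.0, 103, q = 0)
sprintf("Z = %.3f, p = %.4f", cc$Z, cc$p)
#> "Z = 3.884, p = 0.0001"
```

`run_pipeline()` (or the `inst/cli/ssgmnet` script) drives
simulate → extract → metrics → stats from one YAML config with a single
seed and writes CSV tables plus a checksummed JSON manifest; re-running an
unchanged config reproduces identical checksums.

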