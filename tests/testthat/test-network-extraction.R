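test_that("cube parcellation tiles the grid and excludes constant cubes", {
  v <- tiny_volume(c(30, 30, 30), smoothness = 2, seed = 3)
  cs <- parcellate_cubes(v)
  expect_equal(nrow(cs$values), 1000L)
  expect_equal(ncol(cs$values), 27L)
  expect_true(all(cs$origins %% 3 == 0))
  expect_true(!anyDuplicated(cs$origins))

  # trailing voxels are ignored: (31,31,31) still gives 10^3 cubes
  v31 <- tiny_volume(c(31, 31, 31), smoothness = 2, seed = 3)
  expect_equal(nrow(parcellate_cubes(v31)$values), 1000L)

  # forcing one cube constant excludes exactly that node
  d <- v$data
  d[1:3, 1:3, 1:3] <- 0.4
  vc <- gm_volume(d)
  csc <- parcellate_cubes(vc)
  expect_false(csc$kept_mask[1])
  expect_equal(sum(!csc$kept_mask), sum(!cs$kept_mask) + 1L -
                 as.integer(!cs$kept_mask[1]))

  expect_error(parcellate_cubes(v, cube_size = 1), ">= 2")
})

test_that("transform set is a duplicate-free group of bijections with identity", {
  tr <- build_transforms()
  expect_false(anyDuplicated(tr) > 0)
  expect_true(any(apply(tr, 1, function(p) all(p == 1:27))))
  # every row is a permutation of 1:27 ...
  expect_true(all(apply(tr, 1, function(p) identical(sort(p), 1:27))))
  # ... whose inverse is itself a valid permutation (bijectivity by enumeration)
  for (k in seq_len(nrow(tr))) {
    inv <- order(tr[k, ])
    expect_identical(sort(inv), 1:27)
  }
  # applying any transform leaves the multiset of values unchanged
  x <- rnorm(27)
  for (k in sample(nrow(tr), 10)) {
    expect_equal(sort(x[tr[k, ]]), sort(x))
  }
})

test_that("max similarity is exact for self and transform-images, and matches brute force", {
  tr <- build_transforms()
  set.seed(7)
  cube <- rnorm(27)
  expect_equal(max_similarity(cube, cube, tr), 1)
  # a transform-image of the cube is recovered by the maximization
  img <- cube[tr[17, ]]
  expect_equal(max_similarity(cube, img, tr), 1)

  for (i in 1:100) {
    a <- rnorm(27); b <- rnorm(27)
    expect_equal(max_similarity(a, b, tr), oracle_max_similarity(a, b, tr),
                 tolerance = 1e-12)
  }
  expect_error(max_similarity(rep(1, 27), cube, tr), "zero-variance")
})

test_that("similarity matrix is symmetric and matches the pairwise oracle", {
  v <- tiny_volume(c(9, 9, 27), smoothness = 1.5, seed = 5)
  cs <- parcellate_cubes(v)
  cs$kept_mask[-(1:10)] <- FALSE  # keep a 10-node instance
  tr <- build_transforms()
  sm <- similarity_matrix(cs, tr)
  expect_identical(sm$values, t(sm$values))
  expect_true(all(diag(sm$values) == 0))
  expect_true(all(abs(sm$values) <= 1))
  V <- cs$values[1:10, ]
  for (i in 1:9) for (j in (i + 1):10) {
    expect_equal(sm$values[i, j], oracle_max_similarity(V[i, ], V[j, ], tr),
                 tolerance = 1e-12)
  }
})

test_that("cube-wise relabeling by a rigid cube symmetry leaves similarities unchanged", {
  # exact invariance holds for the members that are rigid symmetries of the
  # cube (90-degree rotations and reflections): conjugation by those maps
  # the transform set onto itself
  tr <- build_transforms()
  coords <- as.matrix(expand.grid(x = 0:2, y = 0:2, z = 0:2))
  dist0 <- as.matrix(dist(coords))
  is_isometry <- apply(tr, 1, function(p) {
    isTRUE(all.equal(as.matrix(dist(coords[p, ])), dist0,
                     check.attributes = FALSE))
  })
  # 4 single-axis rotation classes x 8 reflections = 32 rigid symmetries
  expect_equal(sum(is_isometry), 32L)

  v <- tiny_volume(c(9, 9, 18), smoothness = 1.5, seed = 9)
  cs <- parcellate_cubes(v)
  sm <- similarity_matrix(cs, tr)
  for (k in sample(which(is_isometry), 5)) {
    csr <- cs
    csr$values <- cs$values[, tr[k, ]]
    smr <- similarity_matrix(csr, tr)
    expect_equal(smr$values, sm$values, tolerance = 1e-12)
  }
})

test_that("permutation null is seeded, bounded, and matches the i.i.d. regime", {
  v <- tiny_volume(c(15, 15, 15), smoothness = 0, seed = 2)
  cs <- parcellate_cubes(v)
  tr <- build_transforms()
  ns1 <- permutation_null(cs, tr, n_perm = 500, seed = 42)
  ns2 <- permutation_null(cs, tr, n_perm = 500, seed = 42)
  expect_identical(ns1, ns2)
  expect_true(all(ns1 >= -1 & ns1 <= 1))
  expect_error(permutation_null(cs, tr, n_perm = 50, seed = 1), ">= 100")

  # on i.i.d. volumes the null should look like the observed similarities
  ks_p <- vapply(1:5, function(s) {
    vv <- tiny_volume(c(15, 15, 15), smoothness = 0, seed = s)
    cc <- parcellate_cubes(vv)
    sm <- similarity_matrix(cc, tr)
    obs <- sm$values[upper.tri(sm$values)]
    nul <- permutation_null(cc, tr, n_perm = 2000, seed = s + 100)
    suppressWarnings(stats::ks.test(obs, nul)$p.value)
  }, numeric(1))
  expect_gt(median(ks_p), 0.01)
})

test_that("FDR binarization matches a hand-run BH procedure and controls edges", {
  # hand-built 6-node instance with a 20-value null
  S <- matrix(0, 6, 6)
  vals <- c(0.92, 0.15, 0.40, 0.88, 0.05, 0.61, 0.33, 0.92, 0.74, 0.21,
            0.52, 0.92, 0.66, 0.08, 0.85)
  S[upper.tri(S)] <- vals
  S <- S + t(S)
  sim <- structure(list(values = S, origins = matrix(0L, 6, 3), kept = 1:6,
                        n_candidates = 6L), class = "similarity_matrix")
  null20 <- seq(0.025, 0.975, by = 0.05)
  net <- fdr_binarize(sim, null20, q = 0.25)
  # independent BH walk-through on the (b+1)/(m+1) p-values
  p <- (sapply(vals, function(r) sum(null20 >= r)) + 1) / 21
  rej <- oracle_bh_reject(p, 0.25)
  expect_equal(net$adjacency[upper.tri(net$adjacency)], as.integer(rej))
  expect_equal(net$n_edges, sum(rej))
  expect_identical(net$adjacency, t(net$adjacency))
  expect_true(all(diag(net$adjacency) == 0))

  # all observed below the null floor -> empty network
  sim0 <- sim
  sim0$values <- S * 0.001
  expect_equal(fdr_binarize(sim0, null20 + 0.02, q = 0.05)$n_edges, 0)

  # raising q never removes an edge
  net_lo <- fdr_binarize(sim, null20, q = 0.10)
  net_hi <- fdr_binarize(sim, null20, q = 0.40)
  expect_true(all(net_hi$adjacency >= net_lo$adjacency))

  expect_error(fdr_binarize(sim, rep(0.5, 10)), "degenerate")
})

test_that("end-to-end extraction is deterministic and reports network size", {
  v <- tiny_volume(c(15, 15, 15), smoothness = 2, seed = 4)
  ex1 <- extract_network(v, n_perm = 500, seed = 11)
  ex2 <- extract_network(v, n_perm = 500, seed = 11)
  expect_identical(ex1$network$adjacency, ex2$network$adjacency)
  expect_equal(ex1$info$network_size, sum(parcellate_cubes(v)$kept_mask))
  expect_equal(ex1$info$sparsity,
               100 * 2 * ex1$info$n_edges /
                 (ex1$info$network_size * (ex1$info$network_size - 1)))
})

test_that("structured volumes give connected networks with no isolated nodes", {
  for (s in 1:3) {
    v <- generate_gm_volume(c(30, 30, 30), smoothness = 2, seed = s)
    ex <- extract_network(v, n_perm = 2000, seed = s)
    g <- igraph::graph_from_adjacency_matrix(ex$network$adjacency,
                                             mode = "undirected")
    expect_true(igraph::is_connected(g))
    expect_equal(sum(igraph::degree(g) == 0), 0)
  }
})
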