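test_that("clustering handles the canonical graphs and matches triangle enumeration", {
  K4 <- matrix(1L, 4, 4); diag(K4) <- 0L
  expect_equal(clustering_coef(K4)$nodal, rep(1, 4))
  expect_equal(clustering_coef(K4)$mean, 1)

  star <- matrix(0L, 5, 5)
  star[1, 2:5] <- 1L; star <- star + t(star)
  expect_equal(clustering_coef(star)$nodal, rep(0, 5))

  set.seed(61)
  for (i in 1:100) {
    A <- random_adjacency(15, runif(1, 0.1, 0.6))
    expect_equal(clustering_coef(A)$nodal, oracle_clustering(A),
                 tolerance = 1e-12)
  }
})

test_that("characteristic path length matches Floyd-Warshall and flags disconnection", {
  K4 <- matrix(1L, 4, 4); diag(K4) <- 0L
  expect_equal(char_path_length(K4)$length, 1)

  P3 <- matrix(0L, 3, 3); P3[1, 2] <- P3[2, 3] <- 1L; P3 <- P3 + t(P3)
  expect_equal(char_path_length(P3)$length, 4 / 3)

  set.seed(62)
  hit_disconnected <- FALSE
  for (i in 1:50) {
    A <- random_adjacency(15, runif(1, 0.1, 0.5))
    res <- char_path_length(A)
    expect_equal(res$length, oracle_charpath(A), tolerance = 1e-12)
    if (res$disconnected) hit_disconnected <- TRUE
  }
  # a two-component graph is flagged
  two <- matrix(0L, 4, 4); two[1, 2] <- two[3, 4] <- 1L; two <- two + t(two)
  expect_true(char_path_length(two)$disconnected)

  # harmonic convention: reciprocal of the mean inverse distance, finite on
  # disconnected graphs and equal to 1/Eglobal by construction
  expect_equal(char_path_length(K4, convention = "harmonic")$length, 1)
  set.seed(71)
  B <- random_adjacency(12, 0.25)
  expect_equal(char_path_length(B, convention = "harmonic")$length,
               1 / global_efficiency(B), tolerance = 1e-12)
})

test_that("global efficiency and sparsity match enumeration oracles", {
  K4 <- matrix(1L, 4, 4); diag(K4) <- 0L
  expect_equal(global_efficiency(K4), 1)
  expect_equal(sparsity(K4), 100)
  iso2 <- matrix(0L, 2, 2)
  expect_equal(global_efficiency(iso2), 0)
  empty10 <- matrix(0L, 10, 10)
  expect_equal(sparsity(empty10), 0)

  set.seed(63)
  for (i in 1:50) {
    A <- random_adjacency(15, runif(1, 0.05, 0.6))
    expect_equal(global_efficiency(A), oracle_efficiency(A), tolerance = 1e-12)
    expect_equal(sparsity(A), oracle_sparsity(A), tolerance = 1e-12)
  }
})

test_that("global connectivity is the mean off-diagonal similarity", {
  S <- matrix(0.5, 8, 8); diag(S) <- 0
  expect_equal(global_connectivity(S), 0.5)
  Sa <- matrix(0, 4, 4)
  Sa[upper.tri(Sa)] <- c(0.3, -0.3, 0.3, -0.3, 0.3, -0.3)
  Sa <- Sa + t(Sa)
  expect_equal(global_connectivity(Sa), 0)
  set.seed(64)
  R <- matrix(rnorm(100), 10); R <- (R + t(R)) / 2; diag(R) <- 0
  expect_equal(global_connectivity(R), mean(R[row(R) != col(R)]),
               tolerance = 1e-12)
})

test_that("degree-preserving randomization keeps degrees and breaks lattice clustering", {
  set.seed(65)
  for (i in 1:20) {
    A <- random_adjacency(20, 0.3)
    ref <- randomize_preserving_degree(A, seed = i)
    expect_equal(rowSums(ref$adjacency), rowSums(A))
    expect_equal(sum(ref$adjacency), sum(A))
    expect_true(all(diag(ref$adjacency) == 0))
  }
  # ring lattice N=50, k=4: clustering 0.5; randomization should at least halve it
  L <- matrix(0L, 50, 50)
  for (i in 1:50) for (s in 1:2) {
    j <- (i + s - 1) %% 50 + 1
    L[i, j] <- L[j, i] <- 1L
  }
  expect_equal(clustering_coef(L)$mean, 0.5, tolerance = 1e-12)
  refs <- vapply(1:5, function(s)
    clustering_coef(randomize_preserving_degree(L, seed = s)$adjacency)$mean,
    numeric(1))
  expect_lt(mean(refs), 0.25)
})

test_that("normalization behaves on its own null and detects small worlds", {
  set.seed(66)
  er <- igraph::sample_gnp(200, 0.05)
  A <- as.matrix(igraph::as_adjacency_matrix(er, sparse = FALSE))
  storage.mode(A) <- "integer"
  m <- normalized_metrics(A, n_rand = 20, seed = 1)
  expect_gt(m$gamma, 0.8); expect_lt(m$gamma, 1.2)
  expect_gt(m$lambda, 0.9); expect_lt(m$lambda, 1.1)
  expect_equal(m$sigma, m$gamma / m$lambda, tolerance = 1e-15)

  ws <- igraph::simplify(igraph::sample_smallworld(1, 200, 4, 0.1))
  W <- as.matrix(igraph::as_adjacency_matrix(ws, sparse = FALSE))
  storage.mode(W) <- "integer"
  expect_gt(normalized_metrics(W, n_rand = 20, seed = 2)$sigma, 1)
})

test_that("global metrics are invariant under node relabeling", {
  set.seed(67)
  A <- random_adjacency(25, 0.25)
  p <- sample(25)
  B <- A[p, p]
  expect_equal(clustering_coef(B)$mean, clustering_coef(A)$mean, tolerance = 1e-12)
  expect_equal(char_path_length(B)$length, char_path_length(A)$length,
               tolerance = 1e-12)
  expect_equal(global_efficiency(B), global_efficiency(A), tolerance = 1e-12)
  expect_equal(sparsity(B), sparsity(A), tolerance = 1e-12)
})

test_that("adding an edge never hurts efficiency or lengthens paths", {
  set.seed(68)
  for (i in 1:10) {
    A <- random_adjacency(12, 0.45)
    if (char_path_length(A)$disconnected) next
    off <- which(A == 0L & upper.tri(A))
    if (!length(off)) next
    pick <- sample(off, 1)
    B <- A
    B[pick] <- 1L
    B[cbind(col(A)[pick], row(A)[pick])] <- 1L
    expect_gte(global_efficiency(B), global_efficiency(A))
    expect_lte(char_path_length(B)$length, char_path_length(A)$length)
  }
})

test_that("nodal normalized clustering composes clustering with the scalar reference", {
  set.seed(69)
  A <- random_adjacency(30, 0.3)
  nn <- nodal_normalized_clustering(A, n_rand = 5, seed = 3)
  refs <- ssgmnet:::reference_stats(A, 5, 3)
  expect_equal(nn$nodal_clux_normalized,
               clustering_coef(A)$nodal / refs$clux_rand, tolerance = 1e-12)

  star <- matrix(0L, 6, 6); star[1, 2:6] <- 1L; star <- star + t(star)
  nn_star <- nodal_normalized_clustering(star, n_rand = 3, seed = 1)
  expect_true(nn_star$undefined || all(nn_star$nodal_clux_normalized == 0))
})

test_that("regional aggregation averages by cube-center label and flags empty regions", {
  # single-region atlas: regional value = mean over all nodes
  atlas1 <- generate_atlas(c(12, 12, 12), 1)
  origins <- as.matrix(expand.grid(x = c(0, 3, 6, 9), y = c(0, 3, 6, 9),
                                   z = c(0, 3, 6, 9)))
  set.seed(70)
  nodal <- rnorm(nrow(origins))
  agg1 <- aggregate_regional(nodal, origins, atlas1)
  expect_equal(agg1$value, mean(nodal))

  # two-region split along x with hand-computed means
  labs <- array(1L, dim = c(12, 12, 12)); labs[7:12, , ] <- 2L
  atlas2 <- gm_atlas(labs)
  agg2 <- aggregate_regional(nodal, origins, atlas2)
  centers_x <- origins[, 1] + 1  # 0-based center voxel x
  in1 <- centers_x + 1 <= 6
  expect_equal(agg2$value[1], mean(nodal[in1]))
  expect_equal(agg2$value[2], mean(nodal[!in1]))
  expect_equal(agg2$n_cubes, c(sum(in1), sum(!in1)))

  # a region with no cube centers is NA, not zero
  labs3 <- labs; labs3[12, 12, 12] <- 3L
  agg3 <- aggregate_regional(nodal, origins, gm_atlas(labs3))
  expect_true(is.na(agg3$value[agg3$region == 3]))
})
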