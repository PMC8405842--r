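# Global and nodal graph-topology attributes of binary networks, with
# normalization against degree-preserving randomized reference networks.
# Graph primitives are delegated to igraph; conventions (degree<2 nodes get
# clustering 0, characteristic path over reachable pairs, ordered-pair
# sparsity denominator) are fixed here.

as_igraph <- function(net) {
  A <- adjacency_of(net)
  igraph::graph_from_adjacency_matrix(A, mode = "undirected", diag = FALSE)
}

adjacency_of <- function(net) {
  A <- if (inherits(net, "binary_network")) net$adjacency else net
  if (!is.matrix(A) || nrow(A) != ncol(A)) {
    stop("expected a square adjacency matrix or binary_network", call. = FALSE)
  }
  if (!isTRUE(all.equal(A, t(A)))) stop("adjacency must be symmetric", call. = FALSE)
  if (any(A != 0L & A != 1L)) stop("adjacency must be binary", call. = FALSE)
  if (any(diag(A) != 0L)) stop("adjacency must have a zero diagonal", call. = FALSE)
  A
}

# All-pairs shortest-path matrix of a binary undirected graph. For the
# dense, small-diameter graphs this package produces, successive Boolean
# matrix products (BLAS) reach all pairs in a few steps and beat repeated
# BFS; graphs that have not converged after `max_step` products fall back
# to igraph's BFS distances.
graph_distances <- function(A, max_step = 12L) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A == 1L] <- 1
  diag(D) <- 0
  reach <- A == 1L
  diag(reach) <- TRUE
  cur <- A * 1
  k <- 1L
  while (any(!reach)) {
    k <- k + 1L
    if (k > max_step) {
      g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                               diag = FALSE)
      return(igraph::distances(g))
    }
    cur <- (cur %*% A > 0) * 1
    new <- cur > 0 & !reach
    if (!any(new)) break  # remaining pairs are unreachable
    D[new] <- k
    reach <- reach | new
  }
  D
}

#' Local clustering coefficients (Clux)
#'
#' Watts-Strogatz local clustering: the fraction of a node's neighbor pairs
#' that are themselves connected. Nodes with degree < 2 get 0.
#'
#' @param net A [fdr_binarize()] result or symmetric 0/1 adjacency matrix.
#' @return A list with `nodal` (per-node coefficients) and `mean` (Clux).
#' @export
clustering_coef <- function(net) {
  g <- as_igraph(net)
  cc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  cc[is.nan(cc)] <- 0
  list(nodal = cc, mean = mean(cc))
}

#' Characteristic path length (CharPath)
#'
#' Mean shortest-path length (in edges) over all ordered pairs of distinct
#' nodes. With the default `"reachable"` convention, a disconnected graph's
#' mean is taken over reachable pairs only and the result is flagged; the
#' `"harmonic"` convention instead returns the harmonic mean
#' (the reciprocal of the mean inverse distance, unreachable pairs
#' contributing 0), which is finite on disconnected graphs.
#'
#' @inheritParams clustering_coef
#' @param convention `"reachable"` (default) or `"harmonic"`.
#' @return A list with `length` and `disconnected` (logical flag).
#' @export
char_path_length <- function(net, convention = c("reachable", "harmonic")) {
  convention <- match.arg(convention)
  A <- adjacency_of(net)
  D <- graph_distances(A)
  diag(D) <- NA
  reachable <- is.finite(D)
  disconnected <- any(!reachable & !is.na(D))
  if (convention == "harmonic") {
    inv <- 1 / D[!is.na(D)]
    return(list(length = 1 / mean(inv), disconnected = disconnected))
  }
  vals <- D[reachable & !is.na(D)]
  if (length(vals) == 0L) {
    return(list(length = NA_real_, disconnected = TRUE))
  }
  list(length = mean(vals), disconnected = disconnected)
}

#' Global efficiency (Eglobal)
#'
#' Mean over ordered pairs of distinct nodes of the inverse shortest-path
#' length; unreachable pairs contribute 0.
#'
#' @inheritParams clustering_coef
#' @return A scalar in \[0, 1\].
#' @export
global_efficiency <- function(net) {
  A <- adjacency_of(net)
  n <- nrow(A)
  if (n < 2L) stop("need at least 2 nodes", call. = FALSE)
  D <- graph_distances(A)
  diag(D) <- Inf
  mean(1 / D[row(D) != col(D)])
}

#' Global connectivity (GConnect)
#'
#' Mean of all off-diagonal entries of the unthresholded similarity matrix:
#' the binary matrix no longer contains correlations, so the mean is taken
#' before thresholding.
#'
#' @param sim A [similarity_matrix()] or symmetric numeric matrix.
#' @return Mean off-diagonal correlation.
#' @export
global_connectivity <- function(sim) {
  S <- if (inherits(sim, "similarity_matrix")) sim$values else sim
  if (!is.matrix(S) || nrow(S) != ncol(S)) stop("expected a square matrix", call. = FALSE)
  mean(S[row(S) != col(S)])
}

#' Network sparsity (connection density, %)
#'
#' 100 times the number of ordered connected pairs over the `N(N-1)`
#' possible ordered pairs, i.e. `100 * 2K / (N(N-1))`.
#'
#' @inheritParams clustering_coef
#' @return Percentage in \[0, 100\].
#' @export
sparsity <- function(net) {
  A <- adjacency_of(net)
  n <- nrow(A)
  if (n < 2L) stop("need at least 2 nodes", call. = FALSE)
  100 * sum(A) / (n * (n - 1))
}

#' Degree-preserving randomized reference network
#'
#' Maslov-Sneppen double-edge swaps: repeatedly rewires pairs of edges while
#' forbidding self-loops and multi-edges, leaving the degree sequence exactly
#' unchanged. Used to build null references for gamma/lambda/sigma.
#'
#' @inheritParams clustering_coef
#' @param n_swaps Number of attempted swaps; default `10 * K` (a standard
#'   mixing heuristic).
#' @param seed Integer seed.
#' @return A `binary_network` with the randomized adjacency; `swap_failed`
#'   is TRUE when the graph admits no swap and is returned unchanged.
#' @export
randomize_preserving_degree <- function(net, n_swaps = NULL, seed = NULL) {
  A <- adjacency_of(net)
  K <- sum(A) / 2
  if (K < 2) {
    out <- list(adjacency = A, threshold_used = NA_real_, fdr_q = NA_real_,
                n_edges = K, swap_failed = TRUE)
    class(out) <- "binary_network"
    return(out)
  }
  if (is.null(n_swaps)) n_swaps <- 10 * K
  ut <- which(upper.tri(A) & A == 1L, arr.ind = TRUE)
  edges <- with_seed(seed, ms_rewire_cpp(ut - 1L, nrow(A), n_swaps))
  A2 <- matrix(0L, nrow(A), ncol(A))
  A2[edges + 1L] <- 1L
  A2[edges[, 2:1] + 1L] <- 1L
  structure(
    list(adjacency = A2, threshold_used = NA_real_, fdr_q = NA_real_,
         n_edges = sum(A2) / 2, swap_failed = identical(A2, A) && K > 2),
    class = "binary_network"
  )
}

#' Global metrics with random-reference normalization
#'
#' Computes Clux, CharPath, Eglobal, sparsity, mean degree and network size,
#' builds `n_rand` degree-preserving randomized reference networks, and
#' reports `clux_rand`/`charpath_rand` (means over the references), the
#' normalized ratios `gamma = clux/clux_rand`, `lambda =
#' charpath/charpath_rand`, and the small-world coefficient
#' `sigma = gamma/lambda`.
#'
#' @inheritParams clustering_coef
#' @param sim Optional [similarity_matrix()] supplying GConnect.
#' @param n_rand Number of reference networks (default 20).
#' @param seed Integer seed driving all randomizations.
#' @return A one-row data frame of class `global_metrics` with columns
#'   `size`, `n_edges`, `sparsity`, `mean_degree`, `clux`, `charpath`,
#'   `eglobal`, `gconnect`, `clux_rand`, `charpath_rand`, `gamma`, `lambda`,
#'   `sigma`, `disconnected`.
#' @export
normalized_metrics <- function(net, sim = NULL, n_rand = 20L, seed = NULL) {
  A <- adjacency_of(net)
  n <- nrow(A)
  cl <- clustering_coef(A)
  cp <- char_path_length(A)
  refs <- reference_stats(A, n_rand, seed)
  gamma <- cl$mean / refs$clux_rand
  lambda <- cp$length / refs$charpath_rand
  out <- data.frame(
    size = n, n_edges = sum(A) / 2, sparsity = sparsity(A),
    mean_degree = mean(rowSums(A)),
    clux = cl$mean, charpath = cp$length, eglobal = global_efficiency(A),
    gconnect = if (is.null(sim)) NA_real_ else global_connectivity(sim),
    clux_rand = refs$clux_rand, charpath_rand = refs$charpath_rand,
    gamma = gamma, lambda = lambda, sigma = gamma / lambda,
    disconnected = cp$disconnected
  )
  class(out) <- c("global_metrics", "data.frame")
  out
}

reference_stats <- function(A, n_rand, seed) {
  cl_r <- numeric(n_rand)
  cp_r <- numeric(n_rand)
  for (b in seq_len(n_rand)) {
    ref <- randomize_preserving_degree(A, seed = derive_seed(seed, b))
    cl_r[b] <- clustering_coef(ref$adjacency)$mean
    cp_r[b] <- char_path_length(ref$adjacency)$length
  }
  list(clux_rand = mean(cl_r), charpath_rand = mean(cp_r))
}

#' Nodal normalized clustering
#'
#' Each node's local clustering divided by the scalar `clux_rand` (the mean
#' clustering of the degree-preserving reference networks).
#'
#' @inheritParams normalized_metrics
#' @return A list with `nodal_clux`, `nodal_clux_normalized`, `degree`,
#'   `clux_rand`, and `undefined` (TRUE when `clux_rand` is 0).
#' @export
nodal_normalized_clustering <- function(net, n_rand = 20L, seed = NULL) {
  A <- adjacency_of(net)
  cl <- clustering_coef(A)
  refs <- reference_stats(A, n_rand, seed)
  undefined <- refs$clux_rand == 0
  list(
    nodal_clux = cl$nodal,
    nodal_clux_normalized = if (undefined) rep(NA_real_, length(cl$nodal))
                            else cl$nodal / refs$clux_rand,
    degree = rowSums(A),
    clux_rand = refs$clux_rand,
    undefined = undefined
  )
}

#' Aggregate nodal values into atlas regions
#'
#' Assigns each cube node to the region whose label covers the cube's center
#' voxel, then averages the nodal values per region. Regions containing no
#' cube centers are reported as missing (`NA`), not zero.
#'
#' @param nodal Numeric vector of per-node values (e.g.
#'   `nodal_clux_normalized`).
#' @param cube_origins Integer matrix of 0-based cube lower corners, as in a
#'   `similarity_matrix`/`cube_set`.
#' @param atlas A [gm_atlas()] on the same voxel grid.
#' @param cube_size Cube edge length used at parcellation.
#' @return A data frame with `region` (label), `region_name`, `value`
#'   (mean nodal value, NA when empty), `n_cubes`.
#' @export
aggregate_regional <- function(nodal, cube_origins, atlas, cube_size = 3L) {
  stopifnot(inherits(atlas, "gm_atlas"))
  if (nrow(cube_origins) != length(nodal)) {
    stop("`nodal` and `cube_origins` disagree in length", call. = FALSE)
  }
  d <- dim(atlas$labels)
  centers <- cube_origins + cube_size %/% 2L  # 0-based center voxel
  if (any(centers >= matrix(d, nrow(centers), 3, byrow = TRUE))) {
    stop("cube centers fall outside the atlas grid", call. = FALSE)
  }
  lab <- atlas$labels[centers + 1L]
  ids <- sort(as.integer(names(atlas$region_names)))
  agg <- vapply(ids, function(id) {
    sel <- lab == id
    if (!any(sel)) NA_real_ else mean(nodal[sel])
  }, numeric(1))
  counts <- vapply(ids, function(id) sum(lab == id), integer(1))
  data.frame(
    region = ids,
    region_name = unname(atlas$region_names[as.character(ids)]),
    value = agg, n_cubes = counts,
    stringsAsFactors = FALSE
  )
}
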