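# SSGMNet extraction: cube parcellation, rotation/reflection-maximized
# similarity, permutation-null threshold, FDR binarization.

#' Parcellate a volume into cube nodes
#'
#' Tiles the volume with non-overlapping axis-aligned cubes of
#' `cube_size^3` voxels anchored at the volume origin (0-based voxel
#' coordinates); trailing voxels that do not fill a cube are ignored. Cubes
#' whose density variance is at or below `variance_eps` are flagged excluded
#' (their Pearson correlation would be undefined).
#'
#' @param volume A [gm_volume()].
#' @param cube_size Cube edge length in voxels (>= 2; default 3, i.e. 27
#'   voxels per node).
#' @param variance_eps Variance at or below which a cube is excluded
#'   (default 0: only exactly-constant cubes are dropped).
#' @return An object of class `cube_set`: `origins` (n x 3 matrix, 0-based
#'   lower corners), `values` (n x cube_size^3 matrix, column-major voxel
#'   order within the cube), `kept_mask` (logical), `cube_size`.
#' @export
parcellate_cubes <- function(volume, cube_size = 3L, variance_eps = 0) {
  stopifnot(inherits(volume, "gm_volume"))
  cube_size <- as.integer(cube_size)
  if (cube_size < 2L) stop("`cube_size` must be >= 2", call. = FALSE)
  d <- dim(volume$data)
  if (any(d < cube_size)) {
    stop("volume smaller than one cube along some axis", call. = FALSE)
  }
  ncube <- d %/% cube_size
  starts <- lapply(ncube, function(n) (seq_len(n) - 1L) * cube_size + 1L)
  n <- prod(ncube)

  # values: one column per within-cube offset (column-major offset order),
  # one row per cube (column-major cube order)
  m <- cube_size^3
  values <- matrix(0, nrow = n, ncol = m)
  offs <- as.matrix(expand.grid(a = 0:(cube_size - 1L), b = 0:(cube_size - 1L),
                                c = 0:(cube_size - 1L)))
  for (o in seq_len(m)) {
    values[, o] <- as.vector(volume$data[starts[[1]] + offs[o, 1],
                                         starts[[2]] + offs[o, 2],
                                         starts[[3]] + offs[o, 3]])
  }
  grid <- as.matrix(expand.grid(i = starts[[1]], j = starts[[2]], k = starts[[3]]))
  origins <- grid - 1L  # 0-based lower corners

  v <- apply(values, 1L, var)
  structure(
    list(origins = origins, values = values, kept_mask = v > variance_eps,
         cube_size = cube_size, volume_dim = d),
    class = "cube_set"
  )
}

#' @export
print.cube_set <- function(x, ...) {
  cat(sprintf("<cube_set> %d candidate cubes of %d voxels, %d kept\n",
              nrow(x$values), ncol(x$values), sum(x$kept_mask)))
  invisible(x)
}

#' Enumerate within-cube rotation and reflection permutations
#'
#' The similarity between two cube nodes is maximized over grid rotations by
#' multiples of 45 degrees about each axis combined with reflections over all
#' axes, so that similar but differently oriented patches of cortex are not
#' penalized. On a 3x3x3 grid a 45-degree rotation about an axis is realized
#' exactly as a one-step cyclic shift of the 8-voxel perimeter ring of each
#' plane perpendicular to that axis (plane centers fixed). The returned set
#' is the deduplicated composition of the 24 single-axis ring rotations with
#' the 8 axis reflections, and always contains the identity.
#'
#' @return An integer matrix with one row per transform and 27 columns; row
#'   `t` is a permutation `p` of `1:27` such that `values[p]` is the
#'   transformed cube (column-major voxel order).
#' @export
build_transforms <- function() {
  coords <- as.matrix(expand.grid(x = 0:2, y = 0:2, z = 0:2))
  lin <- function(xyz) 1L + xyz[, 1] + 3L * xyz[, 2] + 9L * xyz[, 3]

  # perimeter ring of a 3x3 plane, in circular order; center is (1,1)
  ring <- rbind(c(0, 0), c(0, 1), c(0, 2), c(1, 2), c(2, 2),
                c(2, 1), c(2, 0), c(1, 0))
  ring_key <- ring[, 1] * 3 + ring[, 2]

  rotate_coords <- function(xyz, axis, k) {
    free <- setdiff(1:3, axis)
    uv <- xyz[, free, drop = FALSE]
    out <- xyz
    key <- uv[, 1] * 3 + uv[, 2]
    idx <- match(key, ring_key)        # NA for plane centers
    mov <- !is.na(idx)
    new_uv <- ring[((idx[mov] - 1L + k) %% 8L) + 1L, , drop = FALSE]
    out[mov, free] <- new_uv
    out
  }
  reflect_coords <- function(xyz, flips) {
    out <- xyz
    for (a in which(flips)) out[, a] <- 2L - out[, a]
    out
  }

  perms <- list()
  seen <- character()
  add <- function(newcoords) {
    # transformed[lin(new)] = values[lin(old)]  =>  perm[lin(new)] = lin(old)
    p <- integer(27)
    p[lin(newcoords)] <- lin(coords)
    key <- paste(p, collapse = ",")
    if (!key %in% seen) {
      seen[[length(seen) + 1L]] <<- key
      perms[[length(perms) + 1L]] <<- p
    }
  }
  flipset <- as.matrix(expand.grid(c(FALSE, TRUE), c(FALSE, TRUE), c(FALSE, TRUE)))
  for (axis in 1:3) {
    for (k in 0:7) {
      rc <- rotate_coords(coords, axis, k)
      for (f in seq_len(nrow(flipset))) {
        add(reflect_coords(rc, flipset[f, ]))
      }
    }
  }
  do.call(rbind, perms)
}

#' Maximal rotation/reflection-invariant similarity between two cubes
#'
#' Pearson correlation between a seed and a target cube, maximized over the
#' transform set applied to the seed in both orderings (seed-to-target and
#' target-to-seed), which guarantees symmetry.
#'
#' @param seed_values,target_values Numeric vectors of length 27 with
#'   nonzero variance.
#' @param transforms Permutation matrix from [build_transforms()].
#' @return The maximal correlation, a scalar in \[-1, 1\].
#' @export
max_similarity <- function(seed_values, target_values,
                           transforms = build_transforms()) {
  if (length(seed_values) != ncol(transforms) ||
      length(target_values) != ncol(transforms)) {
    stop("cube value vectors must match the transform length", call. = FALSE)
  }
  if (var(seed_values) == 0 || var(target_values) == 0) {
    stop("zero-variance cube: correlation undefined", call. = FALSE)
  }
  zs <- standardize_rows(matrix(seed_values, nrow = 1))
  zt <- standardize_rows(matrix(target_values, nrow = 1))
  best <- -1
  for (t in seq_len(nrow(transforms))) {
    p <- transforms[t, ]
    best <- max(best, sum(zs[1, p] * zt[1, ]), sum(zt[1, p] * zs[1, ]))
  }
  min(1, best)
}

# center and scale rows to unit sum of squares, so tcrossprod gives Pearson r
standardize_rows <- function(v) {
  v <- v - rowMeans(v)
  ss <- sqrt(rowSums(v^2))
  v / ss
}

#' Rotation-maximized similarity matrix over kept cube nodes
#'
#' Computes, for every pair of kept cubes, the transform-maximized Pearson
#' correlation (see [max_similarity()]), using one dense matrix product per
#' transform. The diagonal is set to 0 (self-edges are excluded from the
#' graph).
#'
#' @param cubes A `cube_set` from [parcellate_cubes()].
#' @param transforms Permutation matrix from [build_transforms()].
#' @return An object of class `similarity_matrix`: `values` (symmetric N x N),
#'   `origins` (kept-node origins), `kept` (indices into the candidate cubes).
#' @export
similarity_matrix <- function(cubes, transforms = build_transforms()) {
  stopifnot(inherits(cubes, "cube_set"))
  kept <- which(cubes$kept_mask)
  if (length(kept) < 2L) stop("need at least 2 kept nodes", call. = FALSE)
  Z <- standardize_rows(cubes$values[kept, , drop = FALSE])
  n <- nrow(Z)
  S <- matrix(-1, n, n)
  for (t in seq_len(nrow(transforms))) {
    S[] <- pmax.int(S, tcrossprod(Z[, transforms[t, ], drop = FALSE], Z))
  }
  S[] <- pmax.int(S, t(S))
  S[S > 1] <- 1
  diag(S) <- 0
  structure(
    list(values = S, origins = cubes$origins[kept, , drop = FALSE],
         kept = kept, n_candidates = nrow(cubes$values)),
    class = "similarity_matrix"
  )
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix> %d nodes (of %d candidate cubes)\n",
              nrow(x$values), x$n_candidates))
  invisible(x)
}

#' Permutation null sample of maximal correlations
#'
#' Draws random pairs of kept cubes, randomly permutes the within-cube voxel
#' order of the seed cube (destroying its spatial structure), and records the
#' transform-maximized correlation with the unpermuted target. The sample
#' estimates the distribution of spurious maximal similarities and drives the
#' individualized FDR threshold.
#'
#' @param cubes A `cube_set`.
#' @param transforms Permutation matrix from [build_transforms()].
#' @param n_perm Number of random pair draws (>= 100; the upper tail is
#'   unstable below that).
#' @param seed Integer seed; the sample is deterministic given the seed.
#' @return Numeric vector of length `n_perm` with values in \[-1, 1\].
#' @export
permutation_null <- function(cubes, transforms = build_transforms(),
                             n_perm = 10000L, seed = NULL) {
  stopifnot(inherits(cubes, "cube_set"))
  n_perm <- as.integer(n_perm)
  if (n_perm < 100L) stop("`n_perm` must be >= 100", call. = FALSE)
  kept <- which(cubes$kept_mask)
  if (length(kept) < 2L) stop("need at least 2 kept nodes", call. = FALSE)
  V <- cubes$values[kept, , drop = FALSE]
  m <- ncol(V)
  with_seed(seed, {
    i <- sample.int(nrow(V), n_perm, replace = TRUE)
    j <- sample.int(nrow(V), n_perm, replace = TRUE)
    # scramble within-cube voxel order of each seed cube
    A <- matrix(0, n_perm, m)
    for (r in seq_len(n_perm)) A[r, ] <- V[i[r], sample.int(m)]
    A <- standardize_rows(A)
    B <- standardize_rows(V[j, , drop = FALSE])
    best <- rep(-1, n_perm)
    for (t in seq_len(nrow(transforms))) {
      p <- transforms[t, ]
      best <- pmax.int(best, rowSums(A[, p, drop = FALSE] * B),
                       rowSums(B[, p, drop = FALSE] * A))
    }
    pmin(best, 1)
  })
}

#' Binarize a similarity matrix with an FDR-corrected permutation threshold
#'
#' Converts each pairwise maximal correlation into an upper-tail empirical
#' p-value against the permutation null (the `(b+1)/(m+1)` estimator, so
#' p is never exactly 0), applies Benjamini-Hochberg across all
#' `N(N-1)/2` node pairs at level `q`, and keeps as edges the rejected
#' pairs. An edge requires a correlation strictly higher than the realized
#' FDR threshold: pairs tied with the largest non-retained correlation are
#' not edges.
#'
#' @param sim A [similarity_matrix()].
#' @param null_sample Numeric null sample from [permutation_null()].
#' @param q FDR control level in (0, 1); default 0.05, bounding the expected
#'   proportion of spurious connections at 5%.
#' @return An object of class `binary_network`: `adjacency` (symmetric 0/1
#'   integer matrix, zero diagonal), `threshold_used` (the correlation value
#'   above which pairs are edges), `fdr_q`, `n_edges`, `origins`.
#' @export
fdr_binarize <- function(sim, null_sample, q = 0.05) {
  stopifnot(inherits(sim, "similarity_matrix"))
  if (length(null_sample) == 0L) stop("empty null sample", call. = FALSE)
  if (length(unique(null_sample)) == 1L) {
    stop("degenerate null sample (all values identical)", call. = FALSE)
  }
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q >= 1) {
    stop("`q` must be in (0, 1)", call. = FALSE)
  }
  S <- sim$values
  n <- nrow(S)
  ut <- upper.tri(S)
  r <- S[ut]
  m <- length(null_sample)
  srt <- sort(null_sample)
  n_below <- findInterval(r, srt, left.open = TRUE)  # #{null < r}
  p <- (m - n_below + 1) / (m + 1)
  padj <- p.adjust(p, method = "BH")
  rejected <- padj <= q
  threshold <- if (any(!rejected)) max(r[!rejected]) else min(srt) - 1
  edge <- r > threshold
  A <- matrix(0L, n, n)
  A[ut] <- as.integer(edge)
  A <- A + t(A)
  structure(
    list(adjacency = A, threshold_used = threshold, fdr_q = q,
         n_edges = sum(edge), origins = sim$origins),
    class = "binary_network"
  )
}

#' @export
print.binary_network <- function(x, ...) {
  n <- nrow(x$adjacency)
  cat(sprintf("<binary_network> G=[N=%d, K=%d], threshold %.4f (FDR q=%.3g), sparsity %.2f%%\n",
              n, x$n_edges, x$threshold_used, x$fdr_q,
              100 * 2 * x$n_edges / (n * (n - 1))))
  invisible(x)
}

#' Extract a single-subject gray-matter network end to end
#'
#' Runs cube parcellation, transform enumeration, rotation-maximized
#' similarity, the permutation null and FDR binarization with one call.
#'
#' @param volume A [gm_volume()].
#' @param cube_size Cube edge length in voxels.
#' @param variance_eps Variance cutoff for node exclusion.
#' @param q FDR control level.
#' @param n_perm Permutation-null sample size.
#' @param seed Integer seed for the permutation null.
#' @return A list with `similarity` ([similarity_matrix()]), `network`
#'   ([fdr_binarize()] result), `cubes`, and `info` (network size = number of
#'   kept nodes, threshold, edge count, sparsity %).
#' @export
extract_network <- function(volume, cube_size = 3L, variance_eps = 0,
                            q = 0.05, n_perm = 10000L, seed = NULL) {
  cubes <- parcellate_cubes(volume, cube_size = cube_size,
                            variance_eps = variance_eps)
  tr <- build_transforms()
  sim <- similarity_matrix(cubes, tr)
  null_sample <- permutation_null(cubes, tr, n_perm = n_perm, seed = seed)
  net <- fdr_binarize(sim, null_sample, q = q)
  n <- nrow(net$adjacency)
  list(
    similarity = sim, network = net, cubes = cubes,
    info = list(network_size = n, threshold = net$threshold_used,
                n_edges = net$n_edges,
                sparsity = 100 * 2 * net$n_edges / (n * (n - 1)))
  )
}
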