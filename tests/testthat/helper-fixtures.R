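# Shared fixtures, built in code at test time.

# small volume with controllable structure
tiny_volume <- function(shape = c(12, 12, 12), smoothness = 2, seed = 1, ...) {
  generate_gm_volume(shape, smoothness = smoothness, seed = seed, ...)
}

# random symmetric 0/1 adjacency with zero diagonal
random_adjacency <- function(n, p = 0.3) {
  A <- matrix(0L, n, n)
  ut <- upper.tri(A)
  A[ut] <- rbinom(sum(ut), 1L, p)
  A + t(A)
}

# --- independent graph oracles (naive enumeration; no igraph) ---

oracle_clustering <- function(A) {
  n <- nrow(A)
  vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] == 1L)
    k <- length(nb)
    if (k < 2L) return(0)
    links <- 0L
    for (a in seq_len(k - 1L)) for (b in (a + 1L):k) {
      links <- links + A[nb[a], nb[b]]
    }
    2 * links / (k * (k - 1))
  }, numeric(1))
}

oracle_distances <- function(A) {
  # Floyd-Warshall
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A == 1L] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  }
  D
}

oracle_charpath <- function(A) {
  D <- oracle_distances(A)
  diag(D) <- NA
  vals <- D[is.finite(D) & !is.na(D)]
  mean(vals)
}

oracle_efficiency <- function(A) {
  D <- oracle_distances(A)
  diag(D) <- Inf
  mean(1 / D[row(D) != col(D)])
}

oracle_sparsity <- function(A) {
  n <- nrow(A)
  100 * sum(A) / (n * (n - 1))
}

# brute-force transform-maximized correlation via an explicit loop
oracle_max_similarity <- function(s, t, transforms) {
  best <- -1
  for (k in seq_len(nrow(transforms))) {
    p <- transforms[k, ]
    best <- max(best, cor(s[p], t), cor(t[p], s))
  }
  best
}

# textbook Benjamini-Hochberg walk-through
oracle_bh_reject <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  below <- which(ps <= q * seq_len(m) / m)
  rejected <- logical(m)
  if (length(below)) rejected[ord[seq_len(max(below))]] <- TRUE
  rejected
}
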