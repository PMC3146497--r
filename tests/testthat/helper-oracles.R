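# Independent oracles used to validate the package's computations:
# brute-force automorphism orbits, Floyd-Warshall path counts, exhaustive
# Wilcoxon rank-sum enumeration, and a BFS component finder. These stay
# deliberately naive and share no code with the implementation.

# All n! permutations of 1..n, one per row.
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  p <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[p], nrow(p), n - 1L))
  }))
}

# Brute-force vertex orbits: test every permutation for automorphism, then
# collect each vertex's set of images. Returns a sorted list of sorted
# label vectors, same shape as vertex_orbits().
oracle_orbits <- function(g) {
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  n <- nrow(A)
  labels <- igraph::V(g)$name
  perms <- all_perms(n)
  is_auto <- apply(perms, 1L, function(p) all(A[p, p] == A))
  autos <- perms[is_auto, , drop = FALSE]
  image_sets <- lapply(seq_len(n), function(v) sort(unique(autos[, v])))
  uniq <- unique(image_sets)
  orbits <- lapply(uniq, function(s) sort(labels[s]))
  orbits[order(vapply(orbits, `[`, character(1L), 1L))]
}

# Orbit-size probability vector (support 1..max size) from the brute-force
# orbits, for direct comparison with orbit_distribution()$probs.
oracle_orbit_probs <- function(g) {
  sizes <- lengths(oracle_orbits(g))
  counts <- tabulate(sizes, nbins = max(sizes))
  counts / length(sizes)
}

# Floyd-Warshall all-pairs shortest paths; probability vector over finite
# unordered pair distances 1..max.
oracle_distance_probs <- function(g) {
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A > 0] <- 1
  diag(D) <- 0
  for (k in seq_len(n))
    D <- pmin(D, outer(D[, k], D[k, ], `+`))
  d <- D[upper.tri(D)]
  d <- d[is.finite(d) & d >= 1]
  if (length(d) == 0L) return(NULL)
  counts <- tabulate(d, nbins = max(d))
  counts / length(d)
}

# Exact two-sided rank-sum p-value by full enumeration of all C(n1+n2, n1)
# rank assignments (tie-free inputs only). The doubling rule on the smaller
# tail is the two-sided test's definition.
oracle_wilcox_p <- function(a, b) {
  n1 <- length(a)
  n2 <- length(b)
  stopifnot(!anyDuplicated(c(a, b)))
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  splits <- utils::combn(n1 + n2, n1)
  ws <- colSums(matrix(seq_len(n1 + n2)[splits], nrow = n1)) - n1 * (n1 + 1) / 2
  p <- if (w_obs > n1 * n2 / 2) mean(ws >= w_obs) else mean(ws <= w_obs)
  min(1, 2 * p)
}

# BFS component sizes, independent of igraph::components.
oracle_component_sizes <- function(g) {
  n <- igraph::vcount(g)
  if (n == 0L) return(integer(0L))
  adj <- lapply(igraph::as_adj_list(g), as.integer)
  seen <- logical(n)
  sizes <- integer(0L)
  for (s in seq_len(n)) {
    if (seen[s]) next
    queue <- s
    seen[s] <- TRUE
    size <- 0L
    while (length(queue) > 0L) {
      v <- queue[1L]
      queue <- queue[-1L]
      size <- size + 1L
      nb <- adj[[v]][!seen[adj[[v]]]]
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    sizes <- c(sizes, size)
  }
  sizes
}
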