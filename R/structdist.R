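# Structural probability distributions: degree, shortest-path distance,
# sphere-based vertex probabilities, and automorphism-orbit sizes. Each is a
# discrete distribution summing to 1; zero bins are kept as true zeros here
# and only replaced by epsilon inside the divergence computation.

new_struct_dist <- function(kind, support_start, probs, labels = NULL) {
  stopifnot(is.numeric(probs), length(probs) > 0L)
  if (any(probs < 0))
    stop("probabilities must be non-negative")
  if (abs(sum(probs) - 1) > 1e-9)
    stop("probabilities must sum to 1 (got ", format(sum(probs)), ")")
  if (is.null(labels)) {
    # trim trailing zero bins so the support ends at the last occupied value
    last <- max(which(probs > 0))
    probs <- probs[seq_len(last)]
  }
  structure(
    list(kind = kind, support_start = support_start, probs = unname(probs),
         labels = labels),
    class = "struct_dist"
  )
}

#' @export
print.struct_dist <- function(x, ...) {
  cat("Structural distribution (", x$kind, "), ", length(x$probs), " bins\n", sep = "")
  df <- as.data.frame(x)
  print(utils::head(df, 10L), row.names = FALSE)
  if (nrow(df) > 10L) cat("... ", nrow(df) - 10L, " more bins\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.struct_dist <- function(x, ...) {
  support <- if (is.null(x$labels))
    seq(x$support_start, length.out = length(x$probs))
  else x$labels
  data.frame(support = support, probability = x$probs,
             stringsAsFactors = FALSE)
}

#' Write a structural distribution as a two-column TSV
#'
#' Columns `support` (degree k, path length l, orbit size s, or vertex
#' label) and `probability`, suitable for plotting distribution profiles.
#'
#' @param d A distribution from [degree_distribution()] and friends.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_distribution <- function(d, path) {
  stopifnot(inherits(d, "struct_dist"))
  utils::write.table(as.data.frame(d), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Degree distribution of a graph
#'
#' P(k) is the fraction of vertices with exactly k neighbours, for
#' k = 0..k_max. Computed on the complete graph, disconnected or not;
#' isolated vertices (which vertex-set alignment introduces) occupy the
#' k = 0 bin.
#'
#' @param g An igraph object.
#' @return A `struct_dist` of kind `"degree"` with support starting at 0.
#' @export
#' @examples
#' degree_distribution(labeled_graph(cbind("hub", c("a", "b", "c"))))
degree_distribution <- function(g) {
  n <- igraph::vcount(g)
  if (n == 0L)
    stop("degree distribution of an empty graph is undefined")
  deg <- igraph::degree(g)
  counts <- tabulate(deg + 1L, nbins = max(deg) + 1L)
  new_struct_dist("degree", 0L, counts / n)
}

#' Shortest-path distance distribution of a graph
#'
#' P(l) is the fraction of unordered vertex pairs whose shortest-path
#' distance equals l, for l = 1..diameter, among the N pairs at finite
#' distance. Disconnected graphs are allowed; pairs in different components
#' are simply not counted.
#'
#' @param g An igraph object.
#' @return A `struct_dist` of kind `"distance"` with support starting at 1.
#' @export
distance_distribution <- function(g) {
  n <- igraph::vcount(g)
  if (n == 0L)
    stop("distance distribution of an empty graph is undefined")
  sp <- igraph::distances(g)
  d <- sp[upper.tri(sp)]
  d <- d[is.finite(d) & d >= 1]
  if (length(d) == 0L)
    stop("distance distribution undefined: no finite vertex pair (edgeless graph)")
  counts <- tabulate(d, nbins = max(d))
  new_struct_dist("distance", 1L, counts / length(d))
}

#' Sphere-based vertex probability distribution
#'
#' Assigns each vertex v of a connected graph an information functional
#' value f(v) = sum_j c_j |S_j(v)|, where S_j(v) is the set of vertices at
#' exact shortest-path distance j from v and the weights c_j = b^j decay
#' geometrically (default base b = 0.5), emphasizing the neighbourhood close
#' to v. Vertex probabilities are p(v) = f(v) / sum_u f(u), reported over
#' vertices in sorted-label order.
#'
#' @param g A connected igraph object with at least two vertices (pass the
#'   largest connected component of a disconnected graph).
#' @param weight_base Base b of the geometric sphere weights, in (0, 1).
#' @return A `struct_dist` of kind `"sphere"` whose support is the sorted
#'   vertex label set (in `$labels`).
#' @export
sphere_probabilities <- function(g, weight_base = 0.5) {
  if (!is.numeric(weight_base) || weight_base <= 0 || weight_base >= 1)
    stop("'weight_base' must lie strictly between 0 and 1")
  n <- igraph::vcount(g)
  if (n < 2L)
    stop("sphere probabilities need at least two vertices (functional is 0 otherwise)")
  if (!igraph::is_connected(g))
    stop("sphere probabilities are defined on connected graphs; ",
         "reduce to the largest connected component first")
  ord <- order(igraph::V(g)$name)
  sp <- igraph::distances(g)[ord, ord, drop = FALSE]
  f <- apply(sp, 1L, function(row) {
    j <- row[row >= 1]
    sum(weight_base^j)
  })
  new_struct_dist("sphere", NA_integer_, f / sum(f),
                  labels = igraph::V(g)$name[ord])
}

#' Vertex orbits of the automorphism group
#'
#' Two vertices are in the same orbit when some automorphism of the
#' (unlabeled) topology maps one onto the other; orbit members are
#' topologically indistinguishable. Orbits are computed exactly from
#' generators of the automorphism group (BLISS canonical-labeling backend)
#' closed under union-find.
#'
#' @param g An igraph object with at least one vertex.
#' @return List of character vectors, each one orbit of vertex labels,
#'   ordered by smallest member label.
#' @export
vertex_orbits <- function(g) {
  n <- igraph::vcount(g)
  if (n == 0L)
    stop("orbits of an empty graph are undefined")
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (n > 1L) {
    gens <- igraph::automorphism_group(g)
    for (p in gens) {
      p <- as.integer(p)
      for (v in seq_len(n)) {
        a <- find(v); b <- find(p[v])
        if (a != b) parent[a] <- b
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1L))
  labels <- igraph::V(g)$name
  orbits <- unname(split(labels, roots))
  orbits <- lapply(orbits, sort)
  orbits[order(vapply(orbits, `[`, character(1L), 1L))]
}

#' Orbit-size distribution of a graph
#'
#' With n_s the number of automorphism-group vertex orbits containing
#' exactly s vertices and N_orb the total number of orbits, P(s) =
#' n_s / N_orb for s = 1..max orbit size. Captures how much topological
#' symmetry (vertex equivalence) a network carries; asymmetric networks
#' concentrate all mass at s = 1.
#'
#' @param g An igraph object, conventionally the largest connected component.
#' @return A `struct_dist` of kind `"orbit"` with support starting at 1.
#' @export
orbit_distribution <- function(g) {
  orbits <- vertex_orbits(g)
  sizes <- lengths(orbits)
  counts <- tabulate(sizes, nbins = max(sizes))
  new_struct_dist("orbit", 1L, counts / length(orbits))
}
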