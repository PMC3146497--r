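# Pairwise graph distances: Kullback-Leibler divergence between structural
# distributions, and the normalized graph edit distance for uniquely-labeled
# graphs on a shared vertex set.

# Align two distributions of the same kind onto a common support, returning
# a two-row matrix (P, Q). Integer-supported kinds are zero-padded to the
# union support range; sphere distributions are aligned on the union of
# their vertex label sets.
align_supports <- function(p, q) {
  if (p$kind != q$kind)
    stop("cannot compare distributions of kind '", p$kind, "' and '", q$kind, "'")
  if (p$kind == "sphere") {
    labels <- sort(unique(c(p$labels, q$labels)))
    pv <- stats::setNames(numeric(length(labels)), labels)
    qv <- pv
    pv[p$labels] <- p$probs
    qv[q$labels] <- q$probs
    rbind(P = unname(pv), Q = unname(qv))
  } else {
    start <- min(p$support_start, q$support_start)
    end <- max(p$support_start + length(p$probs),
               q$support_start + length(q$probs)) - 1L
    len <- end - start + 1L
    pv <- numeric(len)
    qv <- numeric(len)
    pv[(p$support_start - start + 1L):(p$support_start - start + length(p$probs))] <- p$probs
    qv[(q$support_start - start + 1L):(q$support_start - start + length(q$probs))] <- q$probs
    rbind(P = pv, Q = qv)
  }
}

#' Kullback-Leibler divergence between two structural distributions
#'
#' D(P || Q) = sum_i P_i log(P_i / Q_i), with the two distributions first
#' zero-padded onto their union support and every zero entry of either
#' vector then replaced by `epsilon` for numeric stability (substitution
#' only, no renormalization). Asymmetric: the first argument is the
#' reference. Non-negative up to epsilon-induced error.
#'
#' @param p,q Distributions of the same kind (see [degree_distribution()]
#'   and friends).
#' @param epsilon Small positive value substituted for zero probabilities.
#' @param log_base Base of the logarithm: `exp(1)` (nats, default) or `2`
#'   (bits). Prototype selection is invariant to this choice.
#' @return A single non-negative number.
#' @export
#' @examples
#' d <- degree_distribution(labeled_graph(cbind("a", "b")))
#' kld(d, d)  # 0
kld <- function(p, q, epsilon = 1e-10, log_base = exp(1)) {
  stopifnot(inherits(p, "struct_dist"), inherits(q, "struct_dist"))
  if (!is.numeric(epsilon) || epsilon <= 0)
    stop("'epsilon' must be a small positive number")
  m <- align_supports(p, q)
  P <- m["P", ]
  Q <- m["Q", ]
  if (any(P < 0) || any(Q < 0))
    stop("probabilities must be non-negative")
  P[P == 0] <- epsilon
  Q[Q == 0] <- epsilon
  sum(P * (log(P) - log(Q))) / log(log_base)
}

#' Graph edit distance for uniquely-labeled graphs on a fixed vertex set
#'
#' When all vertices are uniquely labeled and both graphs share the same
#' vertex set, no vertex operations are needed and the minimum edit cost
#' under unit edge insertion/deletion weights is exactly the size of the
#' symmetric difference of the edge sets — computable in linear time rather
#' than the NP-complete general case.
#'
#' @param g1,g2 igraph objects on identical vertex label sets (run
#'   [align_vertex_sets()] first if necessary).
#' @return Integer edit distance.
#' @export
ged <- function(g1, g2) {
  v1 <- igraph::V(g1)$name
  v2 <- igraph::V(g2)$name
  if (length(v1) != length(v2) || !setequal(v1, v2))
    stop("graphs must share an identical vertex set; align the cohort first")
  k1 <- edge_keys(g1)
  k2 <- edge_keys(g2)
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}

#' Percentage (normalized) graph edit distance
#'
#' pGED = GED / E_max, the edit distance as a fraction of the maximum
#' possible number of undirected edges. With the default E_max =
#' n(n-1)/2 the maximal edit (complete graph vs edgeless graph) scores
#' exactly 1; sparse cohorts score far below 1. The normalization constant
#' is configurable.
#'
#' @inheritParams ged
#' @param max_edges Normalization constant E_max; defaults to n(n-1)/2.
#' @return Number in \[0, 1\] under the default normalization; symmetric;
#'   0 for identical graphs.
#' @export
pged <- function(g1, g2, max_edges = NULL) {
  d <- ged(g1, g2)
  n <- igraph::vcount(g1)
  if (is.null(max_edges))
    max_edges <- n * (n - 1) / 2
  if (max_edges <= 0)
    stop("'max_edges' must be positive (graphs with < 2 vertices have no edits)")
  d / max_edges
}

#' Distance between two graphs under a named measure
#'
#' Dispatches to [pged()] or to [kld()] over the appropriate structural
#' distribution. KLD-based measures are directed: the first graph supplies
#' the reference distribution P in D(P || Q). The sphere and orbit measures
#' require connected graphs, so this function reduces each input to its
#' largest connected component for those two measures.
#'
#' @param g1,g2 igraph objects; identical vertex sets required for `pged`.
#' @param measure One of [graph_measures()].
#' @param epsilon,log_base Passed to [kld()].
#' @param weight_base Passed to [sphere_probabilities()].
#' @param max_edges Passed to [pged()].
#' @return A single non-negative number.
#' @export
graph_distance <- function(g1, g2, measure = graph_measures(),
                           epsilon = 1e-10, log_base = exp(1),
                           weight_base = 0.5, max_edges = NULL) {
  measure <- match.arg(measure)
  switch(measure,
    pged = pged(g1, g2, max_edges = max_edges),
    kld_degree = kld(degree_distribution(g1), degree_distribution(g2),
                     epsilon = epsilon, log_base = log_base),
    kld_distance = kld(distance_distribution(g1), distance_distribution(g2),
                       epsilon = epsilon, log_base = log_base),
    kld_spheres = kld(
      sphere_probabilities(largest_component(g1), weight_base = weight_base),
      sphere_probabilities(largest_component(g2), weight_base = weight_base),
      epsilon = epsilon, log_base = log_base),
    kld_orbits = kld(orbit_distribution(largest_component(g1)),
                     orbit_distribution(largest_component(g2)),
                     epsilon = epsilon, log_base = log_base)
  )
}
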