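# Synthetic cohorts: sparse scale-free graphs on a shared label set with
# controlled within-group rewiring noise and a known ground-truth base, the
# statistical structure the prototype analysis assumes. Co-expression
# networks carry heavy-tailed degree distributions, which preferential
# attachment reproduces; rewiring preserves the edge count so that distances
# reflect structural change, not density.

#' Generate a preferential-attachment base graph
#'
#' Starts from `attachment_edges` isolated seed vertices; every further
#' vertex attaches `attachment_edges` edges to distinct existing vertices
#' chosen with probability proportional to degree + 1. The result is a
#' simple connected-by-construction graph with exactly
#' `attachment_edges * (n_vertices - attachment_edges)` edges and a
#' heavy-tailed degree distribution. Labels are `g0001..gN`.
#'
#' @param n_vertices Number of vertices (> `attachment_edges`).
#' @param attachment_edges Edges added per new vertex (>= 1).
#' @param seed Optional integer seed; the caller's RNG state is untouched.
#' @param name Graph identifier.
#' @return An igraph object.
#' @export
make_base_graph <- function(n_vertices, attachment_edges = 2L, seed = NULL,
                            name = "base") {
  n <- as.integer(n_vertices)
  m <- as.integer(attachment_edges)
  if (is.na(n) || is.na(m) || m < 1L || n <= m)
    stop("need n_vertices > attachment_edges >= 1")
  with_local_seed(seed, {
    deg <- integer(n)
    n_edges <- m * (n - m)
    from <- integer(n_edges)
    to <- integer(n_edges)
    k <- 0L
    for (v in (m + 1L):n) {
      prev <- seq_len(v - 1L)
      targets <- if (v - 1L == m) prev
                 else sample(prev, m, replace = FALSE, prob = deg[prev] + 1)
      idx <- k + seq_len(m)
      from[idx] <- v
      to[idx] <- targets
      k <- k + m
      deg[v] <- deg[v] + m
      deg[targets] <- deg[targets] + 1L
    }
    width <- max(4L, nchar(as.character(n)))
    labels <- sprintf(paste0("g%0", width, "d"), seq_len(n))
    labeled_graph(cbind(labels[from], labels[to]), vertices = labels,
                  name = name)
  })
}

#' Rewire a fraction of a graph's edges
#'
#' Removes `floor(rewire_fraction * |E|)` edges uniformly at random and
#' replaces them with the same number of uniformly sampled non-edges. The
#' vertex set and the edge count are unchanged, so the perturbation isolates
#' structural signal from density effects. The edit distance to the
#' original is at most twice the number of rewired edges.
#'
#' @param g An igraph object with named vertices.
#' @param rewire_fraction Fraction of edges to rewire, in \[0, 1\].
#' @param seed Optional integer seed.
#' @param name Identifier for the perturbed graph; defaults to the input's.
#' @return An igraph object.
#' @export
perturb_graph <- function(g, rewire_fraction, seed = NULL, name = NULL) {
  if (!is.numeric(rewire_fraction) || rewire_fraction < 0 || rewire_fraction > 1)
    stop("'rewire_fraction' must lie in [0, 1]")
  n <- igraph::vcount(g)
  ne <- igraph::ecount(g)
  k <- floor(rewire_fraction * ne)
  labels <- igraph::V(g)$name
  out_name <- name %||% g$name
  if (k == 0L) {
    out <- g
    out$name <- out_name
    return(out)
  }
  e_max <- n * (n - 1) / 2
  if (e_max - (ne - k) < k)
    stop("graph too dense: not enough non-edges to place ", k, " replacements")
  with_local_seed(seed, {
    el <- igraph::as_edgelist(g, names = FALSE)
    # canonical integer key of an undirected pair (i < j)
    pair_key <- function(i, j) {
      lo <- pmin(i, j); hi <- pmax(i, j)
      (lo - 1) * n + hi
    }
    keys <- pair_key(el[, 1L], el[, 2L])
    drop <- sample(ne, k)
    kept <- keys[-drop]
    new_keys <- numeric(0L)
    present <- c(kept)
    while (length(new_keys) < k) {
      need <- k - length(new_keys)
      i <- sample.int(n, 2L * need + 8L, replace = TRUE)
      j <- sample.int(n, 2L * need + 8L, replace = TRUE)
      ok <- i != j
      cand <- pair_key(i[ok], j[ok])
      cand <- cand[!duplicated(cand)]
      cand <- cand[!(cand %in% present)]
      take <- utils::head(cand, need)
      new_keys <- c(new_keys, take)
      present <- c(present, take)
    }
    all_keys <- c(kept, new_keys)
    lo <- floor((all_keys - 1) / n) + 1
    hi <- all_keys - (lo - 1) * n
    labeled_graph(cbind(labels[lo], labels[hi]), vertices = labels,
                  name = out_name)
  })
}

#' Generate a two-group synthetic cohort with known ground truth
#'
#' Emulates the study design the prototype analysis targets: two groups of
#' networks (for example benign and cancer co-expression networks) on a
#' shared gene label set, each group a set of independent rewirings of a
#' scale-free base graph. Under `shared_base = TRUE` both groups perturb
#' the same base (the null configuration); otherwise each group gets its
#' own independently generated base.
#'
#' @param n_vertices,attachment_edges Passed to [make_base_graph()].
#' @param group_sizes Integer vector of length 2, each >= 2; default
#'   `c(6, 7)`.
#' @param group_names Labels for the two groups.
#' @param rewire_fractions Rewiring noise per group, length 2.
#' @param shared_base Perturb one common base graph (TRUE) or one base per
#'   group (FALSE)?
#' @param seed Optional integer seed making the whole cohort reproducible.
#' @return List with `graphs` (named list of igraph), `groups` (named
#'   character vector), and `truth` (generation parameters plus the base
#'   graph(s)).
#' @export
make_cohort <- function(n_vertices = 500L, attachment_edges = 2L,
                        group_sizes = c(6L, 7L),
                        group_names = c("benign", "cancer"),
                        rewire_fractions = c(0.05, 0.05),
                        shared_base = TRUE, seed = NULL) {
  stopifnot(length(group_sizes) == 2L, length(group_names) == 2L,
            length(rewire_fractions) == 2L)
  if (any(group_sizes < 2L))
    stop("each group needs at least two graphs")
  with_local_seed(seed, {
    bases <- list(make_base_graph(n_vertices, attachment_edges,
                                  name = paste0(group_names[1L], "_base")))
    bases[[2L]] <- if (shared_base) bases[[1L]]
                   else make_base_graph(n_vertices, attachment_edges,
                                        name = paste0(group_names[2L], "_base"))
    graphs <- list()
    groups <- character(0L)
    for (gi in 1:2) {
      for (r in seq_len(group_sizes[gi])) {
        nm <- paste0(group_names[gi], "_", r)
        graphs[[nm]] <- perturb_graph(bases[[gi]], rewire_fractions[gi],
                                      name = nm)
        groups[nm] <- group_names[gi]
      }
    }
    list(graphs = graphs,
         groups = groups,
         truth = list(n_vertices = as.integer(n_vertices),
                      attachment_edges = as.integer(attachment_edges),
                      group_sizes = as.integer(group_sizes),
                      group_names = group_names,
                      rewire_fractions = rewire_fractions,
                      shared_base = shared_base,
                      seed = seed,
                      bases = bases))
  })
}
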