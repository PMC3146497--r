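# Graph fixtures built in code: named small graphs and random generators.

mk <- function(..., vertices = NULL, name = "g") {
  pairs <- list(...)
  edges <- if (length(pairs) > 0L)
    do.call(rbind, lapply(pairs, function(p) matrix(p, ncol = 2L)))
  labeled_graph(edges, vertices = vertices, name = name)
}

path_graph <- function(n, name = paste0("P", n)) {
  labels <- letters[seq_len(n)]
  labeled_graph(cbind(labels[-n], labels[-1L]), name = name)
}

cycle_graph <- function(n, name = paste0("C", n)) {
  labels <- letters[seq_len(n)]
  labeled_graph(cbind(labels, labels[c(2:n, 1L)]), name = name)
}

complete_graph <- function(n, name = paste0("K", n)) {
  labels <- letters[seq_len(n)]
  pairs <- t(utils::combn(n, 2L))
  labeled_graph(cbind(labels[pairs[, 1L]], labels[pairs[, 2L]]), name = name)
}

star_graph <- function(n_leaves, name = "star") {
  labeled_graph(cbind("hub", paste0("leaf", seq_len(n_leaves))), name = name)
}

hypercube_q3 <- function() {
  corners <- c("000", "001", "010", "011", "100", "101", "110", "111")
  pairs <- t(utils::combn(8L, 2L))
  differ <- apply(pairs, 1L, function(p) {
    a <- strsplit(corners[p[1L]], "")[[1L]]
    b <- strsplit(corners[p[2L]], "")[[1L]]
    sum(a != b) == 1L
  })
  labeled_graph(cbind(corners[pairs[differ, 1L]], corners[pairs[differ, 2L]]),
                name = "Q3")
}

# Erdos-Renyi graph on fixed labels; uses the current RNG stream.
rand_graph <- function(n, p = 0.3, labels = sprintf("v%02d", seq_len(n)),
                       name = "rand") {
  pairs <- t(utils::combn(n, 2L))
  sel <- stats::runif(nrow(pairs)) < p
  labeled_graph(cbind(labels[pairs[sel, 1L]], labels[pairs[sel, 2L]]),
                vertices = labels, name = name)
}

rand_connected_graph <- function(n, p = 0.4, name = "rand") {
  repeat {
    g <- rand_graph(n, p, name = name)
    if (igraph::ecount(g) > 0L && igraph::is_connected(g)) return(g)
  }
}

# Exhaustive corpus of connected graphs on n vertices, one representative
# per isomorphism class, found by scanning every edge subset and keeping
# the first member of each canonical-form class.
connected_rep_graphs <- function(n) {
  labels <- letters[seq_len(n)]
  if (n == 1L)
    return(list(labeled_graph(vertices = "a", name = "n1_1")))
  pairs <- t(utils::combn(n, 2L))
  npairs <- nrow(pairs)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  out <- list()
  for (mask in seq_len(2L^npairs - 1L)) {
    sel <- bitwAnd(mask, bitwShiftL(1L, seq_len(npairs) - 1L)) != 0L
    el <- pairs[sel, , drop = FALSE]
    # union-find connectivity over all n vertices
    parent <- seq_len(n)
    find <- function(i) {
      while (parent[i] != i) {
        parent[i] <<- parent[parent[i]]
        i <- parent[i]
      }
      i
    }
    for (e in seq_len(nrow(el))) {
      a <- find(el[e, 1L]); b <- find(el[e, 2L])
      if (a != b) parent[a] <- b
    }
    if (length(unique(vapply(seq_len(n), find, integer(1L)))) != 1L) next
    g <- igraph::graph_from_edgelist(el, directed = FALSE)
    canon <- igraph::permute(g, igraph::canonical_permutation(g)$labeling)
    cel <- igraph::as_edgelist(canon)
    key <- paste(sort(paste(pmin(cel[, 1L], cel[, 2L]),
                            pmax(cel[, 1L], cel[, 2L]), sep = "-")),
                 collapse = ";")
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    out[[length(out) + 1L]] <- labeled_graph(
      cbind(labels[el[, 1L]], labels[el[, 2L]]),
      name = paste0("n", n, "_", length(out) + 1L))
  }
  out
}
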