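# Prototype selection: pairwise distance matrices over a cohort and the
# minimal-mean-distance criterion. The prototype of a set of networks is the
# member whose mean distance to all other members is smallest — a
# representative chosen from the set, never a synthesized consensus.

#' Pairwise distance matrix for a cohort
#'
#' Computes `values[i, j] = graph_distance(G_i, G_j)`; row i holds the
#' distances "from" graph i, which matters for the directed KLD measures.
#' Structural distributions are computed once per graph and reused across
#' pairs, so the cost is m distribution computations plus m^2 divergence
#' evaluations.
#'
#' @param graphs Named list of at least two igraph objects. Unnamed entries
#'   take their graph's `$name`.
#' @param measure One of [graph_measures()].
#' @inheritParams graph_distance
#' @return An m x m numeric matrix with graph names as dimnames and
#'   attributes `measure` and `symmetric`.
#' @export
distance_matrix <- function(graphs, measure = graph_measures(),
                            epsilon = 1e-10, log_base = exp(1),
                            weight_base = 0.5, max_edges = NULL) {
  measure <- match.arg(measure)
  m <- length(graphs)
  if (m < 2L)
    stop("a distance matrix needs at least two graphs")
  nms <- names(graphs)
  if (is.null(nms))
    nms <- vapply(graphs, function(g) g$name %||% "", character(1L))
  blank <- is.na(nms) | nms == ""
  nms[blank] <- vapply(graphs[blank], function(g) g$name %||% "", character(1L))
  if (any(nms == "") || anyDuplicated(nms))
    stop("graphs must carry unique non-empty names")
  values <- matrix(0, m, m, dimnames = list(nms, nms))
  if (measure == "pged") {
    n0 <- igraph::vcount(graphs[[1L]])
    keys <- lapply(graphs, edge_keys)
    e_max <- if (is.null(max_edges)) n0 * (n0 - 1) / 2 else max_edges
    for (i in seq_len(m - 1L)) {
      vi <- igraph::V(graphs[[i]])$name
      for (j in (i + 1L):m) {
        vj <- igraph::V(graphs[[j]])$name
        if (length(vi) != length(vj) || !setequal(vi, vj))
          stop("pged requires identical vertex sets ('", nms[i], "' vs '",
               nms[j], "'); align the cohort first")
        d <- (length(setdiff(keys[[i]], keys[[j]])) +
              length(setdiff(keys[[j]], keys[[i]]))) / e_max
        values[i, j] <- d
        values[j, i] <- d
      }
    }
  } else {
    dists <- lapply(graphs, function(g) {
      switch(measure,
        kld_degree = degree_distribution(g),
        kld_distance = distance_distribution(g),
        kld_spheres = sphere_probabilities(largest_component(g),
                                           weight_base = weight_base),
        kld_orbits = orbit_distribution(largest_component(g))
      )
    })
    for (i in seq_len(m)) for (j in seq_len(m)) {
      if (i != j)
        values[i, j] <- kld(dists[[i]], dists[[j]],
                            epsilon = epsilon, log_base = log_base)
    }
  }
  attr(values, "measure") <- measure
  attr(values, "symmetric") <- measure == "pged"
  values
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mean distance from each graph to the rest of its cohort
#'
#' The selection criterion averages, for each graph, its distances to every
#' other cohort member. For the directed KLD measures the default uses the
#' outgoing direction (row means, averaging D(P_i || P_j) over j); incoming
#' (column) means are available via `direction`.
#'
#' @param dm Matrix from [distance_matrix()].
#' @param direction `"out"` (row means, default) or `"in"` (column means).
#' @return Named numeric vector of mean distances.
#' @export
mean_distances <- function(dm, direction = c("out", "in")) {
  direction <- match.arg(direction)
  m <- nrow(dm)
  if (is.null(m) || m < 2L || m != ncol(dm))
    stop("'dm' must be a square matrix with at least two graphs")
  if (direction == "in")
    dm <- t(dm)
  (rowSums(dm) - diag(dm)) / (m - 1)
}

#' Select the prototype of a cohort
#'
#' The prototype is the graph with minimal mean distance to all other
#' graphs in the cohort. One network is always selected, regardless of how
#' large the distances are — no quality threshold is applied. Exact ties
#' (within `tie_tol`) are reported and broken by input order.
#'
#' @inheritParams mean_distances
#' @param tie_tol Absolute tolerance within which mean distances count as
#'   tied.
#' @return A `prototype_result` list: `measure`, `mean_distances`,
#'   `prototype`, `ties`, `direction`.
#' @export
select_prototype <- function(dm, direction = c("out", "in"), tie_tol = 1e-12) {
  direction <- match.arg(direction)
  md <- mean_distances(dm, direction = direction)
  best <- which.min(md)
  ties <- names(md)[md <= md[best] + tie_tol]
  structure(
    list(measure = attr(dm, "measure") %||% NA_character_,
         mean_distances = md,
         prototype = names(md)[best],
         ties = ties,
         direction = direction),
    class = "prototype_result"
  )
}

#' @export
print.prototype_result <- function(x, ...) {
  cat("Graph prototype (measure: ", x$measure, ", direction: ", x$direction,
      ")\n", sep = "")
  cat("  prototype: ", x$prototype, " (mean distance ",
      format(x$mean_distances[x$prototype], digits = 6), ")\n", sep = "")
  if (length(x$ties) > 1L)
    cat("  tied with:", paste(setdiff(x$ties, x$prototype), collapse = ", "), "\n")
  cat("  mean distances:\n")
  print(round(x$mean_distances, 6))
  invisible(x)
}

#' Write a distance matrix as TSV
#'
#' Header comment records the measure so the convention in force is
#' auditable; first row and column carry graph names.
#'
#' @param dm Matrix from [distance_matrix()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_distance_matrix <- function(dm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# measure: ", attr(dm, "measure") %||% "unknown"), con)
  writeLines(paste(c("graph", colnames(dm)), collapse = "\t"), con)
  for (i in seq_len(nrow(dm)))
    writeLines(paste(c(rownames(dm)[i], format(dm[i, ], digits = 15,
                                               scientific = FALSE, trim = TRUE)),
                     collapse = "\t"), con)
  invisible(path)
}

#' Read a distance matrix written by [write_distance_matrix()]
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix with a `measure` attribute.
#' @export
read_distance_matrix <- function(path) {
  lines <- readLines(path)
  measure <- NA_character_
  meta <- grepl("^# measure:", lines)
  if (any(meta))
    measure <- sub("^# measure:\\s*", "", lines[which(meta)[1L]])
  lines <- lines[!grepl("^#", lines)]
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]][-1L]
  rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
  nms <- vapply(rows, `[`, character(1L), 1L)
  values <- t(vapply(rows, function(r) as.numeric(r[-1L]), numeric(length(header))))
  dimnames(values) <- list(nms, header)
  attr(values, "measure") <- measure
  attr(values, "symmetric") <- identical(measure, "pged")
  values
}
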