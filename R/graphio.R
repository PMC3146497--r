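# Graph input/output: edge-list and GraphML readers/writers, group tables,
# vertex-set alignment, largest connected components.
#
# All graphs are undirected simple igraph objects whose vertices carry unique
# string labels in V(g)$name and whose identifier lives in g$name. Vertex
# labels are kept in sorted order so that every derived quantity (sphere
# distributions, tie-breaking, file output) is deterministic.

#' Construct a labeled graph
#'
#' Builds an undirected simple graph with unique string vertex labels from an
#' edge table. Duplicate edges are collapsed; self-loops are rejected.
#'
#' @param edges Two-column character matrix or data frame of edge endpoints
#'   (labels), or `NULL` for an edgeless graph.
#' @param vertices Character vector of vertex labels; the final vertex set is
#'   the union of `vertices` and all edge endpoints, stored sorted.
#' @param name Graph identifier.
#' @return An igraph object.
#' @export
#' @examples
#' g <- labeled_graph(cbind(c("a", "b"), c("b", "c")), name = "P3")
labeled_graph <- function(edges = NULL, vertices = NULL, name = "graph") {
  if (!is.null(edges)) {
    edges <- as.matrix(edges)
    if (length(edges) == 0L) {
      edges <- NULL
    } else {
      if (ncol(edges) != 2L)
        stop("'edges' must have exactly two columns of vertex labels")
      storage.mode(edges) <- "character"
      loops <- edges[, 1L] == edges[, 2L]
      if (any(loops))
        stop("self-loops are not allowed (e.g. edge '", edges[which(loops)[1L], 1L], "')")
    }
  }
  labels <- sort(unique(c(vertices, as.vector(edges))))
  if (anyNA(labels) || any(labels == ""))
    stop("vertex labels must be non-empty strings")
  g <- igraph::make_empty_graph(n = length(labels), directed = FALSE)
  if (length(labels) > 0L)
    igraph::V(g)$name <- labels
  if (!is.null(edges) && nrow(edges) > 0L) {
    key <- paste(pmin(edges[, 1L], edges[, 2L]), pmax(edges[, 1L], edges[, 2L]), sep = "\r")
    edges <- edges[!duplicated(key), , drop = FALSE]
    g <- igraph::add_edges(g, t(edges))
  }
  g$name <- name
  g
}

#' Read a graph from an edge-list file
#'
#' Parses a tab-separated edge list: two label columns per edge, an optional
#' third (weight) column that is parsed and dropped — every distance measure
#' in this package is topology-only. A one-column line declares an isolated
#' vertex, which aligned cohorts need. Lines starting with `#` and blank
#' lines are skipped. Duplicate edges are collapsed.
#'
#' @param path Path to the TSV file.
#' @param name Graph identifier; defaults to the file name without extension.
#' @return An igraph object.
#' @export
read_edge_list <- function(path, name = NULL) {
  if (is.null(name))
    name <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) {
    warning("'", path, "' contains no edges or vertices; returning an empty graph")
    return(labeled_graph(name = name))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf > 3L))
    stop("line ", idx[which(nf > 3L)[1L]], " of '", path, "' has more than 3 columns")
  singles <- vapply(fields[nf == 1L], `[`, character(1L), 1L)
  ed <- fields[nf >= 2L]
  edges <- NULL
  if (length(ed) > 0L) {
    edges <- cbind(
      vapply(ed, `[`, character(1L), 1L),
      vapply(ed, `[`, character(1L), 2L)
    )
    loop <- edges[, 1L] == edges[, 2L]
    if (any(loop))
      stop("self-loop at line ", idx[nf >= 2L][which(loop)[1L]], " of '", path, "'")
  }
  labeled_graph(edges, vertices = singles, name = name)
}

#' Write a graph as an edge-list file
#'
#' Inverse of [read_edge_list()]: edges as two tab-separated label columns
#' (lexicographically ordered within and across rows), isolated vertices as
#' one-column lines. Reading the file back reproduces the identical vertex
#' and edge sets.
#'
#' @param g An igraph object with named vertices.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_edge_list <- function(g, path) {
  ep <- edge_pairs(g)
  lines <- character(0L)
  if (nrow(ep) > 0L) {
    ord <- order(ep[, 1L], ep[, 2L])
    lines <- paste(ep[ord, 1L], ep[ord, 2L], sep = "\t")
  }
  iso <- igraph::V(g)$name[igraph::degree(g) == 0L]
  writeLines(c(lines, sort(iso)), path)
  invisible(path)
}

#' Read a graph from a GraphML file
#'
#' Secondary reader for graphs exchanged as GraphML. Vertex labels are taken
#' from the `name` vertex attribute if present, otherwise from the GraphML
#' node `id`. The graph is coerced to an undirected simple labeled graph.
#'
#' @inheritParams read_edge_list
#' @return An igraph object.
#' @export
read_graphml <- function(path, name = NULL) {
  if (is.null(name))
    name <- sub("\\.[^.]*$", "", basename(path))
  raw <- igraph::read_graph(path, format = "graphml")
  attrs <- igraph::vertex_attr_names(raw)
  labels <- if ("name" %in% attrs) igraph::V(raw)$name else igraph::V(raw)$id
  if (is.null(labels))
    stop("GraphML file '", path, "' has no vertex 'name' or 'id' attribute")
  el <- igraph::as_edgelist(raw, names = FALSE)
  edges <- cbind(labels[el[, 1L]], labels[el[, 2L]])
  edges <- edges[edges[, 1L] != edges[, 2L], , drop = FALSE]  # drop self-loops
  labeled_graph(edges, vertices = labels, name = name)
}

#' Write a graph as GraphML
#'
#' @inheritParams write_edge_list
#' @return Invisibly, `path`.
#' @export
write_graphml <- function(g, path) {
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read a group-assignment table
#'
#' Reads a two-column TSV mapping graph names to group labels (for example
#' `benign` / `cancer`). No header; `#` comment lines allowed; duplicate
#' graph names are rejected.
#'
#' @param path Path to the TSV file.
#' @return Named character vector: `groups[graph_name] == group_label`.
#' @export
read_groups <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  if (!any(keep))
    return(stats::setNames(character(0L), character(0L)))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  if (any(lengths(fields) < 2L))
    stop("'", path, "' must have two tab-separated columns (graph_name, group)")
  nm <- vapply(fields, `[`, character(1L), 1L)
  grp <- vapply(fields, `[`, character(1L), 2L)
  if (anyDuplicated(nm))
    stop("duplicate graph name(s) in '", path, "': ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  stats::setNames(grp, nm)
}

#' Check that every graph has a group assignment
#'
#' @param graphs Named list of igraph objects (or character vector of names).
#' @param groups Named character vector as returned by [read_groups()].
#' @return Invisibly, the group vector subset to the graphs, in graph order.
#' @export
check_groups <- function(graphs, groups) {
  nms <- if (is.character(graphs)) graphs else names(graphs)
  missing <- setdiff(nms, names(groups))
  if (length(missing) > 0L)
    stop("graph(s) missing from the group table: ", paste(missing, collapse = ", "))
  invisible(groups[nms])
}

#' Align the vertex sets of a cohort of graphs
#'
#' Expands every graph onto the union of all vertex labels, adding isolated
#' vertices where needed; edge sets are unchanged. The measures computed on
#' complete (possibly disconnected) networks — pGED and the degree and
#' distance divergences — assume this shared vertex set.
#'
#' @param graphs List of igraph objects (at least one).
#' @return List of igraph objects on the identical, sorted union vertex set.
#' @export
align_vertex_sets <- function(graphs) {
  if (length(graphs) < 1L)
    stop("need at least one graph")
  all_labels <- sort(unique(unlist(lapply(graphs, function(g) igraph::V(g)$name))))
  lapply(graphs, function(g) {
    add <- setdiff(all_labels, igraph::V(g)$name)
    if (length(add) > 0L)
      g <- igraph::add_vertices(g, length(add), name = add)
    # re-sort vertex order for a canonical representation
    g2 <- igraph::permute(g, order(order(igraph::V(g)$name)))
    g2$name <- g$name
    g2
  })
}

#' Largest connected component of a graph
#'
#' Returns the induced subgraph on the largest connected component. A size
#' tie is broken deterministically in favour of the component containing the
#' lexicographically smallest vertex label. The sphere-based and orbit-based
#' distance measures operate on this reduction.
#'
#' @param g An igraph object.
#' @return An igraph object (empty graph in, empty graph out).
#' @export
largest_component <- function(g) {
  if (igraph::vcount(g) == 0L)
    return(g)
  comp <- igraph::components(g)
  best <- which(comp$csize == max(comp$csize))
  if (length(best) > 1L) {
    firsts <- vapply(best, function(b)
      min(igraph::V(g)$name[comp$membership == b]), character(1L))
    best <- best[order(firsts)[1L]]
  }
  sub <- igraph::induced_subgraph(g, which(comp$membership == best))
  sub$name <- g$name
  sub
}

# Canonical m x 2 character matrix of edges: each row sorted, no dups.
edge_pairs <- function(g) {
  el <- igraph::as_edgelist(g, names = TRUE)
  if (nrow(el) == 0L)
    return(matrix(character(0L), ncol = 2L))
  cbind(pmin(el[, 1L], el[, 2L]), pmax(el[, 1L], el[, 2L]))
}

# Edge keys: one string per undirected edge, canonical form.
edge_keys <- function(g) {
  ep <- edge_pairs(g)
  if (nrow(ep) == 0L) return(character(0L))
  paste(ep[, 1L], ep[, 2L], sep = "\r")
}
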