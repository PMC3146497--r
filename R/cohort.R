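# Between-group statistics on within-group distances, normalized-feature
# clustering, and topological characterization of selected prototypes.

#' Within-group pairwise distances
#'
#' Splits a cohort distance matrix into per-group samples of pairwise
#' distances, keeping only pairs whose two graphs belong to the same group.
#' For the symmetric pGED each unordered pair contributes one value
#' (m_g(m_g-1)/2 per group); for the directed KLD measures both orderings
#' are kept (m_g(m_g-1) values).
#'
#' @param dm Matrix from [distance_matrix()].
#' @param groups Named character vector mapping graph name to group label;
#'   must cover every graph in `dm`.
#' @param symmetric Treat the measure as symmetric (one value per unordered
#'   pair)? Defaults to the matrix's own `symmetric` attribute.
#' @return Named list, one numeric vector of distances per group. Groups
#'   with fewer than two graphs yield an empty vector with a warning.
#' @export
within_group_distances <- function(dm, groups, symmetric = NULL) {
  nms <- rownames(dm)
  check_groups(nms, groups)
  if (is.null(symmetric))
    symmetric <- isTRUE(attr(dm, "symmetric"))
  grp <- groups[nms]
  out <- list()
  for (gname in unique(grp)) {
    members <- which(grp == gname)
    if (length(members) < 2L) {
      warning("group '", gname, "' has fewer than two graphs; no within-group distances")
      out[[gname]] <- numeric(0L)
      next
    }
    sub <- dm[members, members, drop = FALSE]
    out[[gname]] <- if (symmetric) sub[upper.tri(sub)]
                    else sub[row(sub) != col(sub)]
  }
  out
}

#' Two-sided Wilcoxon rank-sum comparison of two distance samples
#'
#' Tests whether within-group distances differ in location between two
#' groups. The exact null distribution is used when both samples have at
#' most 25 values and carry no ties; otherwise the normal approximation
#' with continuity correction. The p-value is Bonferroni-adjusted by the
#' number of distance measures tested.
#'
#' @param a,b Numeric vectors of within-group distances (both non-empty).
#' @param n_measures Bonferroni factor: number of measures tested in the
#'   same family.
#' @param alpha Significance level applied to the adjusted p-value.
#' @return List: `statistic` (W), `p_value`, `p_adjusted`, `significant`,
#'   `exact`.
#' @export
#' @examples
#' compare_groups(c(1, 2, 3), c(4, 5, 6))$p_value  # 0.1
compare_groups <- function(a, b, n_measures = 1L, alpha = 0.05) {
  if (length(a) == 0L || length(b) == 0L)
    stop("both samples must be non-empty")
  exact <- length(a) <= 25L && length(b) <= 25L && !anyDuplicated(c(a, b))
  ht <- stats::wilcox.test(a, b, alternative = "two.sided",
                           exact = exact, correct = TRUE)
  p_adj <- min(1, ht$p.value * n_measures)
  list(statistic = unname(ht$statistic),
       p_value = ht$p.value,
       p_adjusted = p_adj,
       significant = p_adj < alpha,
       exact = exact)
}

#' Wilcoxon comparison table across all measures
#'
#' Runs [compare_groups()] for every distance matrix in a named list,
#' comparing the within-group distances of the two groups, with the
#' Bonferroni factor set to the number of measures tested.
#'
#' @param dms Named list of distance matrices (one per measure).
#' @param groups Named character vector with exactly two group labels
#'   across the cohort.
#' @param alpha Significance level.
#' @return Data frame with one row per measure: `measure`, `statistic`,
#'   `p_value`, `p_adjusted`, `significant`.
#' @export
compare_all_measures <- function(dms, groups, alpha = 0.05) {
  stopifnot(length(dms) >= 1L, !is.null(names(dms)))
  glev <- unique(groups[rownames(dms[[1L]])])
  if (length(glev) != 2L)
    stop("group comparison requires exactly two groups, got: ",
         paste(glev, collapse = ", "))
  n_measures <- length(dms)
  rows <- lapply(names(dms), function(ms) {
    wg <- within_group_distances(dms[[ms]], groups)
    cg <- compare_groups(wg[[glev[1L]]], wg[[glev[2L]]],
                         n_measures = n_measures, alpha = alpha)
    data.frame(measure = ms, statistic = cg$statistic, p_value = cg$p_value,
               p_adjusted = cg$p_adjusted, significant = cg$significant,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Within-group mean distance of every graph
#'
#' For each graph, the mean distance to the other graphs of its own group —
#' the quantity summarized per group and fed into feature clustering.
#'
#' @inheritParams within_group_distances
#' @param direction Passed to [mean_distances()].
#' @return Named numeric vector over all graphs.
#' @export
within_group_mean_distances <- function(dm, groups, direction = "out") {
  nms <- rownames(dm)
  check_groups(nms, groups)
  grp <- groups[nms]
  out <- stats::setNames(rep(NA_real_, length(nms)), nms)
  for (gname in unique(grp)) {
    members <- which(grp == gname)
    if (length(members) < 2L) {
      warning("group '", gname, "' has fewer than two graphs; mean distance undefined")
      next
    }
    sub <- dm[members, members, drop = FALSE]
    out[members] <- mean_distances(sub, direction = direction)
  }
  out
}

#' Per-group summary of within-group mean distances
#'
#' @param dms Named list of distance matrices (one per measure).
#' @inheritParams within_group_mean_distances
#' @return Data frame: `measure`, `group`, `min`, `mean`, `max` of the
#'   within-group mean distances.
#' @export
group_mean_summary <- function(dms, groups, direction = "out") {
  rows <- list()
  for (ms in names(dms)) {
    md <- within_group_mean_distances(dms[[ms]], groups, direction = direction)
    grp <- groups[names(md)]
    for (gname in unique(grp)) {
      v <- md[grp == gname]
      v <- v[!is.na(v)]
      rows[[length(rows) + 1L]] <- data.frame(
        measure = ms, group = gname,
        min = min(v), mean = mean(v), max = max(v),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Normalize per-measure features and cluster the cohort
#'
#' Takes a feature matrix with one row per measure and one column per graph
#' (entries: within-group mean distances), min-max normalizes each row over
#' all graphs jointly — without using the group information — and
#' agglomeratively clusters the columns with Euclidean distance under
#' complete (default) or average linkage. A constant row carries no
#' contrast and is set to all zeros with a warning.
#'
#' @param features Numeric matrix, rows = measures, columns = graphs.
#' @param linkage `"complete"` or `"average"`.
#' @return A `cluster_features` list: `matrix` (normalized), `hclust`,
#'   `linkage`.
#' @export
cluster_features <- function(features, linkage = c("complete", "average")) {
  linkage <- match.arg(linkage)
  stopifnot(is.matrix(features), !is.null(colnames(features)))
  norm <- features
  for (i in seq_len(nrow(features))) {
    rng <- range(features[i, ])
    if (diff(rng) == 0) {
      warning("feature row ", rownames(features)[i] %||% i,
              " is constant; set to 0")
      norm[i, ] <- 0
    } else {
      norm[i, ] <- (features[i, ] - rng[1L]) / diff(rng)
    }
  }
  hc <- stats::hclust(stats::dist(t(norm), method = "euclidean"),
                      method = linkage)
  structure(list(matrix = norm, hclust = hc, linkage = linkage),
            class = "cluster_features")
}

#' @export
print.cluster_features <- function(x, ...) {
  cat("Normalized feature clustering (", x$linkage, " linkage, ",
      ncol(x$matrix), " graphs x ", nrow(x$matrix), " measures)\n", sep = "")
  print(x$hclust)
  invisible(x)
}

#' Topological summary of a network
#'
#' Characterizes a (prototype) network: the `n_hubs` largest distinct
#' degree values with the number of vertices attaining each (hub table,
#' computed on the complete graph), and — on the largest connected
#' component — per-vertex eccentricities, the diameter (maximum
#' eccentricity), the average shortest-path length, and the mean local
#' clustering coefficient, where vertices of degree < 2 contribute 0.
#'
#' @param g An igraph object with at least one vertex.
#' @param n_hubs Number of distinct top degree values to tabulate.
#' @return A `topology_summary` list: `hub_table` (data frame degree/count),
#'   `eccentricities` (named vector, LCC vertices), `diameter`,
#'   `avg_path_length`, `avg_clustering`, `n_vertices`, `n_edges`,
#'   `lcc_size`.
#' @export
topology_summary <- function(g, n_hubs = 15L) {
  if (igraph::vcount(g) == 0L)
    stop("topology summary of an empty graph is undefined")
  deg <- igraph::degree(g)
  tab <- table(deg)
  degs <- sort(as.integer(names(tab)), decreasing = TRUE)
  top <- degs[seq_len(min(n_hubs, length(degs)))]
  hub_table <- data.frame(degree = top,
                          count = as.integer(tab[as.character(top)]),
                          row.names = NULL)
  lcc <- largest_component(g)
  ecc <- igraph::eccentricity(lcc)
  if (igraph::vcount(lcc) > 1L) {
    sp <- igraph::distances(lcc)
    apl <- mean(sp[upper.tri(sp)])
  } else {
    apl <- 0
  }
  cc <- igraph::transitivity(lcc, type = "local", isolates = "zero")
  cc[is.nan(cc)] <- 0  # degree-1 vertices: convention 0
  structure(
    list(hub_table = hub_table,
         eccentricities = stats::setNames(ecc, igraph::V(lcc)$name),
         diameter = as.integer(max(ecc)),
         avg_path_length = apl,
         avg_clustering = mean(cc),
         n_vertices = igraph::vcount(g),
         n_edges = igraph::ecount(g),
         lcc_size = igraph::vcount(lcc)),
    class = "topology_summary"
  )
}

#' @export
print.topology_summary <- function(x, ...) {
  cat("Topology summary: ", x$n_vertices, " vertices, ", x$n_edges,
      " edges (largest component: ", x$lcc_size, ")\n", sep = "")
  cat("  diameter ", x$diameter, ", avg path length ",
      format(x$avg_path_length, digits = 4), ", avg clustering ",
      format(x$avg_clustering, digits = 4), "\n", sep = "")
  cat("  top hub degrees:\n")
  print(utils::head(x$hub_table, 5L), row.names = FALSE)
  invisible(x)
}

#' Compare the eccentricity distributions of two networks
#'
#' Two-sample Kolmogorov-Smirnov test on the per-vertex eccentricities of
#' the two largest connected components. Eccentricities are integers, so
#' ties are expected and the p-value is the usual approximate one.
#'
#' @param g1,g2 Non-empty igraph objects.
#' @return List: `statistic` (D), `p_value`.
#' @export
compare_eccentricities <- function(g1, g2) {
  if (igraph::vcount(g1) == 0L || igraph::vcount(g2) == 0L)
    stop("both graphs must be non-empty")
  e1 <- igraph::eccentricity(largest_component(g1))
  e2 <- igraph::eccentricity(largest_component(g2))
  ht <- suppressWarnings(stats::ks.test(e1, e2, alternative = "two.sided"))
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}
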