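# End-to-end runs: generate synthetic cohorts to disk and execute the full
# prototyping workflow on a cohort, writing every result table. Output is
# deterministic for a fixed input and configuration — no timestamps, fixed
# number formatting — so reruns are byte-identical and auditable.

write_tsv <- function(df, path, comments = character(0L)) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments) > 0L)
    writeLines(paste0("# ", comments), con)
  num <- vapply(df, is.numeric, logical(1L)) & !vapply(df, is.integer, logical(1L))
  df[num] <- lapply(df[num], function(x)
    format(x, digits = 15, scientific = FALSE, trim = TRUE))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a synthetic cohort to disk
#'
#' Generates a cohort with [make_cohort()] and writes one edge-list TSV per
#' graph, a `groups.tsv` group table, and a `truth.json` ground-truth record
#' (generation parameters and base-graph edge lists) — exactly the formats
#' the readers in this package consume.
#'
#' @param out_dir Output directory (created if missing).
#' @inheritParams make_cohort
#' @return Invisibly, the cohort list from [make_cohort()].
#' @export
run_synth <- function(out_dir, n_vertices = 500L, attachment_edges = 2L,
                      group_sizes = c(6L, 7L),
                      group_names = c("benign", "cancer"),
                      rewire_fractions = c(0.05, 0.05),
                      shared_base = TRUE, seed = NULL) {
  if (any(group_sizes < 3L))
    warning("group size below 3: within-group statistics will be weak")
  cohort <- make_cohort(n_vertices = n_vertices,
                        attachment_edges = attachment_edges,
                        group_sizes = group_sizes, group_names = group_names,
                        rewire_fractions = rewire_fractions,
                        shared_base = shared_base, seed = seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(cohort$graphs))
    write_edge_list(cohort$graphs[[nm]], file.path(out_dir, paste0(nm, ".tsv")))
  writeLines(paste(names(cohort$groups), cohort$groups, sep = "\t"),
             file.path(out_dir, "groups.tsv"))
  truth <- cohort$truth
  truth$bases <- lapply(truth$bases, function(b)
    list(name = b$name, n_vertices = igraph::vcount(b),
         n_edges = igraph::ecount(b),
         edges = apply(edge_pairs(b), 1L, paste, collapse = "\t")))
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(cohort)
}

read_graph_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.(tsv|graphml)$", full.names = TRUE))
  files <- files[basename(files) != "groups.tsv"]
  if (length(files) == 0L)
    stop("no .tsv or .graphml graph files found in '", dir, "'")
  graphs <- lapply(files, function(f) {
    if (grepl("\\.graphml$", f)) read_graphml(f) else read_edge_list(f)
  })
  stats::setNames(graphs, vapply(graphs, function(g) g$name, character(1L)))
}

#' Run the full graph-prototyping workflow
#'
#' Aligns the cohort onto a common vertex set, computes one distance matrix
#' per requested measure, selects per-group prototypes, compares the two
#' groups' within-group distances (Wilcoxon, Bonferroni-adjusted), clusters
#' the per-measure normalized mean-distance features, and characterizes the
#' topology of each group's consensus prototype (the network selected by
#' the most measures, ties broken by measure order), including a
#' Kolmogorov-Smirnov comparison of the two prototypes' eccentricity
#' distributions. All tables are written to `out_dir` with header comments
#' naming the conventions in force.
#'
#' @param graphs Named list of igraph objects, or a directory of edge-list
#'   `.tsv` / `.graphml` files.
#' @param groups Named character vector (graph name -> group label), or the
#'   path of a group table readable by [read_groups()].
#' @param out_dir Output directory (created if missing).
#' @param measures Subset of [graph_measures()] to run.
#' @param epsilon,log_base,weight_base Divergence and sphere-functional
#'   parameters, see [kld()] and [sphere_probabilities()].
#' @param direction Mean-distance direction for the directed measures,
#'   see [mean_distances()].
#' @param linkage Linkage for [cluster_features()].
#' @param alpha Significance level for the adjusted p-values.
#' @return Invisibly, a list with `distance_matrices`, `prototypes` (data
#'   frame), `group_summary`, `wilcoxon`, `clustering`,
#'   `group_prototypes`, `topology` (per group), `eccentricity_ks`.
#' @export
run_prototyping <- function(graphs, groups, out_dir,
                            measures = graph_measures(),
                            epsilon = 1e-10, log_base = exp(1),
                            weight_base = 0.5,
                            direction = c("out", "in"),
                            linkage = c("complete", "average"),
                            alpha = 0.05) {
  direction <- match.arg(direction)
  linkage <- match.arg(linkage)
  measures <- match.arg(measures, graph_measures(), several.ok = TRUE)
  if (is.character(graphs) && length(graphs) == 1L)
    graphs <- read_graph_dir(graphs)
  if (is.character(groups) && length(groups) == 1L && file.exists(groups))
    groups <- read_groups(groups)
  check_groups(graphs, groups)
  glev <- unique(unname(groups[names(graphs)]))
  if (length(glev) != 2L)
    stop("the workflow compares exactly two groups, got: ",
         paste(glev, collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  conv <- c(paste0("kld_direction: ", direction),
            paste0("epsilon: ", format(epsilon)),
            paste0("sphere_weight_base: ", format(weight_base)),
            paste0("kld_log_base: ", if (log_base == exp(1)) "e" else format(log_base)))

  aligned <- align_vertex_sets(graphs)
  names(aligned) <- names(graphs)

  dms <- list()
  proto_rows <- list()
  measure_proto <- list()  # measure -> group -> prototype name
  for (ms in measures) {
    dm <- distance_matrix(aligned, measure = ms, epsilon = epsilon,
                          log_base = log_base, weight_base = weight_base)
    dms[[ms]] <- dm
    write_distance_matrix(dm, file.path(out_dir, paste0("distance_matrix_", ms, ".tsv")))
    for (gname in glev) {
      members <- names(graphs)[groups[names(graphs)] == gname]
      sub <- dm[members, members, drop = FALSE]
      attr(sub, "measure") <- ms
      attr(sub, "symmetric") <- attr(dm, "symmetric")
      pr <- select_prototype(sub, direction = direction)
      measure_proto[[ms]][[gname]] <- pr$prototype
      proto_rows[[length(proto_rows) + 1L]] <- data.frame(
        measure = ms, group = gname, prototype = pr$prototype,
        mean_distance = unname(pr$mean_distances[pr$prototype]),
        ties = paste(pr$ties, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  prototypes <- do.call(rbind, proto_rows)
  write_tsv(prototypes, file.path(out_dir, "prototypes.tsv"), conv)

  gsum <- group_mean_summary(dms, groups, direction = direction)
  write_tsv(gsum, file.path(out_dir, "group_summary.tsv"), conv)

  wil <- compare_all_measures(dms, groups, alpha = alpha)
  write_tsv(wil, file.path(out_dir, "wilcoxon.tsv"),
            c(conv, paste0("bonferroni_factor: ", length(dms)),
              paste0("alpha: ", format(alpha)),
              paste0("groups: ", paste(glev, collapse = " vs "))))

  feat <- do.call(rbind, lapply(dms, within_group_mean_distances,
                                groups = groups, direction = direction))
  rownames(feat) <- names(dms)
  cf <- cluster_features(feat, linkage = linkage)
  feat_df <- data.frame(measure = rownames(cf$matrix), cf$matrix,
                        check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(feat_df, file.path(out_dir, "cluster_features.tsv"),
            c(conv, paste0("linkage: ", linkage),
              "entries: min-max normalized within-group mean distances"))
  merges <- data.frame(step = seq_len(nrow(cf$hclust$merge)),
                       left = cf$hclust$merge[, 1L],
                       right = cf$hclust$merge[, 2L],
                       height = cf$hclust$height)
  write_tsv(merges, file.path(out_dir, "dendrogram.tsv"),
            c(paste0("linkage: ", linkage),
              "negative indices are graphs (order of cluster_features columns), positive are merge steps",
              paste0("leaves: ", paste(cf$hclust$labels, collapse = ","))))

  # consensus prototype per group: selected by most measures, measure order
  # breaking ties
  group_proto <- vapply(glev, function(gname) {
    picks <- vapply(measures, function(ms) measure_proto[[ms]][[gname]], character(1L))
    counts <- table(factor(picks, levels = unique(picks)))
    names(counts)[which.max(counts)]
  }, character(1L))
  names(group_proto) <- glev

  topo <- list()
  for (gname in glev) {
    ts <- topology_summary(graphs[[group_proto[[gname]]]])
    topo[[gname]] <- ts
    ecc_tab <- table(ts$eccentricities)
    jsonlite::write_json(
      list(group = gname, prototype = group_proto[[gname]],
           n_vertices = ts$n_vertices, n_edges = ts$n_edges,
           lcc_size = ts$lcc_size, diameter = ts$diameter,
           avg_path_length = ts$avg_path_length,
           avg_clustering = ts$avg_clustering,
           hub_table = ts$hub_table,
           eccentricity_counts = list(eccentricity = as.integer(names(ecc_tab)),
                                      count = as.integer(ecc_tab))),
      file.path(out_dir, paste0("topology_", gname, ".json")),
      auto_unbox = TRUE, digits = NA)
  }
  ks <- compare_eccentricities(graphs[[group_proto[[1L]]]],
                               graphs[[group_proto[[2L]]]])
  write_tsv(data.frame(group_a = glev[1L], prototype_a = group_proto[[1L]],
                       group_b = glev[2L], prototype_b = group_proto[[2L]],
                       ks_statistic = ks$statistic, p_value = ks$p_value,
                       stringsAsFactors = FALSE),
            file.path(out_dir, "eccentricity_ks.tsv"))

  jsonlite::write_json(
    list(measures = measures, epsilon = epsilon,
         kld_log_base = if (log_base == exp(1)) "e" else log_base,
         sphere_weight_base = weight_base, kld_direction = direction,
         linkage = linkage, alpha = alpha,
         n_graphs = length(graphs), groups = as.list(table(groups[names(graphs)])),
         aligned_vertices = igraph::vcount(aligned[[1L]]),
         group_prototypes = as.list(group_proto)),
    file.path(out_dir, "run_summary.json"), auto_unbox = TRUE, digits = NA)

  invisible(list(distance_matrices = dms, prototypes = prototypes,
                 group_summary = gsum, wilcoxon = wil, clustering = cf,
                 group_prototypes = group_proto, topology = topo,
                 eccentricity_ks = ks))
}
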