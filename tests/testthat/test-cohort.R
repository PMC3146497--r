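make_group_dm <- function(m, symmetric = TRUE, measure = "pged") {
  nms <- paste0("g", seq_len(m))
  dm <- matrix(stats::runif(m * m), m, m, dimnames = list(nms, nms))
  if (symmetric) dm[lower.tri(dm)] <- t(dm)[lower.tri(dm)]
  diag(dm) <- 0
  attr(dm, "measure") <- measure
  attr(dm, "symmetric") <- symmetric
  dm
}

test_that("within-group samples have the right pair counts", {
  set.seed(1)
  nms <- paste0("g", 1:10)
  dm <- matrix(stats::runif(100), 10, 10, dimnames = list(nms, nms))
  diag(dm) <- 0
  groups <- stats::setNames(rep(c("A", "B"), c(6, 4)), nms)
  attr(dm, "measure") <- "pged"; attr(dm, "symmetric") <- TRUE
  wg <- within_group_distances(dm, groups)
  expect_length(wg$A, 15L)  # 6*5/2 unordered pairs
  expect_length(wg$B, 6L)
  attr(dm, "measure") <- "kld_degree"; attr(dm, "symmetric") <- FALSE
  wg <- within_group_distances(dm, groups)
  expect_length(wg$A, 30L)  # 6*5 ordered pairs
  expect_length(wg$B, 12L)
  # singleton group: empty with a warning
  g1 <- stats::setNames(rep(c("A", "B"), c(9, 1)), nms)
  expect_warning(wg1 <- within_group_distances(dm, g1), "fewer than two")
  expect_length(wg1$B, 0L)
})

test_that("wilcoxon comparison matches known values and enumeration", {
  res <- compare_groups(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$p_value, 0.1)
  expect_true(res$exact)
  # identical multisets: no evidence of a difference
  expect_equal(compare_groups(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  # Bonferroni arithmetic
  expect_equal(compare_groups(c(1, 2, 3), c(4, 5, 6), n_measures = 5)$p_adjusted,
               0.5)
  expect_error(compare_groups(numeric(0), 1:3), "non-empty")
  # exact p equals full rank-split enumeration on random tie-free samples
  set.seed(8)
  for (i in 1:12) {
    n1 <- sample(2:8, 1L); n2 <- sample(2:8, 1L)
    x <- sample(1:100, n1 + n2)
    a <- x[seq_len(n1)]; b <- x[-seq_len(n1)]
    expect_equal(compare_groups(a, b)$p_value, oracle_wilcox_p(a, b),
                 tolerance = 1e-12)
  }
})

test_that("compare_all_measures applies the family-size Bonferroni factor", {
  set.seed(4)
  nms <- paste0("g", 1:8)
  groups <- stats::setNames(rep(c("A", "B"), each = 4), nms)
  dms <- list()
  for (ms in c("pged", "kld_degree")) {
    dm <- matrix(stats::runif(64), 8, 8, dimnames = list(nms, nms))
    diag(dm) <- 0
    attr(dm, "measure") <- ms
    attr(dm, "symmetric") <- ms == "pged"
    dms[[ms]] <- dm
  }
  tab <- compare_all_measures(dms, groups)
  expect_equal(tab$measure, c("pged", "kld_degree"))
  expect_equal(tab$p_adjusted, pmin(1, tab$p_value * 2))
})

test_that("feature normalization and clustering behave as specified", {
  feat <- rbind(m1 = c(2, 4, 6), m2 = c(1, 1, 2))
  colnames(feat) <- c("x", "y", "z")
  cf <- cluster_features(feat)
  expect_equal(unname(cf$matrix["m1", ]), c(0, 0.5, 1))
  expect_equal(unname(cf$matrix["m2", ]), c(0, 0, 1))
  # constant row: zeroed with a warning
  featc <- rbind(m1 = c(2, 4, 6), m2 = c(3, 3, 3))
  colnames(featc) <- c("x", "y", "z")
  expect_warning(cfc <- cluster_features(featc), "constant")
  expect_equal(unname(cfc$matrix["m2", ]), c(0, 0, 0))
  # identical columns merge first, at height 0
  feat2 <- rbind(m1 = c(1, 1, 5), m2 = c(2, 2, 9))
  colnames(feat2) <- c("x", "y", "z")
  hc <- cluster_features(feat2)$hclust
  expect_equal(hc$height[1L], 0)
  expect_setequal(hc$labels[-hc$merge[1L, ]], c("x", "y"))
})

test_that("three-point agglomeration follows hand-computed merge order", {
  # columns at 0, 0.1, 1 on one normalized axis: x,y merge at 0.1, then z:
  # complete linkage height max(0.9, 1); average linkage (0.9 + 1) / 2
  feat <- rbind(m1 = c(0, 0.1, 1))
  colnames(feat) <- c("x", "y", "z")
  suppressWarnings({
    hc_c <- cluster_features(feat, linkage = "complete")$hclust
    hc_a <- cluster_features(feat, linkage = "average")$hclust
  })
  expect_equal(hc_c$height, c(0.1, 1))
  expect_equal(hc_a$height, c(0.1, 0.95))
})

test_that("clustering is invariant to graph input order", {
  set.seed(21)
  feat <- matrix(stats::runif(20), 4, 5,
                 dimnames = list(paste0("m", 1:4), paste0("g", 1:5)))
  h1 <- cluster_features(feat)$hclust
  perm <- c(3, 5, 1, 2, 4)
  h2 <- cluster_features(feat[, perm])$hclust
  expect_equal(h1$height, h2$height)
  # same partition at every merge level
  for (k in 2:4) {
    c1 <- stats::cutree(h1, k)
    c2 <- stats::cutree(h2, k)[names(c1)]
    expect_equal(length(unique(paste(c1, c2))), k)
  }
})

test_that("topology summaries match hand-computed values", {
  ts <- topology_summary(path_graph(4L))
  expect_equal(unname(ts$eccentricities[c("a", "b", "c", "d")]), c(3, 2, 2, 3))
  expect_equal(ts$diameter, 3L)
  expect_equal(ts$avg_path_length, 10 / 6)
  expect_equal(ts$avg_clustering, 0)  # degree<2 and triangle-free: all 0
  expect_equal(topology_summary(complete_graph(3L))$avg_clustering, 1)
  # star on 5 vertices: hub table rows degree 4 (1 vertex), degree 1 (4)
  hub <- topology_summary(star_graph(4L))$hub_table
  expect_equal(hub$degree, c(4L, 1L))
  expect_equal(hub$count, c(1L, 4L))
  expect_error(topology_summary(labeled_graph()), "empty")
})

test_that("hub table ranks distinct degrees and caps at n_hubs rows", {
  set.seed(10)
  g <- make_base_graph(300, 3, seed = 5)
  hub <- topology_summary(g)$hub_table
  expect_lte(nrow(hub), 15L)
  expect_true(all(diff(hub$degree) < 0))
  deg <- igraph::degree(g)
  for (i in seq_len(nrow(hub)))
    expect_equal(hub$count[i], sum(deg == hub$degree[i]))
})

test_that("eccentricity comparison reproduces hand-computed KS statistics", {
  p4 <- path_graph(4L)
  expect_equal(compare_eccentricities(p4, p4)$statistic, 0)
  # C4 (all ecc 2) vs P4 (ecc 2,2,3,3): D = |F1(2) - F2(2)| = 0.5
  expect_equal(compare_eccentricities(cycle_graph(4L), p4)$statistic, 0.5)
  # disjoint ranges: C4 (all 2) vs P8 (ecc 4..7): D = 1
  expect_equal(compare_eccentricities(cycle_graph(4L), path_graph(8L))$statistic, 1)
  expect_error(compare_eccentricities(labeled_graph(), p4), "non-empty")
})

test_that("within-group mean distances feed the per-group summary", {
  nms <- paste0("g", 1:5)
  dm <- matrix(0, 5, 5, dimnames = list(nms, nms))
  dm[1:3, 1:3] <- 2; dm[4:5, 4:5] <- 6
  diag(dm) <- 0
  attr(dm, "measure") <- "pged"; attr(dm, "symmetric") <- TRUE
  groups <- stats::setNames(rep(c("A", "B"), c(3, 2)), nms)
  md <- within_group_mean_distances(dm, groups)
  expect_equal(unname(md), c(2, 2, 2, 6, 6))
  gs <- group_mean_summary(list(pged = dm), groups)
  expect_equal(gs$mean, c(2, 6))
  expect_equal(gs$min, gs$max)
})
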