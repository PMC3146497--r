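test_that("edge-list parsing handles edges, isolates, comments and weights", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# a comment", "a\tb", "b\tc", "", "d", "a\tb\t0.73"), f)
  g <- read_edge_list(f, name = "P3iso")
  expect_setequal(igraph::V(g)$name, c("a", "b", "c", "d"))
  expect_equal(igraph::ecount(g), 2L)  # duplicate a-b collapsed, weight dropped
  expect_equal(igraph::degree(g, "d"), c(d = 0))
  expect_equal(g$name, "P3iso")
})

test_that("self-loops are rejected with the offending line number", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tb", "c\tc"), f)
  expect_error(read_edge_list(f), "line 2")
})

test_that("an empty edge-list file yields an empty graph with a warning", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# only comments"), f)
  expect_warning(g <- read_edge_list(f), "empty")
  expect_equal(igraph::vcount(g), 0L)
})

test_that("edge lists round-trip through write and read", {
  set.seed(41)
  for (i in 1:20) {
    g <- rand_graph(sample(3:12, 1L), p = stats::runif(1, 0.1, 0.6))
    f <- withr::local_tempfile(fileext = ".tsv")
    write_edge_list(g, f)
    g2 <- read_edge_list(f, name = g$name)
    expect_setequal(igraph::V(g2)$name, igraph::V(g)$name)
    expect_setequal(graphproto:::edge_keys(g2), graphproto:::edge_keys(g))
  }
})

test_that("graphml round-trips vertex labels and edges", {
  g <- mk(c("x", "y"), c("y", "z"), vertices = "lonely", name = "gm")
  f <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(g, f)
  g2 <- read_graphml(f, name = "gm")
  expect_setequal(igraph::V(g2)$name, igraph::V(g)$name)
  expect_setequal(graphproto:::edge_keys(g2), graphproto:::edge_keys(g))
})

test_that("vertex-set alignment takes the union and only adds isolates", {
  g1 <- mk(c("a", "b"), name = "g1")
  g2 <- mk(c("b", "c"), name = "g2")
  al <- align_vertex_sets(list(g1, g2))
  for (g in al)
    expect_equal(igraph::V(g)$name, c("a", "b", "c"))
  expect_equal(graphproto:::edge_keys(al[[1L]]), graphproto:::edge_keys(g1))
  expect_equal(graphproto:::edge_keys(al[[2L]]), graphproto:::edge_keys(g2))
  expect_equal(igraph::degree(al[[1L]], "c"), c(c = 0))
  # idempotence and the single-graph case
  al2 <- align_vertex_sets(al)
  expect_equal(lapply(al2, igraph::ecount), lapply(al, igraph::ecount))
  expect_equal(igraph::V(align_vertex_sets(list(g1))[[1L]])$name, c("a", "b"))
  # names survive
  expect_equal(al[[2L]]$name, "g2")
})

test_that("alignment preserves every edge across random cohorts", {
  set.seed(7)
  for (i in 1:10) {
    graphs <- lapply(1:4, function(j)
      rand_graph(8, 0.3, labels = sample(letters, 8), name = paste0("g", j)))
    al <- align_vertex_sets(graphs)
    for (j in 1:4) {
      expect_setequal(graphproto:::edge_keys(al[[j]]),
                      graphproto:::edge_keys(graphs[[j]]))
      added <- setdiff(igraph::V(al[[j]])$name, igraph::V(graphs[[j]])$name)
      if (length(added) > 0L)
        expect_true(all(igraph::degree(al[[j]], added) == 0))
    }
  }
})

test_that("largest component extraction is correct and deterministic on ties", {
  g <- mk(c("a", "b"), c("b", "c"), vertices = "d", name = "p3iso")
  lcc <- largest_component(g)
  expect_setequal(igraph::V(lcc)$name, c("a", "b", "c"))
  # tie between {a,b} and {c,d}: smallest member label wins
  tie <- mk(c("c", "d"), c("a", "b"), name = "tie")
  expect_setequal(igraph::V(largest_component(tie))$name, c("a", "b"))
  # connected graph is returned whole; empty in, empty out
  k3 <- complete_graph(3L)
  expect_equal(igraph::vcount(largest_component(k3)), 3L)
  expect_equal(igraph::vcount(largest_component(labeled_graph())), 0L)
})

test_that("largest component size matches a BFS oracle on random graphs", {
  set.seed(11)
  for (i in 1:25) {
    g <- rand_graph(sample(4:20, 1L), p = stats::runif(1, 0.05, 0.3))
    expect_equal(igraph::vcount(largest_component(g)),
                 max(oracle_component_sizes(g)))
  }
})

test_that("group tables parse, reject duplicates, and flag missing graphs", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("yu\tbenign", "wang\tcancer"), f)
  groups <- read_groups(f)
  expect_equal(groups, c(yu = "benign", wang = "cancer"))
  writeLines(c("yu\tbenign", "yu\tcancer"), f)
  expect_error(read_groups(f), "duplicate")
  writeLines(character(0L), f)
  expect_length(read_groups(f), 0L)
  expect_error(check_groups(c("yu", "singh"), groups), "singh")
})

test_that("labeled_graph enforces simple-graph invariants", {
  expect_error(labeled_graph(cbind("a", "a")), "self-loop")
  g <- labeled_graph(rbind(c("a", "b"), c("b", "a"), c("a", "b")))
  expect_equal(igraph::ecount(g), 1L)
  expect_equal(igraph::V(g)$name, c("a", "b"))
})
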