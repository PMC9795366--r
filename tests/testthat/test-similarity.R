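test_that("jaccard similarity follows the set definition", {
  expect_equal(jaccard(c("a", "b"), c("b", "c")), 1 / 3)
  expect_equal(jaccard(c("x", "y"), c("x", "y")), 1)
  expect_equal(jaccard("a", "b"), 0)
  expect_equal(jaccard(character(0), character(0)), 0)
  # symmetric, duplicate-insensitive
  set.seed(31)
  for (rep in 1:10) {
    u <- sample(letters, sample(0:8, 1))
    v <- sample(letters, sample(1:8, 1))
    expect_equal(jaccard(u, v), jaccard(v, u))
    expect_equal(jaccard(c(u, u), v), jaccard(u, v))
  }
})

test_that("pairwise jaccard graph matches the exhaustive pair loop", {
  feats <- list(a = c("t1", "t2"), b = c("t1", "t2"), c = c("t1", "t2"))
  g_same <- pairwise_jaccard(feats)
  expect_true(all(g_same$adjacency[upper.tri(g_same$adjacency)] == 1))
  expect_true(all(diag(g_same$adjacency) == 0))

  disjoint <- list(a = "t1", b = "t2", c = "t3")
  expect_true(all(pairwise_jaccard(disjoint)$adjacency == 0))

  set.seed(32)
  feats <- lapply(1:4, function(i) sample(paste0("t", 1:30), 10))
  names(feats) <- paste0("e", 1:4)
  g <- pairwise_jaccard(feats)
  for (i in 1:4) {
    for (j in 1:4) {
      if (i != j) {
        expect_identical(g$adjacency[i, j],
                         jaccard(feats[[i]], feats[[j]]))
      }
    }
  }
  expect_warning(pairwise_jaccard(list(a = "t", b = character(0))), "empty")
})

toy_tree <- function() {
  # depth-4 balanced binary tree; leaves like root.1.1.1.1
  make_toy_hierarchy(2, 4, paste0("d", 1:4), seed = 1)
}

test_that("set shortest path reproduces the taxonomy distance bounds", {
  h <- toy_tree()
  leaves <- grep("^root(\\.\\d+){4}$", h$nodes, value = TRUE)
  expect_equal(set_shortest_path("root.1.1.1.1", "root.1.1.1.1", h), 0)
  # siblings under one parent sit at distance 2
  expect_equal(set_shortest_path("root.1.1.1.1", "root.1.1.1.2", h), 2)
  # opposite top-level branches of the 4-level tree sit at distance 8
  expect_equal(set_shortest_path("root.1.1.1.1", "root.2.1.1.1", h), 8)
  expect_equal(max(outer(leaves, leaves, Vectorize(function(a, b) {
    set_shortest_path(a, b, h)
  }))), 8)
  # shared codes collapse the set distance to zero
  expect_equal(set_shortest_path(c("root.1.1.1.1", "root.2.2.2.2"),
                                 c("root.2.2.2.2"), h), 0)
  expect_error(set_shortest_path("nope", "root.1.1.1.1", h), "absent")
})

test_that("set shortest path agrees with a hand-rolled BFS oracle", {
  h <- toy_tree()
  edges <- as.matrix(h$parent_edges)
  leaves <- grep("^root(\\.\\d+){4}$", h$nodes, value = TRUE)
  set.seed(33)
  for (rep in 1:10) {
    a <- sample(leaves, 1)
    b <- sample(leaves, 1)
    expect_equal(set_shortest_path(a, b, h), oracle_bfs(edges, a, b))
  }
})

test_that("set shortest path is symmetric with zero self-distance", {
  h <- toy_tree()
  leaves <- grep("^root(\\.\\d+){4}$", h$nodes, value = TRUE)
  set.seed(34)
  sets <- lapply(1:6, function(i) sample(leaves, sample(1:3, 1)))
  sp <- function(u, v) set_shortest_path(sets[[u]], sets[[v]], h)
  for (u in 1:6) {
    expect_equal(sp(u, u), 0)
    for (v in 1:6) {
      expect_equal(sp(u, v), sp(v, u))
    }
  }
})

test_that("single-code annotations inherit the graph triangle inequality", {
  # minimum aggregation over multi-code sets can violate the triangle
  # inequality (an entity can be near one code of a hub set whose other
  # code is near a third entity); with one code per entity the set
  # distance is the plain graph metric, which is a true metric
  h <- toy_tree()
  leaves <- grep("^root(\\.\\d+){4}$", h$nodes, value = TRUE)
  set.seed(35)
  codes <- sample(leaves, 6)
  sp <- function(u, v) set_shortest_path(codes[u], codes[v], h)
  for (u in 1:6) {
    for (v in 1:6) {
      for (w in 1:6) {
        expect_lte(sp(u, w), sp(u, v) + sp(v, w))
      }
    }
  }
})

test_that("taxonomy similarity applies the empirical-max normalization", {
  # hand-built 4-level path to two top branches: known SP table
  edges <- data.frame(
    child = c("A", "B", "A1", "A2", "B1", "A1a", "A2a", "B1a",
               "A1a1", "A1a2", "A2a1", "B1a1"),
    parent = c("root", "root", "A", "A", "B", "A1", "A2", "B1",
               "A1a", "A1a", "A2a", "B1a"))
  h <- hierarchy(edges, list(u = "A1a1", v = "A1a2", w = "B1a1"))
  g <- taxonomy_similarity(h)
  # SP(u,v) = 2 siblings, SP(u,w) = SP(v,w) = 8 across root; max = 8
  expect_equal(g$adjacency["u", "v"], 1 - 2 / 8)
  expect_equal(g$adjacency["u", "w"], 0)
  expect_true(all(g$adjacency >= 0 & g$adjacency <= 1))

  # a shared annotation code forces similarity 1
  h2 <- hierarchy(edges, list(u = "A1a1", v = c("A1a1", "B1a1"),
                              w = "B1a1"))
  g2 <- taxonomy_similarity(h2)
  expect_equal(g2$adjacency["u", "v"], 1)

  # two entities only: the lone distance is the empirical max, similarity 0
  h3 <- hierarchy(edges, list(u = "A1a1", v = "A2a1"))
  expect_equal(taxonomy_similarity(h3)$adjacency["u", "v"], 0)

  # all entities sharing one code cannot be normalized
  h4 <- hierarchy(edges, list(u = "A1a1", v = "A1a1"))
  expect_error(taxonomy_similarity(h4), "degenerate")
})

test_that("taxonomy similarity is invariant to entity ordering", {
  h <- toy_tree()
  ann <- h$annotations
  h_rev <- hierarchy(h$parent_edges, rev(ann))
  g <- taxonomy_similarity(h)
  g_rev <- taxonomy_similarity(h_rev)
  ids <- g$entity_ids
  expect_equal(g$adjacency[ids, ids], g_rev$adjacency[ids, ids])
})

test_that("hierarchies reject cycles and unknown annotation codes", {
  expect_error(hierarchy(data.frame(child = c("a", "b"),
                                    parent = c("b", "a")),
                         list(e = "a")),
               "cycle")
  expect_error(hierarchy(data.frame(child = "a", parent = "b"),
                         list(e = "zzz")),
               "unknown")
})
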