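# Graph construction, trimming semantics, shortest paths, the six
# centrality metrics against exhaustive enumeration, and sum-rank scoring.

path_graph <- function(ids) {
  gene_graph(ids, data.frame(from = ids[-length(ids)], to = ids[-1]))
}

test_that("co-expression graphs connect genes above the correlation threshold", {
  set.seed(1)
  base <- rnorm(30)
  mat <- rbind(a = base, b = base * 2 + 3,        # perfectly correlated pair
               c = -base,                          # perfect anti-correlation
               d = rnorm(30), e = rnorm(30))      # independent noise
  colnames(mat) <- paste0("s", 1:30)
  g <- build_coexpression_graph(mat, rownames(mat), 0.9)
  key <- paste(g$edges$from, g$edges$to)
  expect_true("a b" %in% key)
  expect_true("a c" %in% key)                     # |r| is what counts
  expect_equal(g$edges$weight[key == "a b"], 1, tolerance = 1e-12)
  # independent noise at a punishing threshold stays disconnected
  g2 <- build_coexpression_graph(mat[c("d", "e"), ], c("d", "e"), 0.99)
  expect_equal(nrow(g2$edges), 0L)
  expect_error(build_coexpression_graph(mat, rownames(mat), 1), "between 0 and 1")
  flat <- rbind(mat, f = rep(1, 30))
  expect_warning(build_coexpression_graph(flat, rownames(flat), 0.9),
                 "zero-variance")
})

test_that("trimming removes excluded ids first, then degree <= 1 in one pass", {
  # triangle plus pendant: pendant goes, triangle stays
  g <- gene_graph(c("A", "B", "C", "P"),
                  data.frame(from = c("A", "B", "C", "A"),
                             to   = c("B", "C", "A", "P")))
  t1 <- trim_graph(g)
  expect_setequal(t1$nodes, c("A", "B", "C"))
  expect_equal(nrow(t1$edges), 3L)
  # star K1,3: leaves have degree 1 and go; the centre is kept as an
  # isolated node because the pass is not iterated
  star <- gene_graph(c("hub", "l1", "l2", "l3"),
                     data.frame(from = "hub", to = c("l1", "l2", "l3")))
  t2 <- trim_graph(star)
  expect_identical(t2$nodes, "hub")
  expect_equal(nrow(t2$edges), 0L)
  expect_equal(length(trim_graph(star, iterate = TRUE)$nodes), 0L)
  # 4-path: endpoints (degree 1) go, B-C edge survives
  p4 <- path_graph(c("A", "B", "C", "D"))
  t3 <- trim_graph(p4)
  expect_setequal(t3$nodes, c("B", "C"))
  expect_equal(nrow(t3$edges), 1L)
  # exclusion precedes the degree pass
  t4 <- trim_graph(g, excluded_ids = "A")
  expect_equal(length(t4$nodes), 0L)   # B, C drop to degree 1 once A is gone
})

test_that("trimming contract holds on random graphs: no survivor had post-exclusion degree <= 1", {
  set.seed(11)
  for (i in 1:100) {
    A <- random_adjacency(sample(4:10, 1), 0.3)
    g <- graph_from_adjacency(A)
    excl <- sample(g$nodes, sample(0:2, 1))
    pre <- apneahub:::subgraph_drop(g, excl)
    pre_deg <- apneahub:::graph_degrees(pre)
    trimmed <- trim_graph(g, excluded_ids = excl)
    expect_true(all(pre_deg[trimmed$nodes] >= 2))
    expect_setequal(trimmed$nodes, names(which(pre_deg >= 2)))
  }
})

test_that("shortest-path counts match hand values and the matrix-power oracle", {
  p3 <- path_graph(c("A", "B", "C"))
  sp <- all_pairs_shortest_paths(p3)
  expect_equal(sp$distance["A", "C"], 2)
  expect_equal(sp$npaths["A", "C"], 1)
  expect_equal(sp$distance["A", "A"], 0)
  expect_equal(sp$npaths["A", "A"], 1)
  c4 <- gene_graph(c("A", "B", "C", "D"),
                   data.frame(from = c("A", "B", "C", "D"),
                              to   = c("B", "C", "D", "A")))
  sp4 <- all_pairs_shortest_paths(c4)
  expect_equal(sp4$distance["A", "C"], 2)
  expect_equal(sp4$npaths["A", "C"], 2)    # both ways round the square
  # disconnected pairs: infinite distance, zero paths
  two <- gene_graph(c("A", "B", "C"), data.frame(from = "A", to = "B"))
  spd <- all_pairs_shortest_paths(two)
  expect_true(is.infinite(spd$distance["A", "C"]))
  expect_equal(spd$npaths["A", "C"], 0)
  set.seed(5)
  for (i in 1:30) {
    A <- random_adjacency(sample(3:8, 1), 0.35)
    sp <- all_pairs_shortest_paths(graph_from_adjacency(A))
    pw <- power_path_counts(A)
    expect_equal(unname(sp$distance), unname(pw$distance))
    expect_equal(unname(sp$npaths), unname(pw$npaths))
  }
})

test_that("centralities match hand enumeration on the 3-path and triangle", {
  ce <- compute_centralities(path_graph(c("A", "B", "C")))
  b <- ce[ce$gene_id == "B", ]
  a <- ce[ce$gene_id == "A", ]
  expect_equal(b$betweenness, 1)
  expect_equal(b$stress, 1)
  expect_equal(b$closeness, 1)
  expect_equal(a$closeness, 2 / 3)
  expect_equal(ce$clustering, rep(0, 3))
  expect_equal(a$neighborhood_connectivity, 2)
  tri <- gene_graph(c("A", "B", "C"),
                    data.frame(from = c("A", "B", "C"), to = c("B", "C", "A")))
  ct <- compute_centralities(tri)
  expect_equal(ct$degree, rep(2L, 3))
  expect_equal(ct$clustering, rep(1, 3))
  expect_equal(ct$closeness, rep(1, 3))
  expect_equal(ct$betweenness, rep(0, 3))
  expect_equal(ct$stress, rep(0, 3))
  expect_equal(ct$neighborhood_connectivity, rep(2, 3))
})

test_that("all six metrics equal the exhaustive-enumeration oracle on random graphs", {
  set.seed(21)
  for (i in 1:60) {
    A <- random_adjacency(sample(3:8, 1), 0.3)
    ce <- compute_centralities(graph_from_adjacency(A))
    or <- oracle_centralities(A)
    expect_equal(ce$degree, as.integer(or$degree))
    expect_equal(ce$clustering, or$clustering)
    expect_equal(ce$closeness, or$closeness)
    expect_equal(ce$betweenness, or$betweenness)
    expect_equal(ce$neighborhood_connectivity, or$neighborhood_connectivity)
    expect_equal(ce$stress, or$stress)
    # per-pair contribution to stress is at least its betweenness share
    expect_true(all(ce$betweenness <= ce$stress + 1e-12))
  }
})

test_that("metrics agree with igraph where igraph implements them", {
  skip_if_not_installed("igraph")
  set.seed(33)
  for (i in 1:20) {
    A <- random_adjacency(sample(4:8, 1), 0.5)
    g <- graph_from_adjacency(A)
    ce <- compute_centralities(g)
    ig <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    expect_equal(ce$degree, unname(igraph::degree(ig)))
    expect_equal(ce$betweenness, unname(igraph::betweenness(ig)))
    cl <- igraph::transitivity(ig, type = "local", isolates = "zero")
    expect_equal(ce$clustering, unname(cl))
    if (igraph::is_connected(ig) && igraph::vcount(ig) > 1) {
      expect_equal(ce$closeness,
                   unname(igraph::closeness(ig, normalized = TRUE)))
      knn <- igraph::knn(ig)$knn
      expect_equal(ce$neighborhood_connectivity, unname(knn))
    }
  }
})

test_that("metric values are invariant under node relabeling", {
  set.seed(55)
  A <- random_adjacency(7, 0.4)
  ce <- compute_centralities(graph_from_adjacency(A))
  perm <- sample(7)
  B <- A[perm, perm]
  dimnames(B) <- dimnames(A)   # same labels, permuted structure
  ceB <- compute_centralities(graph_from_adjacency(B))
  # node i of the relabeled graph has the structure of original node perm[i]
  for (m in c("degree", "clustering", "closeness", "betweenness",
              "neighborhood_connectivity", "stress")) {
    expect_equal(ceB[[m]], ce[[m]][perm], info = m)
  }
})

test_that("sum rank scores use descending fractional ranks and respect monotone transforms", {
  ce <- data.frame(gene_id = c("a", "b", "c"),
                   degree = c(3L, 2L, 1L), clustering = c(0.9, 0.1, 0.5),
                   closeness = c(1, 0.5, 0.2), betweenness = c(4, 0, 1),
                   neighborhood_connectivity = c(3, 2, 1), stress = c(5, 0, 2))
  rs <- sum_rank_scores(ce)
  expect_equal(rs$sum_rank_score[rs$gene_id == "a"], 6)  # best on all six
  expect_true(all(rs$sum_rank_score >= 6 & rs$sum_rank_score <= 6 * 3))
  # rank columns each sum to n(n+1)/2
  rank_cols <- grep("_rank$", colnames(rs), value = TRUE)
  for (col in rank_cols) expect_equal(sum(rs[[col]]), 6)
  # two tied nodes in a 2-node table: both 6 * 1.5
  tie <- ce[1:2, ]; tie[2, -1] <- tie[1, -1]
  rs2 <- sum_rank_scores(tie)
  expect_equal(rs2$sum_rank_score, c(9, 9))
  # strictly increasing transform of one metric leaves all scores unchanged
  tr <- ce; tr$betweenness <- exp(tr$betweenness)
  expect_equal(sum_rank_scores(tr)$sum_rank_score, rs$sum_rank_score)
  tr2 <- ce; tr2$closeness <- tr2$closeness^3 + 1
  expect_equal(sum_rank_scores(tr2)$sum_rank_score, rs$sum_rank_score)
})

test_that("hub prioritization orders by score, then fold change, then id", {
  rs <- data.frame(gene_id = c("a", "b", "c", "d"),
                   sum_rank_score = c(10, 8, 8, 12))
  fc <- c(a = 2, b = 2, c = 4, d = 8)
  rep <- prioritize_hubs(rs, fc)
  expect_equal(rep$gene_id, c("c", "b", "a", "d"))  # 8-tie: fc 4 beats 2
  expect_warning(out <- prioritize_hubs(rs, fc[-1]), "without a fold change")
  expect_false("a" %in% out$gene_id)
  one <- prioritize_hubs(rs[1, , drop = FALSE], fc)
  expect_equal(nrow(one), 1L)
})
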