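cpx_table <- function(...) {
  lst <- list(...)
  do.call(rbind, lapply(seq_along(lst), function(i)
    data.frame(complex_id = sprintf("CPX-%d", i),
               complex_name = names(lst)[i], protein_id = lst[[i]],
               stringsAsFactors = FALSE)))
}

test_that("complex tables become clique networks without redundancy", {
  net <- build_network(cpx_table(tri = c("a", "b", "c")))
  expect_equal(igraph::ecount(net$graph), 3)

  shared <- build_network(cpx_table(one = c("a", "b", "x"),
                                    two = c("x", "c", "d")))
  expect_equal(igraph::count_components(shared$graph), 1)

  dup <- cpx_table(one = c("a", "b", "c"))
  dup <- rbind(dup, dup)
  expect_equal(igraph::ecount(build_network(dup)$graph), 3)

  empty <- build_network(data.frame(complex_id = character(0),
                                    complex_name = character(0),
                                    protein_id = character(0)))
  expect_equal(igraph::vcount(empty$graph), 0)
})

test_that("personalized PageRank matches a direct linear solve", {
  g <- igraph::make_graph(~ a - b, b - c)
  pr <- personalized_pagerank(g, "a", damping = 0.9)
  adj <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  w <- adj / rowSums(adj)
  r <- c(a = 1, b = 0, c = 0)[rownames(adj)]
  x <- solve(diag(3) - 0.9 * t(w), (1 - 0.9) * r)
  x <- x / sum(x)
  expect_lt(max(abs(pr[rownames(adj)] - x)), 1e-8)
  expect_equal(sum(pr), 1, tolerance = 1e-9)

  # single isolated seed keeps all mass
  g2 <- igraph::make_graph(~ a - b) + igraph::vertices("z")
  expect_equal(unname(personalized_pagerank(g2, "z")["z"]), 1,
               tolerance = 1e-12)

  # vertex-transitive graph seeded everywhere: uniform scores
  ring <- igraph::make_ring(8)
  igraph::V(ring)$name <- letters[1:8]
  pr_ring <- personalized_pagerank(ring, letters[1:8])
  expect_equal(unname(pr_ring), rep(1 / 8, 8), tolerance = 1e-10)

  expect_error(personalized_pagerank(g, "nope"), "seed")
})

test_that("top-quantile selection is inclusive at the threshold", {
  g <- igraph::make_ring(10)
  igraph::V(g)$name <- letters[1:10]
  sc <- setNames(10:1, letters[1:10])
  sub <- top_quantile_subnetwork(g, sc, 0.4)
  expect_equal(igraph::vcount(sub), 4)

  expect_equal(igraph::vcount(
    top_quantile_subnetwork(g, setNames(rep(1, 10), letters[1:10]), 0.4)), 10)
  expect_equal(igraph::vcount(top_quantile_subnetwork(g, sc, 1.0)), 10)
})

test_that("walktrap recovers planted communities", {
  # two disjoint triangles
  tri2 <- igraph::graph_from_data_frame(
    data.frame(from = c("a", "b", "c", "x", "y", "z"),
               to = c("b", "c", "a", "y", "z", "x")), directed = FALSE)
  mem <- walktrap_clusters(tri2)
  expect_equal(length(unique(mem)), 2)
  expect_equal(length(unique(mem[c("a", "b", "c")])), 1)

  # k planted cliques, k = 2..4, bridged
  for (k in 2:4) {
    net <- simulate_complex_network(rep(5, k), n_bridge_edges = k - 1,
                                    seed = 13)
    g <- igraph::graph_from_data_frame(net$edges, directed = FALSE)
    mem <- walktrap_clusters(g, steps = 4)
    expect_equal(length(unique(mem)), k)
    # planted partition recovered exactly
    agree <- table(mem[names(net$membership)], net$membership)
    expect_equal(sum(agree > 0), k)
  }

  # complete graph: one community
  kg <- igraph::make_full_graph(6)
  igraph::V(kg)$name <- letters[1:6]
  expect_equal(length(unique(walktrap_clusters(kg))), 1)
})

test_that("clusters are size-filtered and named by changing markers", {
  tab <- cpx_table(alpha = c("a1", "a2", "a3", "a4"),
                   beta = c("b1", "b2", "b3", "b4"),
                   tiny = c("t1", "t2", "t3"))
  net <- build_network(tab)
  membership <- setNames(c(1, 1, 1, 1, 2, 2, 2, 2, 3, 3, 3),
                         c(paste0("a", 1:4), paste0("b", 1:4),
                           paste0("t", 1:3)))
  out <- filter_and_name(membership, net, changed_proteins = c("a1", "a2",
                                                               "b1"))
  expect_equal(nrow(out), 2)  # the 3-member cluster is dropped
  expect_equal(out$name[out$cluster_id == 1], "alpha")
  expect_equal(out$n_changing[out$cluster_id == 1], 2)

  # all changing markers shared by two complexes -> both names
  tab2 <- cpx_table(first = c("s1", "s2", "s3", "s4"),
                    second = c("s1", "s2", "s3", "s4"))
  net2 <- build_network(tab2)
  mem2 <- setNames(rep(1, 4), paste0("s", 1:4))
  out2 <- filter_and_name(mem2, net2, changed_proteins = c("s1", "s2"))
  expect_equal(out2$name, "first/second")
})

test_that("condition comparison classifies marker-set changes", {
  clusters <- data.frame(cluster_id = 1:3, name = "x", size = 4,
                         n_changing = 1,
                         members = c("a;b", "c;d", "e;f"),
                         changing_members = "", stringsAsFactors = FALSE)
  m1 <- data.frame(protein_id = c("a", "a", "c", "e"),
                   region_id = c("r1", "r2", "r3", "r5"),
                   stringsAsFactors = FALSE)
  m2 <- data.frame(protein_id = c("a", "c", "e"),
                   region_id = c("r1", "r3", "r6"),
                   stringsAsFactors = FALSE)
  out <- compare_conditions(clusters, m1, m2)
  expect_equal(out$delta, c("gain_c1", "shared", "divergent"))

  none <- compare_conditions(clusters[1, ], m1[0, ], m2[0, ])
  expect_equal(none$delta, "none")
})

test_that("the network stage is deterministic end to end", {
  run <- function() {
    net <- simulate_complex_network(c(5, 5, 4), n_bridge_edges = 3, seed = 9)
    fn <- build_network(net$complexes, extra_edges = net$edges)
    pr <- personalized_pagerank(fn, seed_proteins = net$complexes$protein_id[1:4])
    sub <- top_quantile_subnetwork(fn, pr, 0.6)
    mem <- walktrap_clusters(sub)
    filter_and_name(mem, fn, changed_proteins = net$complexes$protein_id[1:4],
                    min_size = 3)
  }
  expect_identical(run(), run())
})
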