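test_that("incidence restricts to contributing genes and significant regions", {
  idx <- index_from_sets(list(g1 = c("A", "B"), g2 = "B", g3 = "C"),
                         regions = c("A", "B", "C"))
  inc <- suppressMessages(build_incidence(idx, c("g1", "g2", "g3"),
                                          c("A", "B")))
  expect_identical(rownames(inc), c("g1", "g2"))   # g3 drops (only C)
  expect_identical(colnames(inc), c("A", "B"))
  expect_identical(unclass(inc)[, "B"], c(g1 = 1L, g2 = 1L))
  # column sums equal the observed counts of those regions for the list
  obs <- observed_counts(idx, c("g1", "g2", "g3"))
  expect_identical(colSums(inc), c(A = 1, B = 2))
  expect_equal(unname(colSums(inc)), unname(obs$counts[c("A", "B")] + 0))
  expect_error(suppressMessages(build_incidence(idx, "g3", "A")),
               "no contributing genes")
  expect_error(build_incidence(idx, "g1", character(0)), "non-empty")
})

test_that("projection weights are shared-region counts; isolates retained", {
  idx <- index_from_sets(list(g1 = c("A", "B"), g2 = c("A", "B"), g3 = "B",
                              g4 = "C"),
                         regions = c("A", "B", "C"))
  inc <- suppressMessages(build_incidence(idx, paste0("g", 1:4),
                                          c("A", "B", "C")))
  net <- suppressMessages(project_network(inc))
  e <- igraph::as_data_frame(net)
  key <- paste(pmin(e$from, e$to), pmax(e$from, e$to))
  w <- setNames(e$weight, key)
  expect_equal(w[["g1 g2"]], 2)
  expect_equal(w[["g1 g3"]], 1)
  expect_equal(w[["g2 g3"]], 1)
  expect_equal(nrow(e), 3)                      # g4 disjoint: no edges
  expect_identical(sort(igraph::V(net)$name), paste0("g", 1:4))
  expect_equal(igraph::degree(net)[["g4"]], 0)  # isolated node retained
})

test_that("projection equals the explicit pair dot-product oracle", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(3:10, 1); r <- sample(2:6, 1)
    inc <- matrix(rbinom(n * r, 1, 0.5), n, r,
                  dimnames = list(sprintf("g%02d", 1:n), paste0("R", 1:r)))
    inc[rowSums(inc) == 0, sample(r, 1)] <- 1L   # incidence invariant
    net <- suppressMessages(project_network(inc))
    want <- oracle_projection_weights(inc)
    e <- igraph::as_data_frame(net)
    expect_equal(nrow(e), nrow(want))
    if (nrow(want)) {
      got <- setNames(e$weight, paste(pmin(e$from, e$to), pmax(e$from, e$to)))
      for (k in seq_len(nrow(want)))
        expect_equal(got[[paste(want$a[k], want$b[k])]], want$w[k])
    }
  }
})

test_that("strength: worked triangle, isolates, handshake, brute-force sweep", {
  edges <- data.frame(a = c(1, 1, 2), b = c(2, 3, 3), w = c(2, 1, 1))
  g <- graph_from_edges(edges, c("g1", "g2", "g3"))
  s <- nodal_strength(g)
  expect_equal(s, c(g1 = 3, g2 = 3, g3 = 2))
  g2 <- graph_from_edges(edges, c("g1", "g2", "g3", "iso"))
  expect_equal(nodal_strength(g2)[["iso"]], 0)
  for (seed in 1:20) {
    n <- 4 + seed %% 5
    edges <- random_graph_edges(n, 0.5, 5, seed)
    g <- graph_from_edges(edges, as.character(seq_len(n)))
    s <- nodal_strength(g)
    expect_equal(unname(s), unname(oracle_strength(as.character(seq_len(n)),
                                                   edges)))
    expect_equal(sum(s), 2 * sum(edges$w))   # handshake identity
  }
})

test_that("betweenness: path centre scores 1, complete graph scores 0", {
  path <- graph_from_edges(data.frame(a = c(1, 2), b = c(2, 3), w = c(4, 4)),
                           c("g1", "g2", "g3"))
  b <- betweenness_centrality(path)
  expect_equal(b$normalized, c(g1 = 0, g2 = 1, g3 = 0))
  k4 <- graph_from_edges(data.frame(a = c(1, 1, 1, 2, 2, 3),
                                    b = c(2, 3, 4, 3, 4, 4),
                                    w = rep(2, 6)), paste0("g", 1:4))
  expect_equal(unname(betweenness_centrality(k4)$normalized), rep(0, 4))
})

test_that("betweenness equals exhaustive path enumeration in all three modes", {
  cases <- 0L
  for (seed in 1:12) {
    n <- 4 + seed %% 4                  # 4..7 nodes
    edges <- random_graph_edges(n, 0.45, 4, seed + 500)
    g <- graph_from_edges(edges, as.character(seq_len(n)))
    for (mode in c("inverse_weight", "unweighted", "weight_as_cost")) {
      got <- betweenness_centrality(g, mode)$normalized
      want <- oracle_betweenness(as.character(seq_len(n)), edges, mode)
      expect_equal(unname(got), unname(want), tolerance = 1e-9)
      cases <- cases + 1L
    }
  }
  expect_gte(cases, 36)
})

test_that("Louvain recovers planted cliques and is seed-deterministic", {
  # two 4-cliques (internal weight 3) + one weight-1 bridge
  cl4 <- function(off) {
    p <- t(combn(off + 1:4, 2)); data.frame(a = p[, 1], b = p[, 2], w = 3)
  }
  edges <- rbind(cl4(0), cl4(4), data.frame(a = 4, b = 5, w = 1))
  g <- graph_from_edges(edges, paste0("g", 1:8))
  cl <- louvain_cluster(g, seed = 1)
  expect_equal(cl$n_clusters, 2)
  expect_length(unique(cl$membership[paste0("g", 1:4)]), 1)
  expect_length(unique(cl$membership[paste0("g", 5:8)]), 1)
  expect_gt(cl$modularity, 0.3)
  # repeated runs, same seed: identical labels after canonicalization
  cl2 <- louvain_cluster(g, seed = 1)
  expect_identical(cl$membership, cl2$membership)
  # triangle collapses to one cluster
  tri <- graph_from_edges(data.frame(a = c(1, 1, 2), b = c(2, 3, 3), w = 1),
                          paste0("g", 1:3))
  expect_equal(louvain_cluster(tri, seed = 3)$n_clusters, 1)
  # edgeless network: all singletons, modularity undefined
  iso <- graph_from_edges(data.frame(a = integer(0), b = integer(0),
                                     w = numeric(0)), paste0("g", 1:3))
  cli <- louvain_cluster(iso, seed = 1)
  expect_identical(unname(cli$membership), 1:3)
  expect_true(is.na(cli$modularity))
  # labels are canonical: cluster 1 is the largest
  edges2 <- rbind(cl4(0), data.frame(a = c(5, 7), b = c(6, 8), w = c(3, 3)))
  cl3 <- louvain_cluster(graph_from_edges(edges2, paste0("g", 1:8)), seed = 2)
  sizes <- table(cl3$membership)
  expect_true(all(diff(as.integer(sizes)) <= 0))
})

test_that("cluster composition percentages are exact and sum to 100", {
  idx <- index_from_sets(list(g1 = "A", g2 = "A", g3 = c("A", "B"),
                              g4 = "B"),
                         regions = c("A", "B"))
  inc <- suppressMessages(build_incidence(idx, paste0("g", 1:4), c("A", "B")))
  cl <- structure(list(membership = c(g1 = 1L, g2 = 1L, g3 = 1L, g4 = 2L),
                       modularity = 0.1, resolution = 1, seed = 1L,
                       n_clusters = 2L), class = "ClusterAssignment")
  comp <- region_cluster_composition(inc, cl)
  expect_equal(comp["A", ], c(cluster1 = 100, cluster2 = 0))  # single-cluster region
  expect_equal(comp["B", ], c(cluster1 = 50, cluster2 = 50))
  expect_equal(unname(rowSums(comp)), c(100, 100))
  # random sweep against direct counting
  for (seed in 1:10) {
    set.seed(seed)
    n <- 12; r <- 4
    inc <- matrix(rbinom(n * r, 1, 0.5), n, r,
                  dimnames = list(sprintf("g%02d", 1:n), paste0("R", 1:r)))
    inc[rowSums(inc) == 0, 1] <- 1L
    for (j in which(colSums(inc) == 0)) inc[sample(n, 1), j] <- 1L
    memb <- setNames(sample(1:3, n, replace = TRUE), rownames(inc))
    memb[1:3] <- 1:3                     # all labels present
    clr <- structure(list(membership = memb, modularity = 0, resolution = 1,
                          seed = 1L, n_clusters = 3L),
                     class = "ClusterAssignment")
    comp <- region_cluster_composition(inc, clr)
    expect_equal(unname(rowSums(comp)), rep(100, r), tolerance = 1e-9)
    for (reg in paste0("R", 1:r)) for (c in 1:3) {
      direct <- 100 * sum(inc[, reg] == 1 & memb == c) / sum(inc[, reg])
      expect_equal(comp[reg, c], unname(direct))
    }
  }
})

test_that("network writers emit edge list, GraphML, metrics and gene lists", {
  idx <- index_from_sets(list(g1 = c("A", "B"), g2 = c("A", "B"), g3 = "B"),
                         regions = c("A", "B"))
  inc <- suppressMessages(build_incidence(idx, paste0("g", 1:3), c("A", "B")))
  net <- suppressMessages(project_network(inc))
  d <- withr::local_tempdir()
  write_edge_list(net, file.path(d, "edges.tsv"))
  e <- data.table::fread(file.path(d, "edges.tsv"))
  expect_identical(names(e), c("gene_a", "gene_b", "weight"))
  expect_equal(sum(e$weight), 4)
  write_graphml(net, file.path(d, "net.graphml"))
  back <- igraph::read_graph(file.path(d, "net.graphml"), format = "graphml")
  expect_equal(igraph::ecount(back), igraph::ecount(net))
  cl <- louvain_cluster(net, seed = 1)
  write_nodal_metrics(net, nodal_strength(net), betweenness_centrality(net),
                      cl, file.path(d, "metrics.tsv"))
  m <- data.table::fread(file.path(d, "metrics.tsv"))
  expect_identical(names(m), c("gene", "strength", "betweenness",
                               "betweenness_raw", "cluster"))
  paths <- write_cluster_gene_lists(cl, d)
  expect_true(all(file.exists(paths)))
  expect_identical(sort(unlist(lapply(paths, readLines))), paste0("g", 1:3))
})
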