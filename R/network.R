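#' Contributing-gene x significant-region incidence matrix
#'
#' Binary membership of the resolved list genes in the significant regions:
#' `cell(g, r) = 1` iff region `r` is in gene `g`'s highest-expression set.
#' Rows are restricted to genes with at least one significant region flagged
#' (the "contributing" genes), so every row and every column has at least
#' one 1 (columns because significant regions have observed count > null
#' mean >= 0).
#'
#' @param index A `HighExpressionIndex`.
#' @param resolved Resolved gene-list symbols (subset of the index genes).
#' @param significant_regions Non-empty character vector of region ids.
#' @return Integer 0/1 matrix (genes x regions) of class
#'   `GeneRegionIncidence`.
#' @export
build_incidence <- function(index, resolved, significant_regions) {
  stopifnot(inherits(index, "HighExpressionIndex"))
  resolved <- as.character(resolved)
  significant_regions <- as.character(significant_regions)
  if (!length(significant_regions))
    stop("`significant_regions` must be non-empty", call. = FALSE)
  bad <- setdiff(significant_regions, index$regions)
  if (length(bad))
    stop("unknown region(s): ", paste(head(bad, 5), collapse = ", "),
         call. = FALSE)
  sub <- index$membership[match(resolved, index$genes), significant_regions,
                          drop = FALSE]
  rownames(sub) <- resolved
  keep <- rowSums(sub) > 0
  if (!any(keep))
    stop("no contributing genes: no list gene flags a significant region",
         call. = FALSE)
  inc <- sub[keep, , drop = FALSE]
  mode(inc) <- "integer"
  message(sprintf("incidence matrix: %d genes x %d regions",
                  nrow(inc), ncol(inc)))
  structure(inc, class = c("GeneRegionIncidence", "matrix", "array"))
}

#' Project an incidence matrix to a weighted gene-gene network
#'
#' One-mode projection of the bipartite gene-region membership: genes are
#' nodes, and two genes share an edge of weight w when their
#' highest-expression sets share w significant regions (the dot product of
#' their incidence rows). Genes contributing to a single unshared region
#' remain as isolated nodes.
#'
#' @param incidence A `GeneRegionIncidence` (or any 0/1 matrix with gene
#'   rownames).
#' @return An undirected weighted [igraph::graph] with a `weight` edge
#'   attribute (integer >= 1) and one vertex per incidence row. The number
#'   of gene pairs assayed, choose(n, 2), is reported.
#' @export
project_network <- function(incidence) {
  inc <- unclass(incidence)
  if (!is.matrix(inc) || is.null(rownames(inc)))
    stop("`incidence` must be a matrix with gene rownames", call. = FALSE)
  W <- tcrossprod(inc)
  diag(W) <- 0
  message(sprintf("assaying %d gene pairs (choose(%d, 2))",
                  choose(nrow(inc), 2), nrow(inc)))
  igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                      weighted = TRUE)
}

#' Nodal strength
#'
#' Sum of incident edge weights for each node; isolated nodes score 0.
#' The handshake identity holds: total strength equals twice the total
#' edge weight.
#'
#' @param net A weighted undirected igraph graph.
#' @return Named numeric vector of strengths.
#' @export
nodal_strength <- function(net) {
  igraph::strength(net, weights = igraph::E(net)$weight)
}

#' Betweenness centrality
#'
#' Fraction of shortest paths between node pairs passing through each node,
#' normalised by `2 / ((n - 1)(n - 2))` so values lie in [0, 1]. Because
#' edge weights here are co-membership counts (similarity, not cost), the
#' default distance transform is `1 / weight`; `"unweighted"` ignores
#' weights, `"weight_as_cost"` uses the raw weight as path length (the
#' common graph-library default). Disconnected pairs contribute nothing.
#'
#' @param net A weighted undirected igraph graph.
#' @param distance_mode `"inverse_weight"` (default), `"unweighted"` or
#'   `"weight_as_cost"`.
#' @return List with `normalized` and `raw` named numeric vectors.
#' @export
betweenness_centrality <- function(net,
                                   distance_mode = c("inverse_weight",
                                                     "unweighted",
                                                     "weight_as_cost")) {
  distance_mode <- match.arg(distance_mode)
  w <- switch(distance_mode,
              inverse_weight = 1 / igraph::E(net)$weight,
              unweighted = NA,
              weight_as_cost = igraph::E(net)$weight)
  raw <- igraph::betweenness(net, weights = w, normalized = FALSE)
  n <- igraph::vcount(net)
  norm <- if (n > 2) raw * 2 / ((n - 1) * (n - 2)) else raw * 0
  list(normalized = norm, raw = raw, distance_mode = distance_mode)
}

#' Louvain community detection
#'
#' Weighted-modularity Louvain partition of the gene network. The partition
#' is deterministic for a fixed seed; labels are canonicalised by
#' descending community size (ties broken by first member) so repeated runs
#' produce identical labels, not merely identical partitions. Isolated
#' nodes become singleton communities. On an edgeless network every node is
#' a singleton and modularity is undefined (NA).
#'
#' @param net A weighted undirected igraph graph.
#' @param resolution Louvain resolution parameter (default 1.0).
#' @param seed Integer seed (default 1).
#' @return A `ClusterAssignment`: list with `membership` (named integer
#'   vector, labels contiguous from 1), `modularity`, `resolution`, `seed`
#'   and `n_clusters`.
#' @export
louvain_cluster <- function(net, resolution = 1.0, seed = 1L) {
  n <- igraph::vcount(net)
  if (n == 0) stop("network has no nodes", call. = FALSE)
  if (igraph::ecount(net) == 0) {
    memb <- setNames(seq_len(n), igraph::V(net)$name)
    return(structure(list(membership = memb, modularity = NA_real_,
                          resolution = resolution, seed = as.integer(seed),
                          n_clusters = n),
                     class = "ClusterAssignment"))
  }
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old), add = TRUE)
  set.seed(as.integer(seed))
  cl <- igraph::cluster_louvain(net, weights = igraph::E(net)$weight,
                                resolution = resolution)
  memb <- igraph::membership(cl)
  memb <- canonicalize_labels(setNames(as.integer(memb), igraph::V(net)$name))
  mod <- igraph::modularity(net, memb, weights = igraph::E(net)$weight)
  structure(list(membership = memb, modularity = mod,
                 resolution = resolution, seed = as.integer(seed),
                 n_clusters = max(memb)),
            class = "ClusterAssignment")
}

# relabel communities 1..k by decreasing size, ties by first appearance
canonicalize_labels <- function(memb) {
  tab <- table(memb)
  first <- vapply(names(tab), function(l) which(memb == as.integer(l))[1], 0L)
  ord <- order(-as.integer(tab), first)
  remap <- setNames(seq_along(ord), names(tab)[ord])
  setNames(as.integer(remap[as.character(memb)]), names(memb))
}

#' @export
print.ClusterAssignment <- function(x, ...) {
  cat(sprintf("ClusterAssignment: %d nodes in %d clusters (modularity %s, resolution %g, seed %d)\n",
              length(x$membership), x$n_clusters,
              if (is.na(x$modularity)) "NA" else sprintf("%.4f", x$modularity),
              x$resolution, x$seed))
  invisible(x)
}

#' Louvain stability over seeds
#'
#' Re-runs [louvain_cluster()] over `k` seeds and reports the number of
#' clusters and modularity per seed, for a quick check that the reported
#' partition is not a seed artefact.
#'
#' @inheritParams louvain_cluster
#' @param k Number of seeds (default 10; seeds are `seed + 0:(k-1)`).
#' @return data.table with columns seed, n_clusters, modularity.
#' @export
louvain_stability <- function(net, resolution = 1.0, seed = 1L, k = 10L) {
  res <- lapply(seq_len(k) - 1L, function(i) {
    cl <- louvain_cluster(net, resolution, as.integer(seed) + i)
    data.table(seed = cl$seed, n_clusters = cl$n_clusters,
               modularity = cl$modularity)
  })
  data.table::rbindlist(res)
}

#' Per-region cluster composition
#'
#' For each significant region, the percentage of its contributing genes in
#' each Louvain cluster. Percentages sum to 100 per region.
#'
#' @param incidence A `GeneRegionIncidence`.
#' @param clusters A `ClusterAssignment` covering all incidence genes.
#' @return Numeric matrix regions x clusters of percentages.
#' @export
region_cluster_composition <- function(incidence, clusters) {
  stopifnot(inherits(clusters, "ClusterAssignment"))
  inc <- unclass(incidence)
  genes <- rownames(inc)
  miss <- setdiff(genes, names(clusters$membership))
  if (length(miss))
    stop("cluster assignment missing gene(s): ",
         paste(head(miss, 5), collapse = ", "), call. = FALSE)
  lab <- clusters$membership[genes]
  k <- max(clusters$membership)
  comp <- sapply(seq_len(k), function(c)
    colSums(inc[lab == c, , drop = FALSE]))
  if (is.null(dim(comp))) comp <- matrix(comp, nrow = ncol(inc))
  rownames(comp) <- colnames(inc)
  colnames(comp) <- paste0("cluster", seq_len(k))
  100 * comp / rowSums(comp)
}

#' Write network outputs
#'
#' `write_incidence`: genes x regions 0/1 TSV. `write_edge_list`: columns
#' gene_a, gene_b, weight. `write_graphml`: GraphML via igraph.
#' `write_nodal_metrics`: gene, strength, betweenness (normalised), cluster.
#' `write_composition`: region x cluster percentage TSV.
#' `write_cluster_gene_lists`: one plain-text gene list per cluster
#' (suitable for external GO tools); returns the file paths.
#'
#' @param incidence A `GeneRegionIncidence`.
#' @param net An igraph network.
#' @param path Output path (directory for `write_cluster_gene_lists`).
#' @return `path` (or paths), invisibly.
#' @export
write_incidence <- function(incidence, path) {
  inc <- unclass(incidence)
  dt <- data.table(gene = rownames(inc))
  dt <- cbind(dt, as.data.table(inc))
  fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname write_incidence
#' @export
write_edge_list <- function(net, path) {
  e <- igraph::as_data_frame(net, what = "edges")
  dt <- data.table(gene_a = e$from, gene_b = e$to,
                   weight = as.integer(e$weight))
  fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname write_incidence
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(net, path, format = "graphml")
  invisible(path)
}

#' @rdname write_incidence
#' @param strength Named vector from [nodal_strength()].
#' @param btw Result of [betweenness_centrality()].
#' @param clusters A `ClusterAssignment`.
#' @export
write_nodal_metrics <- function(net, strength, btw, clusters, path) {
  genes <- igraph::V(net)$name
  dt <- data.table(gene = genes,
                   strength = as.numeric(strength[genes]),
                   betweenness = as.numeric(btw$normalized[genes]),
                   betweenness_raw = as.numeric(btw$raw[genes]),
                   cluster = as.integer(clusters$membership[genes]))
  fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname write_incidence
#' @param composition Matrix from [region_cluster_composition()].
#' @export
write_composition <- function(composition, path) {
  dt <- data.table(region = rownames(composition))
  dt <- cbind(dt, as.data.table(composition))
  fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname write_incidence
#' @param dir Output directory.
#' @export
write_cluster_gene_lists <- function(clusters, dir) {
  stopifnot(inherits(clusters, "ClusterAssignment"))
  paths <- vapply(seq_len(clusters$n_clusters), function(c) {
    p <- file.path(dir, sprintf("cluster_%d_genes.txt", c))
    writeLines(names(clusters$membership)[clusters$membership == c], p)
    p
  }, "")
  invisible(paths)
}
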