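# Small in-code fixtures shared across test files.

make_atlas <- function(values) {
  expression_atlas(values)
}

# atlas from a named list of gene -> numeric vector (regions auto-named)
atlas_from_rows <- function(rows, regions = NULL) {
  m <- do.call(rbind, rows)
  if (is.null(regions)) regions <- paste0("R", seq_len(ncol(m)))
  dimnames(m) <- list(names(rows), regions)
  expression_atlas(m)
}

# random non-negative atlas for property sweeps
random_atlas <- function(n_genes, n_regions, seed) {
  set.seed(seed)
  m <- matrix(rexp(n_genes * n_regions, rate = 0.1), n_genes, n_regions,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("R%02d", seq_len(n_regions))))
  expression_atlas(m)
}

# an index built directly from a membership list (gene -> region ids),
# bypassing the atlas, for enrichment/network unit tests
index_from_sets <- function(sets, regions) {
  genes <- names(sets)
  M <- matrix(FALSE, length(genes), length(regions),
              dimnames = list(genes, regions))
  for (g in genes) M[g, sets[[g]]] <- TRUE
  structure(list(genes = genes, regions = regions,
                 stats = data.table::data.table(gene = genes,
                                                mean = NA_real_,
                                                sd = NA_real_),
                 membership = M,
                 sets = lapply(genes, function(g) regions[M[g, ]]),
                 z_high = 1.96, sd_method = "sample"),
            class = "HighExpressionIndex")
}

# weighted undirected igraph from an edge data.frame(a, b, w) + node names
graph_from_edges <- function(edges, nodes) {
  g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = nodes)
  if (nrow(edges))
    g <- igraph::add_edges(g, rbind(edges$a, edges$b),
                           weight = edges$w)
  g
}
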