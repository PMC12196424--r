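# Independent brute-force oracles. These deliberately avoid igraph and the
# package's own code paths: strength by double loop, betweenness by
# exhaustive simple-path enumeration, projection by explicit pair dot
# products, ARI by the closed-form contingency formula.

oracle_projection_weights <- function(inc) {
  genes <- rownames(inc)
  out <- list()
  for (i in seq_len(nrow(inc))) for (j in seq_len(nrow(inc))) {
    if (i >= j) next
    w <- sum(inc[i, ] * inc[j, ])
    if (w >= 1)
      out[[length(out) + 1L]] <- data.frame(a = genes[i], b = genes[j], w = w)
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(a = character(0), b = character(0), w = numeric(0))
}

oracle_strength <- function(nodes, edges) {
  s <- setNames(numeric(length(nodes)), nodes)
  for (k in seq_len(nrow(edges))) {
    s[edges$a[k]] <- s[edges$a[k]] + edges$w[k]
    s[edges$b[k]] <- s[edges$b[k]] + edges$w[k]
  }
  s
}

# exhaustive betweenness: enumerate every simple path between each ordered
# node pair, keep those of minimal total distance (tolerance 1e-9), and
# credit each interior node with its fraction of shortest paths.
oracle_betweenness <- function(nodes, edges, mode) {
  n <- length(nodes)
  D <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  for (k in seq_len(nrow(edges))) {
    d <- switch(mode,
                inverse_weight = 1 / edges$w[k],
                unweighted = 1,
                weight_as_cost = edges$w[k])
    D[edges$a[k], edges$b[k]] <- d
    D[edges$b[k], edges$a[k]] <- d
  }
  btw <- setNames(numeric(n), nodes)
  all_paths <- function(cur, target, visited, dist) {
    last <- cur[length(cur)]
    if (last == target) return(list(list(path = cur, dist = dist)))
    res <- list()
    for (nxt in seq_len(n)) {
      if (visited[nxt] || !is.finite(D[last, nxt])) next
      visited[nxt] <- TRUE
      res <- c(res, all_paths(c(cur, nxt), target, visited,
                              dist + D[last, nxt]))
      visited[nxt] <- FALSE
    }
    res
  }
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    visited <- rep(FALSE, n); visited[s] <- TRUE
    paths <- all_paths(s, t, visited, 0)
    if (!length(paths)) next
    dists <- vapply(paths, `[[`, 0, "dist")
    best <- min(dists)
    sp <- paths[dists <= best + 1e-9]
    for (p in sp) {
      interior <- p$path[-c(1, length(p$path))]
      for (v in interior) btw[v] <- btw[v] + 1 / length(sp)
    }
  }
  if (n > 2) btw * 2 / ((n - 1) * (n - 2)) else btw * 0
}

# adjusted Rand index from the pair-counting contingency formula
adjusted_rand <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

# random weighted graph on n nodes for property sweeps
random_graph_edges <- function(n, p_edge, max_w, seed) {
  set.seed(seed)
  out <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (runif(1) < p_edge)
      out[[length(out) + 1L]] <- data.frame(a = i, b = j,
                                            w = sample.int(max_w, 1))
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(a = integer(0), b = integer(0), w = numeric(0))
}
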