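# Independent brute-force oracles and small-graph builders used across the
# suite. All oracles operate on raw edge lists or samples, never through the
# package's own code paths.

# graph from an explicit edge matrix (rows = endpoint pairs of vertex ids)
graph_of <- function(n, edges) {
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, t(edges))
  g
}

rand_graph <- function(n, p = 0.4) {
  pairs <- t(combn(n, 2))
  graph_of(n, pairs[runif(nrow(pairs)) < p, , drop = FALSE])
}

adj_matrix <- function(g) {
  as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
}

# brute-force triangle count: enumerate all node triples
oracle_triangles <- function(g) {
  n <- igraph::vcount(g)
  if (n < 3) return(0)
  A <- adj_matrix(g)
  tri <- 0
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n)
    if (A[i, j] && A[i, k] && A[j, k]) tri <- tri + 1
  tri
}

# brute-force average local clustering: per node, fraction of neighbour
# pairs connected; degree < 2 contributes 0
oracle_avg_clustering <- function(g) {
  A <- adj_matrix(g)
  n <- nrow(A)
  vals <- vapply(seq_len(n), function(v) {
    nb <- which(A[v, ] == 1)
    if (length(nb) < 2) return(0)
    pairs <- combn(nb, 2)
    mean(A[cbind(pairs[1, ], pairs[2, ])])
  }, numeric(1))
  mean(vals)
}

# Pearson correlation over the expanded ordered endpoint-degree pair list
oracle_assortativity <- function(g) {
  el <- igraph::as_edgelist(g, names = FALSE)
  d <- igraph::degree(g)
  x <- c(d[el[, 1]], d[el[, 2]])
  y <- c(d[el[, 2]], d[el[, 1]])
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

# quadratic-time two-sample KS: max |ECDF_x - ECDF_y| over pooled points
oracle_ks <- function(x, y) {
  pts <- c(x, y)
  max(vapply(pts, function(v) abs(mean(x <= v) - mean(y <= v)), numeric(1)))
}
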