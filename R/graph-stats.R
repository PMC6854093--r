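# Network statistics used as resampling features, plus an extensible registry
# addressing them by string identifier.

#' Average local clustering coefficient
#'
#' Local clustering of a node is the number of edges among its neighbours
#' divided by the maximum possible number of such edges. Nodes with fewer than
#' two neighbours have no neighbour pairs and contribute 0. The network-level
#' value is the mean over all nodes.
#'
#' @param g an undirected `igraph` graph.
#' @return a number in \[0, 1\].
#' @examples
#' avg_local_clustering(igraph::make_full_graph(4)) # 1
#' @export
avg_local_clustering <- function(g) {
  check_graph(g)
  if (igraph::vcount(g) == 0L) stop("no nodes", call. = FALSE)
  igraph::transitivity(g, type = "localaverage", isolates = "zero")
}

#' Triangle count
#'
#' Number of unordered node triples with all three connecting edges present.
#' A strictly global measure of clustering, in contrast to the average local
#' clustering coefficient.
#'
#' @param g an undirected `igraph` graph.
#' @return non-negative integer count.
#' @export
triangle_count <- function(g) {
  check_graph(g)
  if (igraph::vcount(g) == 0L) return(0)
  sum(igraph::count_triangles(g)) / 3
}

#' Degree assortativity
#'
#' Pearson correlation of the degrees of nodes joined by an edge, each edge
#' contributing both orientations of its endpoint pair. Undefined (returned as
#' `NA`) when the endpoint degrees have zero variance, e.g. on a regular
#' graph; callers must handle the `NA` rather than receive a silent 0.
#'
#' @param g an undirected `igraph` graph with at least one edge.
#' @return a number in \[-1, 1\], or `NA` when undefined.
#' @export
degree_assortativity <- function(g) {
  check_graph(g)
  if (igraph::ecount(g) == 0L) stop("assortativity requires at least one edge", call. = FALSE)
  r <- suppressWarnings(igraph::assortativity_degree(g))
  if (!is.finite(r)) NA_real_ else r
}

#' Quantiles of the degree sequence
#'
#' Empirical quantiles of the node degrees, using the linear-interpolation
#' convention (R's default, type 7). The convention is fixed and documented so
#' that features computed for classifier training and for observed subsamples
#' always agree.
#'
#' @param g an undirected `igraph` graph (non-empty).
#' @param probs probabilities in \[0, 1\].
#' @return numeric vector, one value per element of `probs`.
#' @export
degree_quantiles <- function(g, probs) {
  check_graph(g, allow_empty = FALSE)
  if (length(probs) == 0L) return(numeric(0))
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
    stop("'probs' must lie in [0, 1]", call. = FALSE)
  unname(stats::quantile(igraph::degree(g), probs = probs, type = 7))
}

#' Largest connected component
#'
#' Induced subgraph on the component with the most nodes. Ties are broken
#' deterministically in favour of the component containing the
#' lexicographically smallest node label (vertex id when unnamed).
#'
#' @param g an undirected `igraph` graph (non-empty).
#' @return an `igraph` graph.
#' @export
largest_component <- function(g) {
  check_graph(g, allow_empty = FALSE)
  comp <- igraph::components(g)
  if (comp$no == 1L) return(g)
  biggest <- which(comp$csize == max(comp$csize))
  if (length(biggest) > 1L) {
    labels <- igraph::vertex_attr(g, "name")
    if (is.null(labels)) labels <- as.character(seq_len(igraph::vcount(g)))
    # smallest label within each tied component decides
    firsts <- vapply(biggest, function(ci) min(labels[comp$membership == ci]), character(1))
    biggest <- biggest[order(firsts)][1L]
  }
  igraph::induced_subgraph(g, which(comp$membership == biggest))
}

## ---- statistic registry -----------------------------------------------------

.stat_registry <- new.env(parent = emptyenv())

#' Register a network statistic
#'
#' Adds (or replaces) a scalar network statistic under a string identifier so
#' it can be requested in resampling distributions, goodness-of-fit reports
#' and classifier features. Built-in identifiers: `avg_clustering`,
#' `triangles`, `assortativity`, `deg_q25`, `deg_q50`, `deg_q75`.
#'
#' @param name string identifier.
#' @param fn function taking an igraph graph and returning a single number
#'   (`NA` allowed to flag an undefined value).
#' @return `name`, invisibly.
#' @export
register_stat <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name), is.function(fn))
  assign(name, fn, envir = .stat_registry)
  invisible(name)
}

#' List registered statistic identifiers
#' @return character vector of identifiers.
#' @export
list_stats <- function() sort(ls(.stat_registry))

#' Default statistics used for model selection
#'
#' Average local clustering, triangle count and the three quartiles of the
#' degree distribution: features that react directly (triangles) or strongly
#' (the rest) to triadic closure.
#' @return character vector of identifiers.
#' @export
selection_stats <- function() c("avg_clustering", "triangles", "deg_q25", "deg_q50", "deg_q75")

#' Default statistics used for goodness of fit
#' @return character vector of identifiers.
#' @export
gof_stats <- function() c("avg_clustering", "triangles", "assortativity")

register_builtin_stats <- function() {
  register_stat("avg_clustering", function(g) avg_local_clustering(g))
  register_stat("triangles", function(g) triangle_count(g))
  register_stat("assortativity", function(g) {
    if (igraph::ecount(g) == 0L) return(NA_real_)
    degree_assortativity(g)
  })
  register_stat("deg_q25", function(g) degree_quantiles(g, 0.25))
  register_stat("deg_q50", function(g) degree_quantiles(g, 0.50))
  register_stat("deg_q75", function(g) degree_quantiles(g, 0.75))
}

#' Compute a vector of registered statistics
#'
#' @param g an undirected `igraph` graph.
#' @param stats character vector of registered identifiers; values are
#'   returned in this order.
#' @return named numeric vector; entries may be `NA` where a statistic is
#'   undefined on `g` (e.g. assortativity on a regular graph).
#' @export
compute_stats <- function(g, stats) {
  check_graph(g)
  unknown <- setdiff(stats, ls(.stat_registry))
  if (length(unknown))
    stop("unknown statistic identifier(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  out <- vapply(stats, function(s) as.numeric(get(s, envir = .stat_registry)(g)), numeric(1))
  names(out) <- stats
  out
}
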