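# Mechanistic network simulators and seed-network constructors. Growing
# models (ER growth, DMC, DMR) start from a seed network and add one node per
# step until the target size is reached; the triangle-closure model fills a
# fixed node set with edges one at a time.

## ---- seed networks ----------------------------------------------------------

#' Seed-network specification
#'
#' Describes the small initial graph a growing model starts from. Kinds:
#' \describe{
#'   \item{`complete`}{complete graph on `k` nodes.}
#'   \item{`two_clique_composite`}{the 50-node composite seed used in
#'     duplication-divergence fits of the yeast protein-interaction network:
#'     cliques of 7 and 10 nodes, cross-clique edges added independently with
#'     probability 0.67, plus 33 pendant nodes attached to uniformly chosen
#'     clique nodes (random; consumes the RNG at generation time).}
#'   \item{`inverse_geometric`}{`n0` nodes with i.i.d. standard-normal
#'     coordinates in `d` dimensions, connecting pairs whose Euclidean
#'     distance exceeds the threshold `R` (random).}
#'   \item{`explicit`}{a user-supplied igraph graph.}
#' }
#'
#' @param kind one of `"complete"`, `"two_clique_composite"`,
#'   `"inverse_geometric"`, `"explicit"`.
#' @param k clique size for `kind = "complete"`.
#' @param n0,d,R parameters for `kind = "inverse_geometric"`.
#' @param graph igraph graph for `kind = "explicit"`.
#' @param invert for `inverse_geometric`: if `TRUE`, connect pairs *closer*
#'   than `R` (the usual random-geometric-graph convention) instead of the
#'   farther-than-`R` rule used by default.
#' @return an object of class `seed_spec`.
#' @export
seed_spec <- function(kind = c("complete", "two_clique_composite", "inverse_geometric", "explicit"),
                      k = NULL, n0 = NULL, d = NULL, R = NULL, graph = NULL,
                      invert = FALSE) {
  kind <- match.arg(kind)
  out <- list(kind = kind, k = k, n0 = n0, d = d, R = R, graph = graph, invert = isTRUE(invert))
  switch(kind,
    complete = { out$k <- check_count(k, "k", 1L) },
    inverse_geometric = {
      out$n0 <- check_count(n0, "n0", 1L)
      out$d <- check_count(d, "d", 1L)
      if (!is.numeric(R) || length(R) != 1L || R < 0) stop("'R' must be a single number >= 0", call. = FALSE)
    },
    explicit = { check_graph(graph, allow_empty = FALSE) },
    two_clique_composite = NULL)
  structure(out, class = "seed_spec")
}

#' Complete seed graph
#' @param k number of nodes (>= 1).
#' @return the complete graph on `k` nodes as an igraph graph.
#' @export
seed_complete <- function(k) {
  k <- check_count(k, "k", 1L)
  igraph::make_full_graph(k)
}

#' Two-clique composite seed network (50 nodes)
#'
#' Cliques of 7 and 10 nodes, each of the 70 possible cross-clique edges
#' added independently with probability 0.67, and 33 further nodes attached
#' by a single edge to a uniformly chosen node of the 17 clique nodes.
#' Expected edge count 66 + 70*0.67 + 33 = 145.9.
#'
#' @return an igraph graph with exactly 50 nodes.
#' @export
seed_two_clique_composite <- function() {
  c1 <- 1:7; c2 <- 8:17
  within1 <- t(utils::combn(c1, 2))
  within2 <- t(utils::combn(c2, 2))
  cross <- as.matrix(expand.grid(c1, c2))
  cross <- cross[stats::runif(nrow(cross)) < 0.67, , drop = FALSE]
  pend <- cbind(18:50, sample(17L, 33L, replace = TRUE))
  edges <- rbind(within1, within2, unname(cross), pend)
  igraph::graph_from_edgelist(edges, directed = FALSE)
}

#' Inverse geometric seed network
#'
#' Each node receives i.i.d. N(0, 1) coordinates in `d` dimensions; a pair is
#' connected when the Euclidean distance between their coordinates exceeds
#' `R`. This is the inverse of the usual random-geometric-graph rule; set
#' `invert = TRUE` for the conventional closer-than-`R` rule.
#'
#' @param n0 number of nodes.
#' @param d coordinate dimension.
#' @param R distance threshold.
#' @param invert connect pairs with distance below `R` instead.
#' @return an igraph graph with `n0` nodes.
#' @export
seed_inverse_geometric <- function(n0, d = 2, R = 1.5, invert = FALSE) {
  n0 <- check_count(n0, "n0", 1L)
  d <- check_count(d, "d", 1L)
  x <- matrix(stats::rnorm(n0 * d), nrow = n0)
  dm <- as.matrix(stats::dist(x))
  adj <- if (invert) dm < R else dm > R
  adj[lower.tri(adj, diag = TRUE)] <- FALSE
  edges <- which(adj, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n0, directed = FALSE)
  if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
  g
}

# Materialize a seed_spec into a graph (consumes RNG for random kinds).
seed_graph <- function(ss) {
  stopifnot(inherits(ss, "seed_spec"))
  switch(ss$kind,
    complete = seed_complete(ss$k),
    two_clique_composite = seed_two_clique_composite(),
    inverse_geometric = seed_inverse_geometric(ss$n0, ss$d, ss$R, ss$invert),
    explicit = ss$graph)
}

## ---- model specifications ---------------------------------------------------

#' Candidate generative model specification
#'
#' Families:
#' \describe{
#'   \item{`er_growth`}{Erdos-Renyi as a growth process: starting from the
#'     seed, each new node links to every existing node independently with
#'     probability `p`.}
#'   \item{`dmc`}{duplication-mutation-complementation, parameters `q_mod`
#'     (per-neighbour probability of removing one of the two parallel-role
#'     edges) and `q_con` (probability of linking the duplicate to its
#'     parent).}
#'   \item{`dmr`}{duplication-mutation-random: each copied edge removed
#'     independently with probability `q_del`; each node present at step
#'     start gains an edge to the new node with probability `q_new / n(t)`.
#'     With `remove_singletons = TRUE`, a new node left with no edges is
#'     discarded immediately and growth continues until `n` nodes survive.}
#'   \item{`triangle_closure`}{G(n, m) variant: edges added one at a time to
#'     a uniformly proposed unconnected pair, accepted with probability
#'     [triangle_closure_probability()] based on the number of triangles the
#'     edge would close.}
#' }
#'
#' @param family model family tag.
#' @param n target node count.
#' @param m target edge count (triangle_closure only).
#' @param p attachment probability (er_growth).
#' @param q_mod,q_con DMC parameters.
#' @param q_del,q_new,remove_singletons DMR parameters.
#' @param p0,p1,p_delta triangle-closure acceptance parameters.
#' @param seed a [seed_spec()] (growth families; ignored by
#'   triangle_closure). Defaults to a single-node seed.
#' @param label optional display label used in reports.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(family = c("er_growth", "dmc", "dmr", "triangle_closure"),
                       n, m = NULL, p = NULL, q_mod = NULL, q_con = NULL,
                       q_del = NULL, q_new = NULL, remove_singletons = FALSE,
                       p0 = NULL, p1 = NULL, p_delta = NULL,
                       seed = seed_spec("complete", k = 1), label = NULL) {
  family <- match.arg(family)
  n <- check_count(n, "n", 1L)
  params <- switch(family,
    er_growth = list(p = check_prob(p, "p")),
    dmc = list(q_mod = check_prob(q_mod, "q_mod"), q_con = check_prob(q_con, "q_con")),
    dmr = list(q_del = check_prob(q_del, "q_del"),
               q_new = { if (!is.numeric(q_new) || q_new < 0) stop("'q_new' must be >= 0", call. = FALSE); as.numeric(q_new) },
               remove_singletons = isTRUE(remove_singletons)),
    triangle_closure = {
      if (n < 2L) stop("triangle_closure requires n >= 2", call. = FALSE)
      m <- check_count(m, "m", 0L)
      if (m > n * (n - 1) / 2) stop("m exceeds the maximum C(n, 2) edge count", call. = FALSE)
      if (!is.numeric(p_delta) || p_delta < 0) stop("'p_delta' must be >= 0", call. = FALSE)
      list(p0 = check_prob(p0, "p0"), p1 = check_prob(p1, "p1"), p_delta = as.numeric(p_delta))
    })
  if (family != "triangle_closure") stopifnot(inherits(seed, "seed_spec"))
  if (is.null(label)) label <- family
  structure(list(family = family, n = n, m = if (family == "triangle_closure") m else NULL,
                 params = params, seed = seed, label = label),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  ps <- paste(names(x$params), unlist(lapply(x$params, format)), sep = "=", collapse = ", ")
  cat(sprintf("<model_spec> %s: family=%s, n=%d%s, %s\n", x$label, x$family, x$n,
              if (!is.null(x$m)) sprintf(", m=%d", x$m) else "", ps))
  if (x$family != "triangle_closure")
    cat(sprintf("  seed: %s\n", x$seed$kind))
  invisible(x)
}

#' Triangle-closure acceptance probability
#'
#' Base probability `p0`; if the proposed edge closes at least one triangle
#' the probability increases by `p1`, and by a further `p_delta` for each
#' additional triangle closed, clamped to \[0, 1\].
#'
#' @param t number of triangles the edge would close (non-negative integer).
#' @param p0,p1,p_delta parameters.
#' @return acceptance probability in \[0, 1\].
#' @export
triangle_closure_probability <- function(t, p0, p1, p_delta) {
  stopifnot(all(t >= 0))
  p <- p0 + ifelse(t >= 1, p1 + (t - 1) * p_delta, 0)
  pmin(pmax(p, 0), 1)
}

## ---- generation -------------------------------------------------------------

#' Draw one network from a model specification
#'
#' All randomness comes from R's RNG: a fixed `set.seed()` before the call
#' yields a bit-identical graph.
#'
#' @param spec a [model_spec()].
#' @return an igraph graph with exactly `spec$n` nodes (and `spec$m` edges
#'   for the triangle-closure family).
#' @export
generate_network <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  if (spec$family == "triangle_closure") {
    edges <- cpp_triangle_closure(spec$n, spec$m, spec$params$p0, spec$params$p1,
                                  spec$params$p_delta, max_reject = 1000 * max(spec$m, 1))
    g <- igraph::make_empty_graph(spec$n, directed = FALSE)
    if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
    return(g)
  }
  g0 <- seed_graph(spec$seed)
  n0 <- igraph::vcount(g0)
  if (spec$n < n0)
    stop(sprintf("target n = %d is smaller than the seed network (%d nodes)", spec$n, n0), call. = FALSE)
  se <- igraph::as_edgelist(g0, names = FALSE)
  storage.mode(se) <- "integer"
  edges <- switch(spec$family,
    er_growth = er_growth_edges(se, n0, spec$n, spec$params$p),
    dmc = cpp_dmc(se, n0, spec$n, spec$params$q_mod, spec$params$q_con),
    dmr = cpp_dmr(se, n0, spec$n, spec$params$q_del, spec$params$q_new,
                  spec$params$remove_singletons, max_steps = 100 * spec$n))
  g <- igraph::make_empty_graph(spec$n, directed = FALSE)
  if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
  g
}

# ER growth: node j joins with an independent Bernoulli(p) edge to each of
# the j-1 nodes already present. Pairs inside the seed keep the seed's edges.
er_growth_edges <- function(seed_edges, n0, n, p) {
  new_edges <- vector("list", max(n - n0, 0L))
  for (j in seq_len(n - n0)) {
    v <- n0 + j
    hit <- which(stats::runif(v - 1L) < p)
    if (length(hit)) new_edges[[j]] <- cbind(hit, v)
  }
  out <- rbind(seed_edges, do.call(rbind, new_edges))
  if (is.null(out)) out <- matrix(integer(0), ncol = 2)
  storage.mode(out) <- "integer"
  out
}
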