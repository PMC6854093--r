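# Plain-text edge-list I/O. Dialect: one edge per line, two whitespace- or
# tab-separated node labels; `#` starts a comment; a `%ISOLATED` line starts
# a sidecar section listing degree-0 nodes one per line (plain edge lists
# cannot represent them, and DMR with singleton retention produces them).

#' Read an undirected graph from a plain-text edge list
#'
#' Node labels are kept as opaque strings and never reindexed. Self-loops and
#' duplicate edges are dropped with a message reporting the counts.
#'
#' @param path file path.
#' @return an igraph graph with a `name` vertex attribute.
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  iso_at <- which(trimws(lines) == "%ISOLATED")
  iso <- character(0)
  if (length(iso_at)) {
    iso <- trimws(lines[(iso_at[1] + 1):length(lines)])
    iso <- iso[nzchar(iso)]
    lines <- lines[seq_len(iso_at[1] - 1)]
  }
  keep <- nzchar(trimws(lines))
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  bad <- which(lengths(fields) < 2L)
  if (length(bad))
    stop(sprintf("malformed edge on line %d: need two node labels", which(keep)[bad[1]]), call. = FALSE)
  ends <- do.call(rbind, lapply(fields, function(f) f[1:2]))
  if (is.null(ends)) ends <- matrix(character(0), ncol = 2)
  loops <- ends[, 1] == ends[, 2]
  if (any(loops)) message(sprintf("dropped %d self-loop(s)", sum(loops)))
  ends <- ends[!loops, , drop = FALSE]
  key <- paste(pmin(ends[, 1], ends[, 2]), pmax(ends[, 1], ends[, 2]))
  dup <- duplicated(key)
  if (any(dup)) message(sprintf("dropped %d duplicate edge(s)", sum(dup)))
  ends <- ends[!dup, , drop = FALSE]
  nodes <- sort(unique(c(as.vector(ends), iso)))
  g <- igraph::make_empty_graph(length(nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = nodes)
  if (nrow(ends)) g <- igraph::add_edges(g, t(matrix(match(ends, nodes), ncol = 2)))
  g
}

#' Write an undirected graph as a plain-text edge list
#'
#' Endpoints within each line, and the lines themselves, are sorted
#' lexicographically so output is canonical; isolated nodes are listed under
#' a `%ISOLATED` sidecar section. `read_edge_list()` restores the graph
#' exactly.
#'
#' @param g an igraph graph.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path) {
  check_graph(g)
  labels <- igraph::vertex_attr(g, "name")
  if (is.null(labels)) labels <- as.character(seq_len(igraph::vcount(g)))
  el <- igraph::as_edgelist(g, names = FALSE)
  lines <- character(0)
  if (nrow(el)) {
    a <- labels[el[, 1]]; b <- labels[el[, 2]]
    lines <- sort(paste(pmin(a, b), pmax(a, b)))
  }
  iso <- labels[igraph::degree(g) == 0L]
  if (length(iso)) lines <- c(lines, "%ISOLATED", sort(iso))
  writeLines(lines, path)
  invisible(path)
}

#' Read model specifications from a YAML config file
#'
#' The file holds a list of model mappings, each with `family`, `n`,
#' optional `m` and `label`, a `params` mapping with the family's
#' parameters, and a `seed` mapping (`kind` plus `k`, or `n0`/`d`/`R`, or
#' `path` to an edge list for `kind: explicit`).
#'
#' @param path YAML file path.
#' @return list of [model_spec()] objects.
#' @export
read_model_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$models)) raw <- raw$models
  lapply(raw, function(mc) {
    # YAML 1.1 parses a bare `n` key as boolean FALSE; restore it
    names(mc)[names(mc) == "FALSE"] <- "n"
    sd <- mc$seed
    seed <- if (is.null(sd)) seed_spec("complete", k = 1)
      else switch(sd$kind,
        complete = seed_spec("complete", k = sd$k),
        two_clique_composite = seed_spec("two_clique_composite"),
        inverse_geometric = seed_spec("inverse_geometric", n0 = sd$n0, d = sd$d, R = sd$R,
                                      invert = isTRUE(sd$invert)),
        explicit = seed_spec("explicit", graph = read_edge_list(sd$path)),
        stop("unknown seed kind: ", sd$kind))
    do.call(model_spec, c(list(family = mc$family, n = mc$n, m = mc$m,
                               seed = seed, label = mc$label), mc$params))
  })
}
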