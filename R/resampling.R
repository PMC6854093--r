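# Node-wise bootstrap subsampling and construction of the three resampling
# distributions:
#   F_o  - statistics over induced subgraphs of B_o node subsamples of the
#          observed network;
#   F_c  - one subsample from each of B_M independent draws from a candidate
#          model (sized like the observed network);
#   F_1  - B_M subsamples of a single draw from the candidate model.
# Observed- and model-side subsamples always use the same node fraction so
# both carry the same amount of "missingness".

#' Subsampling scheme
#'
#' @param fraction fraction of nodes per subsample, in (0, 1]. Subsample size
#'   is `max(1, floor(fraction * n))`. Fractions below ~0.3 are recommended
#'   for observed networks so subsamples retain variability.
#' @param B_obs number of subsamples taken from an observed network.
#' @param B_model number of model draws (independent mode) or subsamples of a
#'   single draw (single-draw mode).
#' @param seed integer RNG seed governing every random choice made under the
#'   scheme; per-row substreams make results order-independent.
#' @return an object of class `subsample_scheme`.
#' @export
subsample_scheme <- function(fraction = 0.3, B_obs = 100, B_model = 100, seed = 1) {
  if (!is.numeric(fraction) || length(fraction) != 1L || fraction <= 0 || fraction > 1)
    stop("'fraction' must lie in (0, 1]", call. = FALSE)
  structure(list(fraction = as.numeric(fraction),
                 B_obs = check_count(B_obs, "B_obs"),
                 B_model = check_count(B_model, "B_model"),
                 seed = check_count(seed, "seed", 0L)),
            class = "subsample_scheme")
}

#' @export
print.subsample_scheme <- function(x, ...) {
  cat(sprintf("<subsample_scheme> fraction=%g, B_obs=%d, B_model=%d, seed=%d\n",
              x$fraction, x$B_obs, x$B_model, x$seed))
  invisible(x)
}

#' Uniform node subsample with induced subgraph
#'
#' Samples `max(1, floor(fraction * n))` nodes uniformly without replacement
#' and returns the induced subgraph (the sampled nodes and every edge of `g`
#' with both endpoints sampled).
#'
#' @param g an undirected `igraph` graph (non-empty).
#' @param fraction fraction of nodes, in (0, 1].
#' @return an igraph graph.
#' @export
node_subsample <- function(g, fraction) {
  check_graph(g, allow_empty = FALSE)
  if (fraction <= 0 || fraction > 1) stop("'fraction' must lie in (0, 1]", call. = FALSE)
  n <- igraph::vcount(g)
  k <- max(1L, as.integer(floor(fraction * n)))
  if (k == n) return(g)
  igraph::induced_subgraph(g, sample.int(n, k))
}

# shared row builder: returns matrix of stats over subsample rows; each row
# generated under its own substream seed.
resample_rows <- function(draw_graph, stats, B, row_seeds) {
  vals <- matrix(NA_real_, nrow = B, ncol = length(stats),
                 dimnames = list(NULL, stats))
  for (b in seq_len(B)) {
    set.seed(row_seeds[b])
    vals[b, ] <- compute_stats(draw_graph(b), stats)
  }
  vals
}

new_resampling_distribution <- function(values, stats, provenance, scheme, source) {
  keep <- stats::complete.cases(values)
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(sprintf("dropped %d subsample row(s) with undefined statistics", n_dropped))
    values <- values[keep, , drop = FALSE]
  }
  structure(list(values = values, stats = stats, provenance = provenance,
                 scheme = scheme, source = source, n_dropped = n_dropped),
            class = "resampling_distribution")
}

#' Resampling distribution from an observed network (F_o)
#'
#' Takes `scheme$B_obs` node subsamples of `g`, computes the requested
#' statistics on each induced subgraph, and stacks them into a B x |S|
#' matrix. Rows on which any statistic is undefined (e.g. assortativity on a
#' regular subsample) are dropped, with the count reported.
#'
#' @param g observed network (igraph, non-empty).
#' @param stats character vector of registered statistic identifiers.
#' @param scheme a [subsample_scheme()].
#' @return an object of class `resampling_distribution` with provenance
#'   `"observed"`.
#' @export
resample_observed <- function(g, stats, scheme) {
  check_graph(g, allow_empty = FALSE)
  stopifnot(inherits(scheme, "subsample_scheme"))
  row_seeds <- substream_seeds(scheme$seed, scheme$B_obs, offset = 0L)
  vals <- resample_rows(function(b) node_subsample(g, scheme$fraction),
                        stats, scheme$B_obs, row_seeds)
  new_resampling_distribution(vals, stats, "observed", scheme,
                              sprintf("observed network (n=%d, m=%d)",
                                      igraph::vcount(g), igraph::ecount(g)))
}

#' Resampling distribution from a candidate model (F_c or F_1)
#'
#' In `independent` mode (F_c), draws `scheme$B_model` networks from the
#' model and takes exactly one subsample from each: the stable default for
#' comparison with an observed network. In `single_draw` mode (F_1), draws a
#' single network and takes `scheme$B_model` subsamples of it, mirroring how
#' the observed side is treated.
#'
#' @param spec a [model_spec()]. When comparing against an observed network,
#'   `spec$n` should equal that network's node count; a warning is emitted via
#'   the calling procedure if not.
#' @param stats character vector of registered statistic identifiers.
#' @param scheme a [subsample_scheme()]; the same fraction as the observed
#'   side must be used for comparability.
#' @param mode `"independent"` (F_c) or `"single_draw"` (F_1).
#' @return an object of class `resampling_distribution`.
#' @export
resample_model <- function(spec, stats, scheme, mode = c("independent", "single_draw")) {
  stopifnot(inherits(spec, "model_spec"), inherits(scheme, "subsample_scheme"))
  mode <- match.arg(mode)
  B <- scheme$B_model
  if (mode == "independent") {
    row_seeds <- substream_seeds(scheme$seed, B, offset = 1L)
    vals <- resample_rows(function(b) {
      g <- tryCatch(generate_network(spec),
                    error = function(e) stop(sprintf("model draw %d: %s", b, conditionMessage(e)), call. = FALSE))
      node_subsample(g, scheme$fraction)
    }, stats, B, row_seeds)
    prov <- "model_independent"
  } else {
    g1 <- with_seed(substream_seeds(scheme$seed, 1L, offset = 2L), generate_network(spec))
    row_seeds <- substream_seeds(scheme$seed, B, offset = 3L)
    vals <- resample_rows(function(b) node_subsample(g1, scheme$fraction),
                          stats, B, row_seeds)
    prov <- "model_single_draw"
  }
  new_resampling_distribution(vals, stats, prov, scheme,
                              sprintf("model %s (n=%d)", spec$label, spec$n))
}

#' @export
print.resampling_distribution <- function(x, ...) {
  cat(sprintf("<resampling_distribution> %s: %d rows x %d statistics (%s)\n",
              x$provenance, nrow(x$values), length(x$stats), x$source))
  if (x$n_dropped > 0) cat(sprintf("  %d row(s) dropped (undefined statistics)\n", x$n_dropped))
  print(utils::head(x$values, 4))
  if (nrow(x$values) > 4) cat(sprintf("  ... %d more rows\n", nrow(x$values) - 4))
  invisible(x)
}

#' @export
summary.resampling_distribution <- function(object, ...) {
  apply(object$values, 2, stats::quantile, probs = c(0.025, 0.25, 0.5, 0.75, 0.975))
}

#' @export
as.data.frame.resampling_distribution <- function(x, ...) as.data.frame(x$values)

#' Histogram panel of a resampling distribution
#' @param x a `resampling_distribution`.
#' @param ... passed to [graphics::hist()].
#' @export
plot.resampling_distribution <- function(x, ...) {
  k <- length(x$stats)
  op <- graphics::par(mfrow = c(1, k))
  on.exit(graphics::par(op))
  for (s in x$stats)
    graphics::hist(x$values[, s], main = s, xlab = s,
                   col = "grey80", border = "white", ...)
  invisible(x)
}

#' Write / read a resampling distribution as annotated TSV
#'
#' The header comment block carries provenance, scheme and seed so a file is
#' self-describing; [read_resampling_tsv()] restores the object.
#'
#' @param x a `resampling_distribution`.
#' @param path file path.
#' @return `path` invisibly (write); a `resampling_distribution` (read).
#' @export
write_resampling_tsv <- function(x, path) {
  stopifnot(inherits(x, "resampling_distribution"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# provenance: %s", x$provenance),
    sprintf("# source: %s", x$source),
    sprintf("# fraction: %g", x$scheme$fraction),
    sprintf("# B_obs: %d", x$scheme$B_obs),
    sprintf("# B_model: %d", x$scheme$B_model),
    sprintf("# seed: %d", x$scheme$seed),
    sprintf("# n_dropped: %d", x$n_dropped)), con)
  utils::write.table(x$values, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_resampling_tsv
#' @export
read_resampling_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  field <- function(key) sub(sprintf("^# %s: ", key), "", grep(sprintf("^# %s:", key), hdr, value = TRUE))
  vals <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE, sep = "\t",
                            check.names = FALSE)
  vals <- as.matrix(vals)
  scheme <- subsample_scheme(as.numeric(field("fraction")), as.integer(field("B_obs")),
                             as.integer(field("B_model")), as.integer(field("seed")))
  structure(list(values = vals, stats = colnames(vals), provenance = field("provenance"),
                 scheme = scheme, source = field("source"),
                 n_dropped = as.integer(field("n_dropped"))),
            class = "resampling_distribution")
}

#' Diagnostic: expected KS distance between F_1 and F_c over fractions
#'
#' For each candidate subsample fraction, builds `replicates` pairs of F_1
#' (subsamples of one model draw) and F_c (one subsample of each of many
#' independent draws) and reports the mean per-statistic KS distance. Small
#' values indicate that subsamples from a single network behave like
#' subsamples from independent draws, i.e. the fraction retains model
#' features without letting single-draw instability dominate; used to choose
#' a working fraction.
#'
#' @param spec a [model_spec()].
#' @param stats statistic identifiers.
#' @param fractions fractions in (0, 1) to evaluate.
#' @param scheme a [subsample_scheme()]; `B_model` governs both sides
#'   (a warning is given when `B_model < 30`, since KS on tiny samples is
#'   uninformative).
#' @param replicates number of (F_1, F_c) pairs averaged per fraction.
#' @return data frame with columns `fraction`, one column per statistic
#'   (mean KS), and `replicates`.
#' @export
fraction_diagnostic <- function(spec, stats, fractions, scheme, replicates = 3) {
  stopifnot(all(fractions > 0), all(fractions < 1))
  if (scheme$B_model < 30)
    warning("B_model < 30: KS distances on so few rows are unstable")
  rows <- lapply(fractions, function(f) {
    ks_acc <- matrix(NA_real_, nrow = replicates, ncol = length(stats))
    for (r in seq_len(replicates)) {
      sch <- subsample_scheme(f, scheme$B_obs, scheme$B_model,
                              seed = substream_seeds(scheme$seed, replicates, offset = 400L)[r])
      f1 <- resample_model(spec, stats, sch, mode = "single_draw")
      sch2 <- subsample_scheme(f, scheme$B_obs, scheme$B_model,
                               seed = substream_seeds(scheme$seed, replicates, offset = 500L)[r])
      fc <- resample_model(spec, stats, sch2, mode = "independent")
      ks_acc[r, ] <- vapply(seq_along(stats), function(j)
        ks_statistic(f1$values[, j], fc$values[, j]), numeric(1))
    }
    c(fraction = f, colMeans(ks_acc))
  })
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c("fraction", stats)
  out$replicates <- replicates
  out
}
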