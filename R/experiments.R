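# Reproduction harnesses for the two simulation studies, at configurable
# scale. These double as the package's synthetic-data machinery for tests:
# every study is fully determined by (config, seed).

#' Configuration for the model-selection study
#'
#' Two triangle-closure models on `n` nodes and `m` edges are compared:
#' model 1 has `p_delta = 0` (plain G(n, m) beyond the first-triangle bonus),
#' model 2 has the cell's `p_delta`. A classifier is trained on one
#' subsample from each of `train_draws` draws per model and evaluated on
#' `test_networks` fresh draws per model, each selected by majority over
#' `subsamples` observed-side subsamples.
#'
#' Full-scale counts are `train_draws = 10000`, `test_networks = 1000`; the
#' `scale` factor multiplies both (default 0.1, i.e. 1000 training draws and
#' 100 test networks per model) so every grid cell runs at desk scale.
#'
#' @param p_delta grid of `p_delta` values for model 2.
#' @param m grid of edge counts.
#' @param cells optional data frame with columns `p_delta` and `m` selecting
#'   specific cells; default is the full `p_delta` x `m` grid.
#' @param n nodes per network.
#' @param p0,p1 shared triangle-closure parameters.
#' @param train_draws,test_networks full-scale per-model counts.
#' @param subsamples observed-side subsamples per test network.
#' @param fraction subsample fraction (0.8: subsamples of 80 of 100 nodes).
#' @param learner a [learner_spec()].
#' @param seed RNG seed.
#' @param scale scale factor in (0, 1] applied to `train_draws` and
#'   `test_networks`.
#' @return an object of class `selection_study_config`.
#' @export
selection_study_config <- function(p_delta = c(0.05, 0.03, 0.01, 0.005),
                                   m = c(100, 500, 1000, 2000),
                                   cells = NULL,
                                   n = 100, p0 = 0.3, p1 = 0.1,
                                   train_draws = 10000, test_networks = 1000,
                                   subsamples = 100, fraction = 0.8,
                                   learner = learner_spec(), seed = 1,
                                   scale = 0.1) {
  if (scale <= 0 || scale > 1) stop("'scale' must lie in (0, 1]", call. = FALSE)
  if (is.null(cells)) cells <- expand.grid(p_delta = p_delta, m = m)
  stopifnot(all(c("p_delta", "m") %in% names(cells)))
  cfg <- list(cells = cells, n = n, p0 = p0, p1 = p1,
              train_draws = max(1L, as.integer(round(train_draws * scale))),
              test_networks = max(1L, as.integer(round(test_networks * scale))),
              subsamples = check_count(subsamples, "subsamples"),
              fraction = fraction, learner = learner,
              seed = check_count(seed, "seed", 0L), scale = scale)
  structure(cfg, class = "selection_study_config")
}

# Stat rows for `n_networks` draws of `spec`, `B` subsamples each.
# Returns list(values = matrix, network = row index of the source network).
study_test_rows <- function(spec, n_networks, B, fraction, stats, seed) {
  net_seeds <- substream_seeds(seed, n_networks, offset = 810L)
  obs_seeds <- substream_seeds(seed, n_networks, offset = 820L)
  vals <- vector("list", n_networks)
  for (t in seq_len(n_networks)) {
    g <- with_seed(net_seeds[t], generate_network(spec))
    f <- resample_observed(g, stats, subsample_scheme(fraction, B, 1, seed = obs_seeds[t]))
    vals[[t]] <- f$values
  }
  list(values = do.call(rbind, vals),
       network = rep(seq_len(n_networks), vapply(vals, nrow, integer(1))))
}

#' Run the model-selection study
#'
#' For each grid cell, trains a selector on model 1 (`p_delta = 0`) versus
#' model 2 (the cell's `p_delta`), classifies the subsamples of every test
#' network, and records the proportion of test networks whose generating
#' model was selected, together with each test network's confidence in the
#' correct model (the proportion of its subsamples assigned to it).
#'
#' @param cfg a [selection_study_config()].
#' @return an object of class `selection_study`: `$cells` has one row per
#'   grid cell (`prop_correct`, `mean_confidence`, `median_confidence`);
#'   `$records` one row per test network.
#' @export
run_selection_study <- function(cfg) {
  stopifnot(inherits(cfg, "selection_study_config"))
  stats <- selection_stats()
  n_cells <- nrow(cfg$cells)
  cell_seeds <- substream_seeds(cfg$seed, n_cells, offset = 700L)
  cell_rows <- vector("list", n_cells)
  records <- vector("list", n_cells)
  for (ci in seq_len(n_cells)) {
    pd <- cfg$cells$p_delta[ci]
    m <- cfg$cells$m[ci]
    spec1 <- model_spec("triangle_closure", n = cfg$n, m = m,
                        p0 = cfg$p0, p1 = cfg$p1, p_delta = 0, label = "model_1")
    spec2 <- model_spec("triangle_closure", n = cfg$n, m = m,
                        p0 = cfg$p0, p1 = cfg$p1, p_delta = pd, label = "model_2")
    scheme <- subsample_scheme(cfg$fraction, B_obs = cfg$subsamples,
                               B_model = cfg$train_draws, seed = cell_seeds[ci])
    selector <- fit_selector(list(spec1, spec2), stats, scheme, cfg$learner)
    test_seeds <- substream_seeds(cell_seeds[ci], 2L, offset = 900L)
    recs <- vector("list", 2L)
    for (true_model in 1:2) {
      rows <- study_test_rows(if (true_model == 1) spec1 else spec2,
                              cfg$test_networks, cfg$subsamples, cfg$fraction,
                              stats, test_seeds[true_model])
      scores <- predict(selector, rows$values)
      assigned <- assign_rows(scores)
      conf_correct <- vapply(seq_len(cfg$test_networks), function(t) {
        a <- assigned[rows$network == t]
        mean(a == true_model)
      }, numeric(1))
      selected <- ifelse(conf_correct > 0.5, true_model,
                         ifelse(conf_correct < 0.5, 3L - true_model,
                                1L)) # exact tie -> lowest index
      recs[[true_model]] <- data.frame(
        p_delta = pd, m = m, true_model = true_model,
        network = seq_len(cfg$test_networks),
        confidence_correct = conf_correct,
        correct = selected == true_model)
    }
    cell_rec <- do.call(rbind, recs)
    records[[ci]] <- cell_rec
    cell_rows[[ci]] <- data.frame(
      p_delta = pd, m = m,
      prop_correct = mean(cell_rec$correct),
      mean_confidence = mean(cell_rec$confidence_correct),
      median_confidence = stats::median(cell_rec$confidence_correct))
  }
  structure(list(cells = do.call(rbind, cell_rows),
                 records = do.call(rbind, records), config = cfg),
            class = "selection_study")
}

#' @export
print.selection_study <- function(x, ...) {
  cat(sprintf("Model-selection study: %d cell(s), %d training draws and %d test networks per model\n",
              nrow(x$cells), x$config$train_draws, x$config$test_networks))
  print(transform(x$cells, prop_correct = round(prop_correct, 3),
                  mean_confidence = round(mean_confidence, 3),
                  median_confidence = round(median_confidence, 3)))
  invisible(x)
}

#' Histograms of confidence in the correct model, one panel per cell
#' @param x a `selection_study`.
#' @param ... unused.
#' @export
plot.selection_study <- function(x, ...) {
  cells <- x$cells
  op <- graphics::par(mfrow = grDevices::n2mfrow(nrow(cells)))
  on.exit(graphics::par(op))
  for (ci in seq_len(nrow(cells))) {
    rec <- x$records[x$records$p_delta == cells$p_delta[ci] & x$records$m == cells$m[ci], ]
    graphics::hist(rec$confidence_correct, breaks = seq(0, 1, by = 0.05),
                   main = sprintf("p_delta=%g, m=%d", cells$p_delta[ci], cells$m[ci]),
                   xlab = "confidence in correct model", col = "grey80", border = "white")
    graphics::abline(v = stats::median(rec$confidence_correct), col = "red", lwd = 2)
  }
  invisible(x)
}

#' Write the per-cell study table as TSV
#' @param x a `selection_study` or `stability_study`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_study_tsv <- function(x, path) {
  tab <- if (inherits(x, "selection_study")) x$cells else x$summary
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---- stability of the degree distribution under the seed network -----------

#' Configuration for the seed-stability study
#'
#' Generates `replicates` networks per (model, n, seed size) cell and
#' summarises replicate-to-replicate variability of the degree distribution.
#' The variability summary is the mean pairwise total-variation distance
#' between the replicate empirical degree distributions, a scalar proxy for
#' the visual band-width assessment of stacked degree-distribution plots.
#'
#' @param models named list of parameter lists. Each element needs a
#'   `family` (`"er_growth"`, `"dmc"` or `"dmr"`) plus that family's
#'   parameters. Defaults: ER growth with `p = 0.1` and DMC with
#'   `q_mod = 0.2`, `q_con = 0.1`.
#' @param n vector of target node counts (full study: 1000, 3000, 5000,
#'   7000, 10000).
#' @param seed_sizes complete-graph seed sizes (full study: 5, 8, 10, 20,
#'   50, 100).
#' @param replicates networks per cell (full study: 50).
#' @param seed RNG seed.
#' @return an object of class `stability_study_config`.
#' @export
stability_study_config <- function(models = list(er_growth = list(family = "er_growth", p = 0.1),
                                                 dmc = list(family = "dmc", q_mod = 0.2, q_con = 0.1)),
                                   n = 1000, seed_sizes = c(5, 8, 10, 20, 50, 100),
                                   replicates = 50, seed = 1) {
  structure(list(models = models, n = n, seed_sizes = seed_sizes,
                 replicates = check_count(replicates, "replicates", 2L),
                 seed = check_count(seed, "seed", 0L)),
            class = "stability_study_config")
}

# empirical degree distribution as a probability vector over 0..max degree
degree_distribution_vec <- function(g) {
  d <- igraph::degree(g)
  tabulate(d + 1L, nbins = max(d) + 1L) / length(d)
}

# total-variation distance between two discrete distributions (padded)
tv_distance <- function(p, q) {
  len <- max(length(p), length(q))
  p <- c(p, rep(0, len - length(p)))
  q <- c(q, rep(0, len - length(q)))
  0.5 * sum(abs(p - q))
}

mean_pairwise_tv <- function(dists) {
  k <- length(dists)
  tot <- 0
  for (i in seq_len(k - 1)) for (j in (i + 1):k) tot <- tot + tv_distance(dists[[i]], dists[[j]])
  tot / (k * (k - 1) / 2)
}

#' Run the seed-stability study
#'
#' @param cfg a [stability_study_config()].
#' @return an object of class `stability_study`: `$summary` has one row per
#'   (model, n, seed size) with `mean_pairwise_tv`; `$degree_dists` holds the
#'   replicate degree distributions.
#' @export
run_stability_study <- function(cfg) {
  stopifnot(inherits(cfg, "stability_study_config"))
  grid <- expand.grid(model = names(cfg$models), n = cfg$n, seed_size = cfg$seed_sizes,
                      stringsAsFactors = FALSE)
  cell_seeds <- substream_seeds(cfg$seed, nrow(grid), offset = 750L)
  dists <- vector("list", nrow(grid))
  tv <- numeric(nrow(grid))
  for (ci in seq_len(nrow(grid))) {
    pars <- cfg$models[[grid$model[ci]]]
    spec <- do.call(model_spec, c(pars, list(n = grid$n[ci],
                                             seed = seed_spec("complete", k = grid$seed_size[ci]),
                                             label = grid$model[ci])))
    rep_seeds <- substream_seeds(cell_seeds[ci], cfg$replicates)
    dd <- lapply(seq_len(cfg$replicates), function(r)
      with_seed(rep_seeds[r], degree_distribution_vec(generate_network(spec))))
    dists[[ci]] <- dd
    tv[ci] <- mean_pairwise_tv(dd)
  }
  grid$mean_pairwise_tv <- tv
  structure(list(summary = grid, degree_dists = dists, config = cfg),
            class = "stability_study")
}

#' @export
print.stability_study <- function(x, ...) {
  cat(sprintf("Seed-stability study: %d replicates per cell\n", x$config$replicates))
  print(transform(x$summary, mean_pairwise_tv = signif(mean_pairwise_tv, 4)))
  invisible(x)
}
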