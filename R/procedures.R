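# The three statistical procedures built on the subsampling bootstrap:
# goodness of fit, classifier-based model selection with majority-rule
# confidence, and pairwise comparison of multiple observed networks.

## ---- goodness of fit --------------------------------------------------------

#' Assess goodness of fit of candidate models to an observed network
#'
#' Builds the observed resampling distribution F_o once, one independent-mode
#' model distribution F_c per candidate, and reports per-statistic distances
#' (one [distance_profile()] per measure and candidate) together with the
#' candidate ordering each statistic induces (ascending distance = better
#' fit). Orderings are reported per statistic and never collapsed into a
#' single ranking unless a joint measure is supplied explicitly, since
#' different statistics can legitimately disagree about which model fits
#' best.
#'
#' @param g_obs observed network (igraph).
#' @param candidates list of [model_spec()] objects. Each candidate's `n`
#'   should equal the observed node count; a warning is given otherwise.
#' @param stats statistic identifiers (default [gof_stats()]).
#' @param scheme a [subsample_scheme()].
#' @param measures subset of `c("ks", "kl")`.
#' @return an object of class `netboot_gof`.
#' @export
assess_gof <- function(g_obs, candidates, stats = gof_stats(),
                       scheme = subsample_scheme(), measures = "ks") {
  check_graph(g_obs, allow_empty = FALSE)
  stopifnot(length(candidates) >= 1, all(vapply(candidates, inherits, logical(1), "model_spec")))
  measures <- match.arg(measures, c("ks", "kl"), several.ok = TRUE)
  n_obs <- igraph::vcount(g_obs)
  for (cand in candidates)
    if (cand$n != n_obs)
      warning(sprintf("candidate '%s' has n = %d but the observed network has %d nodes; draws should match the observed size",
                      cand$label, cand$n, n_obs))
  labels <- make.unique(vapply(candidates, `[[`, character(1), "label"))
  f_o <- resample_observed(g_obs, stats, scheme)
  f_c <- vector("list", length(candidates))
  for (i in seq_along(candidates)) {
    sch_i <- subsample_scheme(scheme$fraction, scheme$B_obs, scheme$B_model,
                              seed = substream_seeds(scheme$seed, length(candidates), offset = 100L)[i])
    f_c[[i]] <- resample_model(candidates[[i]], stats, sch_i, mode = "independent")
    if (nrow(f_c[[i]]$values) == 0L)
      warning(sprintf("candidate '%s': all subsample rows degenerate (undefined statistics)", labels[i]))
  }
  names(f_c) <- labels
  profiles <- lapply(measures, function(ms)
    lapply(f_c, function(fc) distance_profile(f_o, fc, measure = ms)))
  names(profiles) <- measures
  dist_tables <- lapply(profiles, function(pl)
    do.call(rbind, lapply(pl, `[[`, "distances")))
  orderings <- lapply(dist_tables, function(tab)
    apply(tab, 2, function(col) labels[order(col)], simplify = FALSE))
  structure(list(f_obs = f_o, f_model = f_c, candidates = candidates,
                 labels = labels, stats = stats, measures = measures,
                 profiles = profiles, distances = dist_tables,
                 orderings = orderings, scheme = scheme),
            class = "netboot_gof")
}

#' @export
print.netboot_gof <- function(x, ...) {
  cat(sprintf("Bootstrap-subsampling goodness of fit: %d candidate(s), %d statistics\n",
              length(x$candidates), length(x$stats)))
  cat(sprintf("  fraction %g, B_obs %d, B_model %d\n\n",
              x$scheme$fraction, x$scheme$B_obs, x$scheme$B_model))
  for (ms in x$measures) {
    cat(sprintf("%s distances (rows = candidates; smaller = better fit):\n", toupper(ms)))
    print(round(x$distances[[ms]], 4))
    cat("\n")
  }
  invisible(x)
}

#' @export
summary.netboot_gof <- function(object, ...) {
  qs <- lapply(c(list(observed = object$f_obs), object$f_model), summary)
  list(distances = object$distances, orderings = object$orderings, quantiles = qs)
}

#' Overlaid resampling-distribution histograms per statistic
#' @param x a `netboot_gof` object.
#' @param ... unused.
#' @export
plot.netboot_gof <- function(x, ...) {
  k <- length(x$stats)
  op <- graphics::par(mfrow = c(1, k))
  on.exit(graphics::par(op))
  cols <- grDevices::hcl.colors(length(x$f_model) + 1, "Dark 3", alpha = 0.5)
  for (j in seq_len(k)) {
    all_vals <- c(x$f_obs$values[, j], unlist(lapply(x$f_model, function(f) f$values[, j])))
    br <- pretty(all_vals, n = 30)
    graphics::hist(x$f_obs$values[, j], breaks = br, col = cols[1], border = NA,
                   main = x$stats[j], xlab = x$stats[j], freq = FALSE)
    for (i in seq_along(x$f_model))
      graphics::hist(x$f_model[[i]]$values[, j], breaks = br, col = cols[i + 1],
                     border = NA, add = TRUE, freq = FALSE)
    graphics::legend("topright", legend = c("observed", x$labels), fill = cols, bty = "n", cex = 0.8)
  }
  invisible(x)
}

#' Serialize a goodness-of-fit report
#'
#' `as_json` carries full provenance (model specs, scheme, seed) for re-runs;
#' `write_gof_tsv` writes the distance table.
#'
#' @param x a `netboot_gof` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gof_json <- function(x, path) {
  stopifnot(inherits(x, "netboot_gof"))
  spec_info <- lapply(x$candidates, function(cd)
    list(family = cd$family, n = cd$n, m = cd$m, params = cd$params,
         seed_kind = if (is.null(cd$seed)) NULL else cd$seed$kind, label = cd$label))
  obj <- list(
    procedure = "goodness_of_fit",
    scheme = unclass(x$scheme),
    candidates = spec_info,
    stats = x$stats,
    distances = lapply(x$distances, function(tab) {
      by_cand <- lapply(seq_len(nrow(tab)), function(i)
        as.list(stats::setNames(tab[i, ], colnames(tab))))
      names(by_cand) <- rownames(tab)
      by_cand
    }),
    orderings = x$orderings,
    n_dropped = c(observed = x$f_obs$n_dropped,
                  vapply(x$f_model, `[[`, integer(1), "n_dropped")))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_gof_json
#' @export
write_gof_tsv <- function(x, path) {
  stopifnot(inherits(x, "netboot_gof"))
  tabs <- lapply(names(x$distances), function(ms) {
    tab <- as.data.frame(x$distances[[ms]])
    data.frame(measure = ms, candidate = rownames(tab), tab, row.names = NULL, check.names = FALSE)
  })
  utils::write.table(do.call(rbind, tabs), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---- model selection --------------------------------------------------------

#' Train a model-selection classifier
#'
#' Builds the training table by drawing `scheme$B_model` networks from each
#' candidate in independent mode (one subsample per draw) and labelling each
#' statistic row with its model index, then trains the requested learner on
#' it. The fitted selector classifies statistic rows from observed-network
#' subsamples; see [select_model()].
#'
#' @param candidates list of two or more [model_spec()] objects.
#' @param stats statistic identifiers (default [selection_stats()]).
#' @param scheme a [subsample_scheme()]; its fraction must match the one used
#'   later on observed networks.
#' @param learner a [learner_spec()].
#' @return an object of class `netboot_selector`.
#' @export
fit_selector <- function(candidates, stats = selection_stats(),
                         scheme = subsample_scheme(), learner = learner_spec()) {
  stopifnot(length(candidates) >= 2, all(vapply(candidates, inherits, logical(1), "model_spec")),
            inherits(learner, "learner_spec"))
  labels <- make.unique(vapply(candidates, `[[`, character(1), "label"))
  parts <- vector("list", length(candidates))
  for (i in seq_along(candidates)) {
    sch_i <- subsample_scheme(scheme$fraction, scheme$B_obs, scheme$B_model,
                              seed = substream_seeds(scheme$seed, length(candidates), offset = 200L)[i])
    parts[[i]] <- resample_model(candidates[[i]], stats, sch_i, mode = "independent")
  }
  X <- do.call(rbind, lapply(parts, `[[`, "values"))
  y <- factor(rep(seq_along(candidates), vapply(parts, function(p) nrow(p$values), integer(1))),
              levels = seq_along(candidates))
  if (nlevels(droplevels(y)) < 2)
    stop("training table is degenerate: fewer than two model classes survived", call. = FALSE)
  train_seed <- substream_seeds(scheme$seed, 1L, offset = 300L)
  fit <- with_seed(train_seed, train_learner(as.data.frame(X), y, learner, seed = train_seed))
  structure(list(fit = fit, learner = learner, stats = stats, scheme = scheme,
                 candidates = candidates, labels = labels,
                 n_train = as.integer(table(y))),
            class = "netboot_selector")
}

#' @export
print.netboot_selector <- function(x, ...) {
  cat(sprintf("<netboot_selector> %s on %d models (%s), %d features, %s training rows\n",
              x$learner$kind, length(x$candidates), paste(x$labels, collapse = " vs "),
              length(x$stats), paste(x$n_train, collapse = "+")))
  if (!is.null(x$fit$weights))
    cat("  ensemble weights:", paste(sprintf("%s=%.2f", names(x$fit$weights), x$fit$weights), collapse = ", "), "\n")
  invisible(x)
}

#' Per-row class scores from a fitted selector
#' @param object a `netboot_selector`.
#' @param newdata matrix or data frame of statistic rows (columns in the
#'   selector's statistic order).
#' @param ... unused.
#' @return matrix of class scores, one column per candidate model.
#' @export
predict.netboot_selector <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  stopifnot(identical(colnames(newdata), object$stats))
  sc <- object$fit$predict(newdata)
  colnames(sc) <- object$labels
  sc
}

# scores matrix -> per-row assigned model index. Binary case follows the
# score-threshold rule (score for model 2 above 0.5 picks model 2); exact 0.5
# and multi-class ties go to the lowest model index.
assign_rows <- function(scores) {
  apply(scores, 1, which.max)
}

#' Select a model for an observed network
#'
#' Takes `scheme$B_obs` subsamples of the observed network, classifies each
#' statistic row with the trained selector, and selects the model assigned
#' most frequently (majority for two candidates, plurality otherwise). The
#' proportion of subsamples assigned to the winning model is reported as the
#' confidence in the selection; per-model proportions quantify the evidence
#' for every candidate. Plurality ties are flagged and broken in favour of
#' the lowest model index.
#'
#' @param selector a fitted [fit_selector()] object.
#' @param g_obs observed network (igraph).
#' @param scheme optional [subsample_scheme()] override for the observed
#'   side; its fraction must equal the selector's training fraction.
#' @return an object of class `netboot_selection`.
#' @export
select_model <- function(selector, g_obs, scheme = NULL) {
  stopifnot(inherits(selector, "netboot_selector"))
  check_graph(g_obs, allow_empty = FALSE)
  if (is.null(scheme)) scheme <- selector$scheme
  if (!isTRUE(all.equal(scheme$fraction, selector$scheme$fraction)))
    stop("observed-side fraction must match the selector's training fraction (same missingness on both sides)",
         call. = FALSE)
  f_o <- resample_observed(g_obs, selector$stats, scheme)
  scores <- predict(selector, f_o$values)
  assigned <- assign_rows(scores)
  props <- tabulate(assigned, nbins = length(selector$labels)) / length(assigned)
  names(props) <- selector$labels
  winners <- which(props == max(props))
  structure(list(selected = winners[1L], selected_label = selector$labels[winners[1L]],
                 confidence = max(props), proportions = props, assignments = assigned,
                 scores = scores, tie = length(winners) > 1L,
                 B_used = length(assigned), n_dropped = f_o$n_dropped,
                 learner = selector$learner$kind, scheme = scheme),
            class = "netboot_selection")
}

#' @export
print.netboot_selection <- function(x, ...) {
  cat(sprintf("Selected model: %s (confidence %.2f over %d subsamples%s)\n",
              x$selected_label, x$confidence, x$B_used,
              if (x$tie) "; PLURALITY TIE, lowest index chosen" else ""))
  cat("Assignment proportions:\n")
  print(round(x$proportions, 3))
  invisible(x)
}

#' Serialize a selection result with full provenance
#' @param x a `netboot_selection`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_selection_json <- function(x, path) {
  stopifnot(inherits(x, "netboot_selection"))
  obj <- list(procedure = "model_selection",
              selected = x$selected, selected_label = x$selected_label,
              confidence = x$confidence, proportions = as.list(x$proportions),
              tie = x$tie, assignments = x$assignments,
              B_used = x$B_used, n_dropped = x$n_dropped,
              learner = x$learner, scheme = unclass(x$scheme))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

## ---- comparison of multiple networks ---------------------------------------

#' Pairwise comparison of multiple observed networks
#'
#' Builds an observed-side resampling distribution for each network and
#' computes the chosen distance between every pair, per statistic. With the
#' KS measure the result is symmetric.
#'
#' @param graphs list of two or more igraph graphs (named list names are used
#'   as labels).
#' @param stats statistic identifiers.
#' @param scheme a [subsample_scheme()].
#' @param measure `"ks"` or `"kl"`.
#' @return an object of class `netboot_comparison`: `per_stat` is a
#'   k x k x |S| array, `aggregate` the mean over statistics.
#' @export
compare_networks <- function(graphs, stats = gof_stats(),
                             scheme = subsample_scheme(), measure = "ks") {
  stopifnot(is.list(graphs), length(graphs) >= 2)
  k <- length(graphs)
  labels <- names(graphs)
  if (is.null(labels)) labels <- paste0("network_", seq_len(k))
  fs <- vector("list", k)
  for (i in seq_len(k)) {
    sch_i <- subsample_scheme(scheme$fraction, scheme$B_obs, scheme$B_model,
                              seed = substream_seeds(scheme$seed, k, offset = 600L)[i])
    fs[[i]] <- resample_observed(graphs[[i]], stats, sch_i)
  }
  per_stat <- array(0, dim = c(k, k, length(stats)), dimnames = list(labels, labels, stats))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    per_stat[i, j, ] <- distance_profile(fs[[i]], fs[[j]], measure = measure)$distances
  }
  structure(list(per_stat = per_stat, aggregate = apply(per_stat, c(1, 2), mean),
                 labels = labels, stats = stats, measure = measure, scheme = scheme),
            class = "netboot_comparison")
}

#' @export
print.netboot_comparison <- function(x, ...) {
  cat(sprintf("Pairwise %s distances between %d networks (mean over %d statistics):\n",
              toupper(x$measure), length(x$labels), length(x$stats)))
  print(round(x$aggregate, 4))
  invisible(x)
}

#' Write the pairwise comparison matrix as TSV
#' @param x a `netboot_comparison`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_comparison_tsv <- function(x, path) {
  stopifnot(inherits(x, "netboot_comparison"))
  rows <- do.call(rbind, lapply(seq_along(x$stats), function(s)
    data.frame(statistic = x$stats[s], from = rep(x$labels, each = length(x$labels)),
               to = rep(x$labels, length(x$labels)),
               distance = as.vector(t(x$per_stat[, , s])))))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
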