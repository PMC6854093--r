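# Distances between resampling distributions. The KS statistic is used
# descriptively (no p-values): it is well defined for the discrete,
# heavily-tied samples that graph statistics produce.

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' Supremum over the pooled sample points of the absolute difference between
#' the two empirical CDFs. Valid for discrete data with ties; symmetric; in
#' \[0, 1\].
#'
#' @param x,y non-empty numeric samples.
#' @return the KS distance in \[0, 1\].
#' @export
ks_statistic <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("samples must be non-empty", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("samples must not contain NA", call. = FALSE)
  pts <- sort(unique(c(x, y)))
  cx <- findInterval(pts, sort(x)) / length(x)
  cy <- findInterval(pts, sort(y)) / length(y)
  max(abs(cx - cy))
}

#' Kullback-Leibler divergence between two samples
#'
#' Histogram estimator on bins shared by both samples: bin width from the
#' Freedman-Diaconis rule on the pooled sample (with fallbacks for degenerate
#' spreads), additive smoothing of `1/(2 * (length(x) + length(y)))` added to
#' every bin mass before normalisation so the divergence is always finite.
#' Asymmetric: `kl_divergence(x, y)` estimates KL(P_x || P_y).
#'
#' @param x,y non-empty numeric samples.
#' @param breaks shared bin boundaries; by default derived from the pooled
#'   sample by the Freedman-Diaconis rule.
#' @param smooth additive mass per bin; set to 0 for the raw plug-in
#'   estimator (may be infinite when supports differ).
#' @return divergence in nats, >= 0.
#' @export
kl_divergence <- function(x, y, breaks = NULL, smooth = NULL) {
  if (length(x) == 0L || length(y) == 0L) stop("samples must be non-empty", call. = FALSE)
  pooled <- c(x, y)
  if (is.null(breaks)) {
    rng <- range(pooled)
    if (diff(rng) == 0) {
      breaks <- c(rng[1] - 0.5, rng[1] + 0.5)
    } else {
      w <- 2 * stats::IQR(pooled) / length(pooled)^(1 / 3) # Freedman-Diaconis
      if (w <= 0) w <- diff(rng) / ceiling(sqrt(length(pooled)))
      nb <- max(1L, ceiling(diff(rng) / w))
      breaks <- seq(rng[1], rng[2], length.out = nb + 1L)
    }
  }
  if (is.null(smooth)) smooth <- 1 / (2 * length(pooled))
  px <- graphics::hist(x, breaks = breaks, plot = FALSE)$counts + smooth
  py <- graphics::hist(y, breaks = breaks, plot = FALSE)$counts + smooth
  px <- px / sum(px)
  py <- py / sum(py)
  keep <- px > 0
  sum(px[keep] * log(px[keep] / py[keep]))
}

#' Per-statistic distance profile between two resampling distributions
#'
#' Computes the chosen distance between corresponding statistic columns of
#' two resampling distributions (e.g. F_o vs F_c for one candidate model).
#' Multidimensional distances over the joint distribution of all statistics
#' are an extension point: supply any function of two numeric matrices via
#' `joint_fn` to obtain an additional scalar, but no specific generalization
#' is shipped.
#'
#' @param a,b `resampling_distribution` objects with identical statistics in
#'   identical order.
#' @param measure `"ks"` or `"kl"`.
#' @param joint_fn optional `function(matrix_a, matrix_b) -> scalar` applied
#'   to the full value matrices for a joint, all-statistics distance.
#' @return an object of class `distance_profile`: per-statistic distances,
#'   measure tag, sample sizes, and optional `joint` value.
#' @export
distance_profile <- function(a, b, measure = c("ks", "kl"), joint_fn = NULL) {
  stopifnot(inherits(a, "resampling_distribution"), inherits(b, "resampling_distribution"))
  measure <- match.arg(measure)
  if (!identical(a$stats, b$stats))
    stop("statistic mismatch between distributions: [",
         paste(a$stats, collapse = ", "), "] vs [",
         paste(b$stats, collapse = ", "), "]", call. = FALSE)
  fn <- if (measure == "ks") ks_statistic else kl_divergence
  d <- vapply(seq_along(a$stats), function(j) fn(a$values[, j], b$values[, j]), numeric(1))
  names(d) <- a$stats
  structure(list(distances = d, measure = measure,
                 n_a = nrow(a$values), n_b = nrow(b$values),
                 joint = if (!is.null(joint_fn)) joint_fn(a$values, b$values) else NULL),
            class = "distance_profile")
}

#' @export
print.distance_profile <- function(x, ...) {
  cat(sprintf("<distance_profile> measure=%s (n = %d vs %d)\n", x$measure, x$n_a, x$n_b))
  print(round(x$distances, 4))
  if (!is.null(x$joint)) cat(sprintf("  joint: %.4f\n", x$joint))
  invisible(x)
}
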