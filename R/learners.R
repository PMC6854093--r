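# Pluggable classifiers for model selection. Every learner exposes per-row
# class scores (a B x n_classes probability matrix) so majority-rule
# confidence can be computed uniformly, and so the stacked ensemble can
# combine base learners by cross-validated weighting.

#' Learner specification for model selection
#'
#' Available kinds:
#' \describe{
#'   \item{`svm`}{support vector machine, nu-classification with `nu = 0.5`
#'     and a radial kernel (via \pkg{e1071}); class probabilities by Platt
#'     scaling.}
#'   \item{`rf`}{random forest with `ntree = 1000` and minimum terminal node
#'     size 1 (via \pkg{randomForest}); vote fractions as scores.}
#'   \item{`knn`}{k-nearest neighbours with `k = 10` on standardized
#'     features; neighbour vote fractions as scores.}
#'   \item{`super`}{stacked ensemble of the three above: 5-fold
#'     cross-validated class scores are combined with non-negative weights
#'     summing to one, chosen on a simplex grid to minimise the Brier score.}
#' }
#'
#' @param kind learner kind.
#' @param nu,ntree,nodesize,k,folds,weight_step hyperparameters (defaults as
#'   above).
#' @return an object of class `learner_spec`.
#' @export
learner_spec <- function(kind = c("super", "svm", "rf", "knn"),
                         nu = 0.5, ntree = 1000, nodesize = 1, k = 10,
                         folds = 5, weight_step = 0.02) {
  kind <- match.arg(kind)
  structure(list(kind = kind, nu = nu, ntree = ntree, nodesize = nodesize,
                 k = k, folds = folds, weight_step = weight_step),
            class = "learner_spec")
}

# ---- base learners ----------------------------------------------------------
# Each trainer returns list(predict = function(newX) -> prob matrix with one
# column per level of y, in levels(y) order).

train_svm <- function(X, y, ls) {
  fit <- e1071::svm(x = X, y = y, type = "nu-classification", nu = ls$nu,
                    kernel = "radial", probability = TRUE)
  lev <- levels(y)
  list(predict = function(newX) {
    pr <- attr(stats::predict(fit, newX, probability = TRUE), "probabilities")
    pr[, lev, drop = FALSE]
  })
}

train_rf <- function(X, y, ls) {
  fit <- randomForest::randomForest(x = X, y = y, ntree = ls$ntree, nodesize = ls$nodesize)
  lev <- levels(y)
  list(predict = function(newX) {
    pr <- stats::predict(fit, newX, type = "prob")
    pr[, lev, drop = FALSE]
  })
}

# kNN with full per-class vote fractions (class::knn only reports the winning
# class proportion). Features standardized by training means/sds; test rows
# processed in chunks to bound the distance-matrix size.
train_knn <- function(X, y, ls) {
  X <- as.matrix(X)
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[sd == 0] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sd, "/")
  lev <- levels(y)
  k <- min(ls$k, nrow(Z))
  list(predict = function(newX) {
    newZ <- sweep(sweep(as.matrix(newX), 2, mu), 2, sd, "/")
    out <- matrix(0, nrow(newZ), length(lev), dimnames = list(NULL, lev))
    chunk <- 2000L
    sq_tr <- rowSums(Z^2)
    for (start in seq(1L, nrow(newZ), by = chunk)) {
      idx <- start:min(start + chunk - 1L, nrow(newZ))
      D <- outer(rowSums(newZ[idx, , drop = FALSE]^2), sq_tr, "+") -
        2 * newZ[idx, , drop = FALSE] %*% t(Z)
      for (r in seq_along(idx)) {
        nb <- y[order(D[r, ])[seq_len(k)]]
        out[idx[r], ] <- tabulate(nb, nbins = length(lev)) / k
      }
    }
    out
  })
}

train_base <- function(kind, X, y, ls) {
  switch(kind, svm = train_svm(X, y, ls), rf = train_rf(X, y, ls), knn = train_knn(X, y, ls),
         stop("unknown base learner: ", kind))
}

# ---- stacked ensemble -------------------------------------------------------

# All weight vectors on the simplex with given step (3 learners -> ~1300
# candidates at step 0.02).
simplex_grid <- function(k, step) {
  stopifnot(k >= 1)
  ticks <- round(1 / step)
  combs <- utils::combn(ticks + k - 1, k - 1)
  grid <- apply(combs, 2, function(cut) diff(c(0, cut, ticks + k - 1)) - 1) / ticks
  t(grid)
}

train_super <- function(X, y, ls, seed) {
  base_kinds <- c("svm", "rf", "knn")
  n <- nrow(X)
  lev <- levels(y)
  folds <- ls$folds
  fold_id <- with_seed(seed, sample(rep(seq_len(folds), length.out = n)))
  # cross-validated scores, one slab per base learner
  cv <- lapply(base_kinds, function(kind) {
    scores <- matrix(NA_real_, n, length(lev))
    for (f in seq_len(folds)) {
      hold <- fold_id == f
      fit <- train_base(kind, X[!hold, , drop = FALSE], droplevels(y[!hold]), ls)
      pr <- fit$predict(X[hold, , drop = FALSE])
      scores[hold, match(colnames(pr), lev)] <- pr
    }
    scores
  })
  # Brier-optimal weights on the simplex grid
  Yind <- outer(as.integer(y), seq_along(lev), function(a, b) as.numeric(a == b))
  W <- simplex_grid(length(base_kinds), ls$weight_step)
  risk <- apply(W, 1, function(w) {
    mix <- Reduce(`+`, Map(function(s, wi) wi * s, cv, as.list(w)))
    mean((mix - Yind)^2)
  })
  w_best <- W[which.min(risk), ]
  names(w_best) <- base_kinds
  fits <- lapply(base_kinds, function(kind) train_base(kind, X, y, ls))
  list(predict = function(newX) {
    preds <- lapply(fits, function(f) f$predict(newX))
    Reduce(`+`, Map(function(p, wi) wi * p, preds, as.list(w_best)))
  }, weights = w_best, cv_risk = min(risk))
}

train_learner <- function(X, y, ls, seed) {
  if (ls$kind == "super") train_super(X, y, ls, seed) else train_base(ls$kind, X, y, ls)
}
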