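# Internal helpers shared across modules.

#' Derive per-row RNG seeds from a base seed
#'
#' Draws `n` independent 31-bit seeds from a stream initialised at
#' `seed + offset`. Each resampling row (and each model draw) is generated
#' under its own seed so that results are identical whether rows are computed
#' serially or in any other order.
#'
#' @param seed integer base seed.
#' @param n number of substream seeds.
#' @param offset phase offset so different phases of one analysis (observed
#'   rows, model draws, classifier folds, ...) use disjoint streams.
#' @return integer vector of length `n`, values in `[1, 2^31 - 2]`.
#' @export
substream_seeds <- function(seed, n, offset = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed((as.integer(seed) + as.integer(offset)) %% 2147483647L)
  sample.int(2147483646L, n, replace = FALSE)
}

#' Evaluate an expression under a fixed seed
#'
#' Runs `expr` with the RNG seeded at `seed`, restoring the caller's RNG
#' state afterwards, so one randomized step can be pinned down without
#' disturbing the surrounding stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Validate a single probability parameter.
check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a single probability in [0, 1]", name), call. = FALSE)
  as.numeric(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    stop(sprintf("'%s' must be a single integer >= %d", name, min), call. = FALSE)
  as.integer(x)
}

# Coerce/validate an igraph object for use in netboot: undirected and simple.
check_graph <- function(g, allow_empty = TRUE) {
  if (!igraph::is_igraph(g)) stop("expected an igraph object", call. = FALSE)
  if (igraph::is_directed(g)) stop("graph must be undirected", call. = FALSE)
  if (!allow_empty && igraph::vcount(g) == 0L) stop("no nodes", call. = FALSE)
  g
}
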