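#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed`, so seeded package internals never
#' disturb the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Min-max feature scaling fitted on a training set
#'
#' Maps each feature column to \[0, 1\] using the training-set range;
#' constant columns map to 0. The fitted ranges travel with the trained
#' model so streaming classification applies the identical transform.
#'
#' @param fm a `feature_matrix`.
#' @return A list with `min` and `range` vectors (class `feature_scaling`).
#' @export
fit_feature_scaling <- function(fm) {
  X <- feature_values(fm)
  mins <- apply(X, 2, min)
  rng <- apply(X, 2, max) - mins
  rng[rng == 0] <- 1
  structure(list(min = mins, range = rng), class = "feature_scaling")
}

#' @rdname fit_feature_scaling
#' @param scaling a `feature_scaling`.
#' @export
apply_feature_scaling <- function(fm, scaling) {
  X <- feature_values(fm)
  X <- sweep(sweep(X, 2, scaling$min), 2, scaling$range, "/")
  make_feature_matrix(fm$t_ms, X, fm$label)
}
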