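# Random-forest classifier used by every cascade stage: bootstrap-bagged
# CART trees with a fresh random feature subset at every split
# (mtry = floor(sqrt(p)) by default), grown to purity. P(positive) is the
# forest-averaged leaf class proportion. Implemented in C++ with an own
# RNG so identical seeds give identical forests on any platform.

#' Train a random forest
#'
#' @param X Numeric feature matrix (rows = examples).
#' @param y Factor or 0/1 vector; the second level / value 1 is the
#'   positive class.
#' @param n_trees Number of trees (default 100).
#' @param mtry Features tried per split (default `floor(sqrt(ncol(X)))`).
#' @param seed Integer seed; forests are reproducible per seed.
#' @param min_node Minimum node size to attempt a split.
#' @param max_depth Maximum tree depth.
#' @return An `rf_model`.
#' @export
rf_train <- function(X, y, n_trees = 100L, mtry = NULL, seed = 1L,
                     min_node = 2L, max_depth = 30L) {
  X <- as.matrix(X)
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.integer(y)
  stopifnot(nrow(X) == length(y), all(y %in% c(0L, 1L)))
  if (length(unique(y)) < 2L)
    stop("training data contains a single class", call. = FALSE)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  forest <- cpp_rf_train(X, y, as.integer(n_trees), as.integer(mtry),
                         as.integer(min_node), as.integer(max_depth),
                         as.integer(seed))
  structure(list(forest = forest, n_trees = as.integer(n_trees),
                 mtry = as.integer(mtry), seed = as.integer(seed),
                 feature_names = colnames(X)),
            class = "rf_model")
}

#' Predict P(positive) with a random forest
#'
#' @param model An [rf_train] result.
#' @param X Feature matrix with the training columns (reordered by name
#'   when named).
#' @return Numeric vector of probabilities in [0, 1].
#' @export
rf_predict <- function(model, X) {
  X <- as.matrix(X)
  if (!is.null(colnames(X)) && !is.null(model$feature_names)) {
    if (!all(model$feature_names %in% colnames(X)))
      stop("feature columns do not match the trained model", call. = FALSE)
    X <- X[, model$feature_names, drop = FALSE]
  }
  cpp_rf_predict(model$forest, X)
}
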