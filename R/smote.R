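#' SMOTE oversampling of a minority class
#'
#' Creates `target - nrow(minority)` synthetic minority examples. Each
#' synthetic point is `x + u * (x_nn - x)` where `x` is an existing
#' minority point (taken round-robin), `x_nn` one of its `k` nearest
#' minority neighbours (Euclidean; optionally in min-max-scaled space so
#' that large-magnitude features do not dominate) and `u` uniform on
#' [0, 1] — so every synthetic coordinate lies between the two parents'.
#' Deterministic for a fixed seed.
#'
#' @param minority Numeric matrix, one minority example per row (a list
#'   of `feature_vector`s is also accepted).
#' @param k Number of nearest neighbours (default 5; clamped to
#'   `nrow - 1`).
#' @param target Desired minority size after augmentation.
#' @param seed Integer seed.
#' @param scale_bounds Optional list with `min`/`max` per column used for
#'   neighbour search (interpolation happens in the original space, which
#'   is equivalent for any affine scaling).
#' @return Matrix of the synthetic rows only (0 rows when
#'   `target == nrow(minority)`).
#' @export
smote_oversample <- function(minority, k = 5L, target, seed,
                             scale_bounds = NULL) {
  if (is.list(minority) && !is.matrix(minority))
    minority <- do.call(rbind, minority)
  n <- nrow(minority)
  if (n < 2L) stop("need at least 2 minority examples for SMOTE",
                   call. = FALSE)
  stopifnot(k >= 1L, target >= n)
  n_syn <- target - n
  out <- matrix(numeric(), 0L, ncol(minority),
                dimnames = list(NULL, colnames(minority)))
  if (n_syn == 0L) return(out)
  k <- min(k, n - 1L)

  Xs <- minority
  if (!is.null(scale_bounds)) {
    rng <- pmax(scale_bounds$max - scale_bounds$min, 1e-12)
    Xs <- sweep(sweep(minority, 2L, scale_bounds$min, "-"), 2L, rng, "/")
  }
  d <- as.matrix(stats::dist(Xs))
  diag(d) <- Inf
  nn_idx <- matrix(0L, n, k)
  for (r in seq_len(n)) nn_idx[r, ] <- order(d[r, ])[seq_len(k)]

  with_seed(seed, {
    base <- rep_len(seq_len(n), n_syn)
    pick <- nn_idx[cbind(base, sample.int(k, n_syn, replace = TRUE))]
    u <- runif(n_syn)
    out <- minority[base, , drop = FALSE] +
      u * (minority[pick, , drop = FALSE] - minority[base, , drop = FALSE])
  })
  rownames(out) <- NULL
  out
}
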