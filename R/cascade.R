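new_stage_training_set <- function(stage, X, y, ids) {
  stopifnot(stage %in% 1:3, nrow(X) == length(y))
  structure(list(stage = stage, X = X,
                 y = factor(y, levels = c("negative", "positive")),
                 ids = ids),
            class = "stage_training_set")
}

#' @export
print.stage_training_set <- function(x, ...) {
  cat(sprintf("<stage_training_set> stage %d: %d x %d (%d positive, %d negative)\n",
              x$stage, nrow(x$X), ncol(x$X),
              sum(x$y == "positive"), sum(x$y == "negative")))
  invisible(x)
}

# Enumerate the three structure levels of one window with no classifier
# gating: all exact stems, the deduplicated non-exact stems they extend
# to, and one hairpin per non-exact stem.
enumerate_structures <- function(pm, config) {
  stems <- find_exact_stems(pm, config$min_exact_stem, config$min_loop)
  nes_map <- list()
  for (st in stems) {
    nes <- extend_to_non_exact_stem(pm, st, config$min_loop)
    key <- paste(nes$psum, nes$stems[[1L]]$a5_start, n_pairs(nes), sep = ":")
    if (is.null(nes_map[[key]])) nes_map[[key]] <- nes
  }
  nes_list <- unname(nes_map)
  hairpins <- lapply(nes_list, function(nes) build_hairpin(pm, nes, config))
  list(stems = stems, nes = nes_list, hairpins = hairpins)
}

best_structure <- function(lst, pos_of) {
  scores <- vapply(lst, n_pairs, 0L)
  at <- vapply(lst, pos_of, 0L)
  lst[[order(-scores, at)[1L]]]
}

#' Build the three stage-wise training sets
#'
#' Every input sequence is run through matrix construction and the full
#' three-stage structural search with no classifier gating; at each
#' stage the single highest-scoring candidate (most paired bases, ties
#' broken 5'-most) contributes one labelled example, so each sequence
#' yields at most one row per stage. Sequences producing no exact stem
#' are skipped with a warning.
#'
#' @param positives,negatives Lists of [rna_seq] (known hairpins vs.
#'   other ncRNA / pseudo-hairpin / background sequences).
#' @param config A [scan_config].
#' @param energy Energy backend for the feature computation.
#' @return List of three `stage_training_set`s (ARFF-serializable via
#'   [write_arff]).
#' @export
build_stage_training_sets <- function(positives, negatives,
                                      config = scan_config(),
                                      energy = stacking_energy_backend()) {
  stopifnot(length(positives) >= 1L, length(negatives) >= 1L)
  rows <- list(list(), list(), list())
  labs <- list(character(), character(), character())
  ids <- list(character(), character(), character())
  for (label in c("positive", "negative")) {
    seqs <- if (label == "positive") positives else negatives
    for (sq in seqs) {
      pm <- build_pairing_matrix(sq)
      es <- enumerate_structures(pm, config)
      if (!length(es$stems)) {
        warning("sequence '", sq$id, "' yields no exact stem (>= ",
                config$min_exact_stem, " bp); skipped", call. = FALSE)
        next
      }
      fv <- list(
        stage1_features(best_structure(es$stems, function(s) s$a5_start),
                        sq, energy),
        stage2_features(best_structure(es$nes,
                                       function(s) s$stems[[1L]]$a5_start),
                        sq, energy),
        stage3_features(best_structure(es$hairpins, function(h) h$start),
                        sq, energy))
      for (s in 1:3) {
        rows[[s]][[length(rows[[s]]) + 1L]] <- as.numeric(fv[[s]])
        labs[[s]] <- c(labs[[s]], label)
        ids[[s]] <- c(ids[[s]], sq$id)
      }
    }
  }
  out <- vector("list", 3L)
  for (s in 1:3) {
    if (!length(rows[[s]]) || length(unique(labs[[s]])) < 2L)
      stop("training-data error: need at least one usable example of ",
           "each class at stage ", s, call. = FALSE)
    X <- do.call(rbind, rows[[s]])
    colnames(X) <- feature_names(s)
    out[[s]] <- new_stage_training_set(s, X, labs[[s]], ids[[s]])
  }
  out
}

scale_bounds_of <- function(X)
  list(min = apply(X, 2L, min), max = apply(X, 2L, max))

# SMOTE the minority class of (X, y) to parity. Returns the augmented
# X/y plus the synthetic block for audit.
rebalance_smote <- function(X, y, k, seed, bounds = scale_bounds_of(X)) {
  counts <- table(y)
  if (counts[1L] == counts[2L])
    return(list(X = X, y = y, synthetic = X[0, , drop = FALSE]))
  minority <- names(counts)[which.min(counts)]
  idx <- which(y == minority)
  synth <- smote_oversample(X[idx, , drop = FALSE], k = k,
                            target = max(counts), seed = seed,
                            scale_bounds = bounds)
  list(X = rbind(X, synth),
       y = factor(c(as.character(y), rep(minority, nrow(synth))),
                  levels = levels(y)),
       synthetic = synth)
}

#' Train one stage model (SMOTE + random forest)
#'
#' The minority class is SMOTE-oversampled to parity (neighbour search
#' on min-max-scaled features; the scaling bounds are stored with the
#' model) and a random forest is trained on the balanced set.
#'
#' @param ts A `stage_training_set`.
#' @param smote_k SMOTE neighbour count (default 5).
#' @param n_trees Forest size (default 100).
#' @param seed Integer seed; training is reproducible per seed.
#' @return A `stage_model` emitting P(positive).
#' @export
train_stage_model <- function(ts, smote_k = 5L, n_trees = 100L, seed = 1L) {
  stopifnot(inherits(ts, "stage_training_set"))
  if (length(unique(ts$y)) < 2L)
    stop("training-data error: single-class training set", call. = FALSE)
  bounds <- scale_bounds_of(ts$X)
  bal <- rebalance_smote(ts$X, ts$y, smote_k, seed, bounds)
  rf <- rf_train(bal$X, bal$y, n_trees = n_trees,
                 seed = seed + 1000L * ts$stage)
  structure(list(stage = ts$stage, rf = rf,
                 feature_names = colnames(ts$X), scale_bounds = bounds,
                 smote_k = as.integer(smote_k),
                 n_trees = as.integer(n_trees), seed = as.integer(seed),
                 class_counts = table(ts$y),
                 balanced_counts = table(bal$y)),
            class = "stage_model")
}

#' Gate a feature vector through a stage model
#'
#' @param model A `stage_model`.
#' @param fv A `feature_vector` of the matching stage, or a matrix of
#'   them (one per row).
#' @param threshold Probability threshold; a candidate passes when
#'   P(positive) is greater than or equal to it (inclusive rule).
#' @return List with `prob` and logical `pass`, vectorized over rows.
#' @export
classify_stage <- function(model, fv, threshold) {
  stopifnot(inherits(model, "stage_model"),
            threshold >= 0, threshold <= 1)
  if (!is.matrix(fv)) {
    st <- attr(fv, "stage")
    if (!is.null(st) && st != model$stage)
      stop("feature vector stage ", st, " does not match model stage ",
           model$stage, call. = FALSE)
    fv <- matrix(as.numeric(fv), nrow = 1L,
                 dimnames = list(NULL, names(fv)))
  }
  if (ncol(fv) != length(model$feature_names))
    stop("feature vector stage does not match model stage", call. = FALSE)
  prob <- rf_predict(model$rf, fv)
  list(prob = prob, pass = prob >= threshold)
}

#' Train the full three-stage cascade
#'
#' Convenience wrapper: builds the stage training sets from positive and
#' negative FASTA-derived sequences and trains one SMOTE + random-forest
#' model per stage.
#'
#' @inheritParams build_stage_training_sets
#' @inheritParams train_stage_model
#' @return A `cascade_model` (three `stage_model`s plus the stage
#'   thresholds from `config`).
#' @export
train_cascade <- function(positives, negatives, config = scan_config(),
                          smote_k = 5L, n_trees = 100L, seed = 1L,
                          energy = stacking_energy_backend()) {
  sets <- build_stage_training_sets(positives, negatives, config, energy)
  models <- lapply(sets, train_stage_model, smote_k = smote_k,
                   n_trees = n_trees, seed = seed)
  structure(list(models = models, thresholds = config$thresholds,
                 config = config, seed = as.integer(seed)),
            class = "cascade_model")
}

#' @export
print.cascade_model <- function(x, ...) {
  cat(sprintf("<cascade_model> thresholds (%.2f, %.2f, %.2f); %d trees/stage\n",
              x$thresholds[1L], x$thresholds[2L], x$thresholds[3L],
              x$models[[1L]]$n_trees))
  invisible(x)
}

#' Stratified cross-validation of a stage training set
#'
#' Stratified k-fold CV of the SMOTE + random-forest stage classifier.
#' SMOTE runs inside each training fold only — synthetic points never
#' enter an evaluation fold — and fold-wise confusion counts are pooled
#' before computing the metrics. Class decisions use P(positive) >= 0.5.
#'
#' @param ts A `stage_training_set`.
#' @param folds Number of folds (default 10); both classes must have at
#'   least `folds` members.
#' @param seed Integer seed driving fold assignment, SMOTE and forests.
#' @param smote_k,n_trees As in [train_stage_model].
#' @return List with `SN`, `SL`, `GM`, pooled `counts`
#'   (TP/FP/FN/TN) and `fold_details` (per fold: original test indices,
#'   training indices and the synthetic block added to that training
#'   fold) for leakage audits.
#' @export
cross_validate <- function(ts, folds = 10L, seed = 1L, smote_k = 5L,
                           n_trees = 100L) {
  stopifnot(inherits(ts, "stage_training_set"), folds >= 2L)
  y <- ts$y
  if (any(table(y) < folds))
    stop("cv-configuration error: each class needs >= ", folds,
         " examples", call. = FALSE)
  fold_id <- integer(length(y))
  with_seed(seed, for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold_id[idx] <- rep_len(seq_len(folds), length(idx))
  })
  tp <- fp <- fn <- tn <- 0L
  details <- vector("list", folds)
  for (f in seq_len(folds)) {
    test_idx <- which(fold_id == f)
    train_idx <- which(fold_id != f)
    Xtr <- ts$X[train_idx, , drop = FALSE]
    ytr <- y[train_idx]
    bal <- rebalance_smote(Xtr, ytr, smote_k, seed + f)
    rf <- rf_train(bal$X, bal$y, n_trees = n_trees, seed = seed + 7L * f)
    prob <- rf_predict(rf, ts$X[test_idx, , drop = FALSE])
    pred_pos <- prob >= 0.5
    truth_pos <- y[test_idx] == "positive"
    tp <- tp + sum(pred_pos & truth_pos)
    fp <- fp + sum(pred_pos & !truth_pos)
    fn <- fn + sum(!pred_pos & truth_pos)
    tn <- tn + sum(!pred_pos & !truth_pos)
    details[[f]] <- list(test = test_idx, train = train_idx,
                         synthetic = bal$synthetic)
  }
  m <- compute_metrics(tp, fn, fp)
  list(SN = m[["SN"]], SL = m[["SL"]], GM = m[["GM"]],
       counts = c(TP = tp, FP = fp, FN = fn, TN = tn),
       fold_details = details)
}

#' Persist a cascade model to a directory
#'
#' One serialized model file per stage plus a plain-text `metadata.txt`
#' recording seed, thresholds, SMOTE/forest parameters, feature order
#' and scaling bounds.
#'
#' @param model A `cascade_model`.
#' @param dir Target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_cascade <- function(model, dir) {
  stopifnot(inherits(model, "cascade_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in 1:3)
    saveRDS(model$models[[s]], file.path(dir, sprintf("stage%d.rds", s)))
  meta <- c(sprintf("thresholds=%s", paste(model$thresholds, collapse = ",")),
            sprintf("seed=%d", model$seed),
            sprintf("smote_k=%d", model$models[[1L]]$smote_k),
            sprintf("n_trees=%d", model$models[[1L]]$n_trees),
            unlist(lapply(1:3, function(s) c(
              sprintf("stage%d_features=%s", s,
                      paste(model$models[[s]]$feature_names, collapse = ",")),
              sprintf("stage%d_scale_min=%s", s,
                      paste(model$models[[s]]$scale_bounds$min, collapse = ",")),
              sprintf("stage%d_scale_max=%s", s,
                      paste(model$models[[s]]$scale_bounds$max, collapse = ","))))))
  writeLines(meta, file.path(dir, "metadata.txt"))
  saveRDS(model$config, file.path(dir, "config.rds"))
  invisible(dir)
}

#' Load a cascade model saved by [save_cascade]
#'
#' @param dir Model directory.
#' @return A `cascade_model`.
#' @export
load_cascade <- function(dir) {
  models <- lapply(1:3, function(s)
    readRDS(file.path(dir, sprintf("stage%d.rds", s))))
  meta <- readLines(file.path(dir, "metadata.txt"))
  thr <- as.numeric(strsplit(sub("^thresholds=", "",
                                 grep("^thresholds=", meta, value = TRUE)),
                             ",")[[1L]])
  seed <- as.integer(sub("^seed=", "", grep("^seed=", meta, value = TRUE)))
  config <- readRDS(file.path(dir, "config.rds"))
  structure(list(models = models, thresholds = thr, config = config,
                 seed = seed),
            class = "cascade_model")
}
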