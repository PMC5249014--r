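empty_predictions <- function() {
  data.frame(seqid = character(), start = integer(), end = integer(),
             strand = character(), prob = numeric(),
             structure = character(), seq = character(),
             window = integer(), stringsAsFactors = FALSE)
}

# Window start offsets: 0, step, 2*step, ... plus a final window
# anchored at n - window so the 3' tail is always covered.
window_offsets <- function(n, window, step) {
  n <- as.integer(n); window <- as.integer(window); step <- as.integer(step)
  if (n <= window) return(0L)
  off <- seq.int(0L, n - window, by = step)
  if (off[length(off)] != n - window) off <- c(off, n - window)
  as.integer(off)
}

#' Scan a sequence for pre-miRNA hairpins with a trained cascade
#'
#' Slides a window along the sequence (default 150 nt, 10-nt steps, last
#' window anchored at the tail). Per window the pairing matrix is built
#' and candidates flow through the three gates: exact stems are scored
#' by the stage-1 model, surviving stems are extended to non-exact stems
#' and scored by stage 2, and the hairpins built from surviving
#' non-exact stems are scored by stage 3 and size-filtered. Surviving
#' hairpins are mapped to source coordinates and duplicates from
#' overlapping windows are merged with [merge_predictions]. Stage-3
#' feature vectors are cached by (subsequence, structure) because the
#' same hairpin is re-found by consecutive windows.
#'
#' @param seq An [rna_seq] (DNA accepted, normalized to RNA).
#' @param model A trained `cascade_model`.
#' @param config A [scan_config]; defaults to the one the model was
#'   trained with.
#' @param energy Energy backend used for the features.
#' @return Prediction data frame: `seqid`, `start`, `end` (0-based
#'   half-open), `strand`, `prob` (stage-3 probability), `structure`
#'   (dot-bracket), `window` (origin offset). Sorted by start.
#' @export
scan_sequence <- function(seq, model, config = NULL,
                          energy = stacking_energy_backend()) {
  stopifnot(inherits(seq, "rna_seq"), inherits(model, "cascade_model"))
  if (is.null(config)) config <- model$config
  if (seq$n < config$min_size) {
    warning("sequence '", seq$id, "' shorter than min_size; no scan",
            call. = FALSE)
    return(empty_predictions())
  }
  preds <- scan_strand(seq, model, config, energy, "+")
  if (config$scan_reverse) {
    rc <- rna_seq(reverse_complement(seq$residues), id = seq$id)
    rp <- scan_strand(rc, model, config, energy, "-")
    if (nrow(rp)) {
      s <- rp$start
      rp$start <- seq$n - rp$end
      rp$end <- seq$n - s
    }
    preds <- rbind(preds, rp)
  }
  merge_predictions(preds)
}

# Look up cached probabilities by key, computing and caching the missing
# ones with `fv_fun` (feature row builder) and the stage model.
cached_probs <- function(cache, keys, items, fv_fun, rf, n_feat) {
  miss <- which(!vapply(keys, function(k) !is.null(cache[[k]]), TRUE))
  if (length(miss)) {
    X <- t(vapply(items[miss], fv_fun, numeric(n_feat)))
    pr <- rf_predict(rf, X)
    for (t in seq_along(miss)) cache[[keys[miss[t]]]] <- pr[t]
  }
  vapply(keys, function(k) cache[[k]], 0)
}

scan_strand <- function(seq, model, config, energy, strand) {
  thr <- model$thresholds
  # caches keyed on absolute coordinates: overlapping windows re-find
  # the same stems/stems-chains, whose features only depend on content
  cache1 <- new.env(parent = emptyenv())
  cache2 <- new.env(parent = emptyenv())
  cache <- new.env(parent = emptyenv())
  acc_start <- integer(); acc_end <- integer(); acc_prob <- numeric()
  acc_struct <- character(); acc_seq <- character(); acc_win <- integer()
  for (off in window_offsets(seq$n, config$window, config$step)) {
    win <- window_seq(seq, off, min(config$window, seq$n))
    win_chars <- nt_chars(win)
    pm <- build_pairing_matrix(win)
    stems <- find_exact_stems(pm, config$min_exact_stem, config$min_loop)
    if (!length(stems)) next
    k1 <- vapply(stems, function(st)
      sprintf("%d:%d:%d", off + st$a5_start,
              off + st$psum - st$a5_start, st$L), "")
    p1 <- cached_probs(cache1, k1, stems, function(st)
      as.numeric(stage1_features(st, win_chars, energy)),
      model$models[[1L]]$rf, 29L)
    stems <- stems[p1 >= thr[1L]]
    if (!length(stems)) next

    nes_map <- list()
    for (st in stems) {
      nes <- extend_to_non_exact_stem(pm, st, config$min_loop)
      key <- paste(2L * off + nes$psum,
                   paste(vapply(nes$stems, function(s)
                     sprintf("%d.%d", off + s$a5_start, s$L), ""),
                     collapse = "_"),
                   sep = ":")
      if (is.null(nes_map[[key]])) nes_map[[key]] <- nes
    }
    nes_list <- unname(nes_map)
    p2 <- cached_probs(cache2, names(nes_map), nes_list, function(ns)
      as.numeric(stage2_features(ns, win_chars, energy)),
      model$models[[2L]]$rf, 35L)
    nes_list <- nes_list[p2 >= thr[2L]]
    if (!length(nes_list)) next

    seen <- new.env(parent = emptyenv())
    for (nes in nes_list) {
      cand <- build_hairpin(pm, nes, config)
      if (!filter_by_size(cand, config$min_size, config$max_size)) next
      key <- paste(cand$seq, cand$structure, sep = "|")
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      p3 <- if (!is.null(cache[[key]])) cache[[key]]
      else {
        fv <- stage3_features(cand, win_chars, energy)
        pr <- rf_predict(model$models[[3L]]$rf,
                         matrix(as.numeric(fv), nrow = 1L))
        cache[[key]] <- pr
        pr
      }
      if (p3 < thr[3L]) next
      acc_start <- c(acc_start, off + cand$start)
      acc_end <- c(acc_end, off + cand$end)
      acc_prob <- c(acc_prob, p3)
      acc_struct <- c(acc_struct, cand$structure)
      acc_seq <- c(acc_seq, cand$seq)
      acc_win <- c(acc_win, off)
    }
  }
  if (!length(acc_start)) return(empty_predictions())
  data.frame(seqid = seq$id, start = acc_start, end = acc_end,
             strand = strand, prob = acc_prob, structure = acc_struct,
             seq = acc_seq, window = acc_win, stringsAsFactors = FALSE)
}

#' Merge duplicate predictions from overlapping windows
#'
#' Greedy maximum-probability suppression: the highest-probability
#' prediction is kept and absorbs every prediction on the same sequence
#' and strand whose interval overlaps it by at least 50% of both lengths
#' (reciprocal overlap); the rule repeats on the remainder. This keeps
#' the prediction count non-increasing when the stage-3 threshold rises.
#' Output sorted by start.
#'
#' @param preds Prediction data frame as returned by [scan_sequence].
#' @return Reduced prediction data frame.
#' @export
merge_predictions <- function(preds) {
  if (!nrow(preds)) return(preds)
  # collapse exact interval duplicates (the same hairpin re-found by
  # consecutive windows) before the pairwise overlap suppression
  key <- paste(preds$seqid, preds$strand, preds$start, preds$end)
  best_dup <- vapply(split(seq_len(nrow(preds)), key), function(idx)
    idx[which.max(preds$prob[idx])], 0L)
  preds <- preds[sort(unname(best_dup)), , drop = FALSE]
  n <- nrow(preds)
  gr <- GenomicRanges::GRanges(
    seqnames = paste(preds$seqid, preds$strand),
    ranges = IRanges::IRanges(start = preds$start + 1L, end = preds$end))
  hits <- GenomicRanges::findOverlaps(gr, drop.self = TRUE)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ov <- pmin(preds$end[qi], preds$end[si]) -
        pmax(preds$start[qi], preds$start[si])
  recip <- ov >= 0.5 * (preds$end[qi] - preds$start[qi]) &
           ov >= 0.5 * (preds$end[si] - preds$start[si])
  partners <- split(si[recip], factor(qi[recip], levels = seq_len(n)))
  state <- integer(n)                      # 0 undecided, 1 keep, -1 gone
  for (i in order(-preds$prob, preds$start)) {
    if (state[i] != 0L) next
    state[i] <- 1L
    ps <- partners[[i]]
    state[ps[state[ps] == 0L]] <- -1L
  }
  res <- preds[state == 1L, , drop = FALSE]
  res <- res[order(res$seqid, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Sensitivity, selectivity and their geometric mean
#'
#' `SN = 100 TP / (TP + FN)`, `SL = 100 TP / (TP + FP)` (selectivity,
#' i.e. precision) and `GM = sqrt(SN * SL)`. A zero denominator yields 0
#' with a warning.
#'
#' @param tp,fn,fp Non-negative confusion counts.
#' @return Named numeric vector `c(SN, SL, GM)` (percentages).
#' @examples
#' compute_metrics(tp = 3, fn = 1, fp = 1)
#' @export
compute_metrics <- function(tp, fn, fp) {
  if (any(c(tp, fn, fp) < 0)) stop("counts must be >= 0", call. = FALSE)
  sn <- if (tp + fn > 0) 100 * tp / (tp + fn) else {
    warning("TP + FN = 0; SN set to 0", call. = FALSE); 0
  }
  sl <- if (tp + fp > 0) 100 * tp / (tp + fp) else {
    warning("TP + FP = 0; SL set to 0", call. = FALSE); 0
  }
  c(SN = sn, SL = sl, GM = geometric_mean(sn, sl))
}

#' Geometric mean of sensitivity and selectivity
#'
#' @param sn,sl Percentages.
#' @return `sqrt(sn * sl)`.
#' @export
geometric_mean <- function(sn, sl) sqrt(sn * sl)

#' Match predictions against known hairpins and evaluate
#'
#' A prediction is a true positive when the distance between its center
#' and the center of a known hairpin is at most 10% of the known
#' hairpin's length (inclusive). Matching is greedy one-to-one by
#' smallest center distance; every known hairpin absorbs at most one
#' prediction. Unmatched predictions are false positives and unmatched
#' known hairpins false negatives.
#'
#' @param preds Prediction data frame (0-based half-open `start`/`end`,
#'   `seqid`).
#' @param known Data frame of known hairpins with columns `seqid`,
#'   `start`, `end` (same coordinate convention; see [read_truth_bed]).
#' @param center_tol Matching tolerance as a fraction of the known
#'   hairpin length (default 0.1).
#' @return An `evaluation_result`: counts `TP`, `FP`, `FN`, metrics
#'   `SN`, `SL`, `GM` and the matched-pairs data frame.
#' @export
match_predictions <- function(preds, known, center_tol = 0.1) {
  pc <- (preds$start + preds$end) / 2
  kc <- (known$start + known$end) / 2
  cand <- expand.grid(p = seq_len(nrow(preds)), k = seq_len(nrow(known)))
  if (nrow(cand)) {
    cand <- cand[preds$seqid[cand$p] == known$seqid[cand$k], , drop = FALSE]
    cand$dist <- abs(pc[cand$p] - kc[cand$k])
    cand$tol <- center_tol * (known$end[cand$k] - known$start[cand$k])
    cand <- cand[cand$dist <= cand$tol, , drop = FALSE]
    cand <- cand[order(cand$dist, cand$p, cand$k), , drop = FALSE]
  }
  used_p <- logical(nrow(preds)); used_k <- logical(nrow(known))
  matches <- list()
  if (nrow(cand)) for (r in seq_len(nrow(cand))) {
    i <- cand$p[r]; j <- cand$k[r]
    if (used_p[i] || used_k[j]) next
    used_p[i] <- TRUE; used_k[j] <- TRUE
    matches[[length(matches) + 1L]] <-
      data.frame(pred = i, known = j, dist = cand$dist[r])
  }
  tp <- sum(used_p)
  fp <- sum(!used_p)
  fn <- sum(!used_k)
  m <- compute_metrics(tp, fn, fp)
  structure(list(TP = tp, FP = fp, FN = fn,
                 SN = m[["SN"]], SL = m[["SL"]], GM = m[["GM"]],
                 matches = if (length(matches)) do.call(rbind, matches)
                           else data.frame(pred = integer(),
                                           known = integer(),
                                           dist = numeric())),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("<evaluation_result> TP=%d FP=%d FN=%d | SN=%.2f SL=%.2f GM=%.2f\n",
              x$TP, x$FP, x$FN, x$SN, x$SL, x$GM))
  invisible(x)
}

preds_to_granges <- function(preds) {
  GenomicRanges::GRanges(
    seqnames = preds$seqid,
    ranges = IRanges::IRanges(start = preds$start + 1L, end = preds$end),
    strand = preds$strand)
}

#' Write predictions as GFF3
#'
#' 1-based coordinates, feature type `pre_miRNA`, the stage-3
#' probability as score.
#'
#' @param preds Prediction data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(preds, path) {
  gr <- preds_to_granges(preds)
  gr$source <- "mircascade"
  gr$type <- "pre_miRNA"
  gr$score <- round(preds$prob, 4)
  gr$ID <- sprintf("premir_%03d", seq_len(nrow(preds)))
  gr$structure <- preds$structure
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write predictions as BED6
#'
#' Score is the probability scaled to 0-1000 as BED requires.
#'
#' @inheritParams write_gff3
#' @export
write_bed <- function(preds, path) {
  gr <- preds_to_granges(preds)
  gr$name <- sprintf("premir_%03d", seq_len(nrow(preds)))
  gr$score <- round(1000 * preds$prob)
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read known hairpin annotations from BED
#'
#' @param path BED file of known hairpins.
#' @return Data frame `seqid`, `start`, `end` (0-based half-open),
#'   `name` — the convention [match_predictions] expects.
#' @export
read_truth_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(seqid = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             name = if (!is.null(gr$name)) gr$name else
               sprintf("known_%03d", seq_along(gr)),
             stringsAsFactors = FALSE)
}

#' Read predictions back from a GFF3 written by [write_gff3]
#'
#' @param path GFF3 path.
#' @return Prediction data frame (0-based half-open).
#' @export
read_gff3_predictions <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  data.frame(seqid = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             prob = as.numeric(gr$score),
             structure = if (!is.null(gr$structure))
               as.character(gr$structure) else NA_character_,
             window = NA_integer_,
             stringsAsFactors = FALSE)
}
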