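#' Feature names for a cascade stage
#'
#' Stage 1 has 29 features (stem size, deltaG, nucleotide composition,
#' maximum homopolymer runs, percentage of G:U pairing, the 16
#' dinucleotide percentages and the two composition-difference
#' percentages). Stage 2 appends 6 pairing/loop statistics (35 total);
#' stage 3 appends 13 hairpin-geometry and energy-index features plus the
#' 32 structure triplets (80 total). Each stage's vector is a
#' prefix-extension of the previous stage's block, recomputed over the
#' larger structure.
#'
#' @param stage Integer 1, 2 or 3.
#' @return Character vector of feature names in canonical order.
#' @export
feature_names <- function(stage) {
  s1 <- c("size", "delta_g",
          paste0("pct_", NT_ALPHABET), paste0("maxrun_", NT_ALPHABET),
          "pct_gu_pairing", paste0("dinuc_", DINUCS),
          "pct_ga_minus_cu", "pct_g_minus_c")
  s2 <- c(s1, "pct_base_pairing", "n_exact_stems", "avg_palindrome_size",
          "n_sym_loops", "avg_sym_loop", "max_sym_loop")
  s3 <- c(s2, "avg_exact_stem_size", "terminal_loop_size", "pct_gc_pairing",
          "adj_mfe", "pct_nes_coverage", "max_bulge_side_diff",
          "max_bulge_left", "max_bulge_right", "bulge_count_diff_lr",
          "n_consec_bulges", "n_consec_bulges_same_side", "mfe1", "mfe2",
          TRIPLET_NAMES)
  switch(stage, s1, s2, s3)
}

new_feature_vector <- function(values, stage) {
  nm <- feature_names(stage)
  stopifnot(identical(names(values), nm))
  structure(values, stage = stage, class = c("feature_vector", "numeric"))
}

#' Dinucleotide percentage profile
#'
#' @param seq An [rna_seq] or nucleotide string of length >= 2.
#' @return Named numeric vector of the 16 ordered dinucleotide
#'   percentages (100 x count / (n - 1)); sums to 100.
#' @examples
#' dinucleotide_profile("ACGU")
#' @export
dinucleotide_profile <- function(seq) {
  chars <- nt_chars(seq)
  n <- length(chars)
  if (n < 2L) stop("sequence shorter than 2 nt", call. = FALSE)
  di <- paste0(chars[-n], chars[-1L])
  counts <- table(factor(di, levels = DINUCS))
  setNames(100 * as.numeric(counts) / (n - 1L), paste0("dinuc_", DINUCS))
}

#' Structure triplet percentage profile
#'
#' For every window of three consecutive positions, the paired/unpaired
#' pattern (closing brackets count as paired) together with the middle
#' nucleotide defines one of 4 x 8 = 32 triplet elements; the profile is
#' the percentage of the n - 2 windows showing each element and sums
#' to 100.
#'
#' @param seq An [rna_seq] or string of length n >= 3.
#' @param structure Dot-bracket string of the same length.
#' @return Named numeric vector of 32 percentages (pattern letters: `p`
#'   paired, `u` unpaired).
#' @export
triplet_profile <- function(seq, structure) {
  chars <- nt_chars(seq)
  n <- length(chars)
  sym <- strsplit(chartr("()", "pp", structure), "", fixed = TRUE)[[1L]]
  if (length(sym) != n)
    stop("structure length does not match sequence", call. = FALSE)
  if (n < 3L) stop("sequence shorter than 3 nt", call. = FALSE)
  if (any(!sym %in% c("p", ".")))
    stop("invalid dot-bracket character", call. = FALSE)
  sym[sym == "."] <- "u"
  pat <- paste0(sym[1:(n - 2L)], sym[2:(n - 1L)], sym[3:n])
  key <- paste0("tri_", chars[2:(n - 1L)], "_", pat)
  counts <- table(factor(key, levels = TRIPLET_NAMES))
  setNames(100 * as.numeric(counts) / (n - 2L), TRIPLET_NAMES)
}

# Composition block shared by all stages, computed over `chars`:
# nucleotide percentages, max homopolymer runs, dinucleotides and the two
# composition differences. Returns the 26 values in stage-1 order
# (without size/delta_g/pct_gu_pairing).
composition_block <- function(chars) {
  n <- length(chars)
  codes <- match(chars, NT_ALPHABET)
  cnt <- tabulate(codes, 4L)
  pct <- setNames(100 * cnt / n, paste0("pct_", NT_ALPHABET))
  r <- rle(codes)
  maxrun <- vapply(1:4, function(k) {
    hit <- r$lengths[r$values == k]
    if (length(hit)) max(hit) else 0L
  }, 0L)
  names(maxrun) <- paste0("maxrun_", NT_ALPHABET)
  di <- if (n >= 2L)
    setNames(100 * tabulate((codes[-n] - 1L) * 4L + codes[-1L], 16L) /
               (n - 1L), paste0("dinuc_", DINUCS))
  else setNames(rep(0, 16L), paste0("dinuc_", DINUCS))
  diffs <- c(pct_ga_minus_cu =
               100 * ((cnt[3L] + cnt[1L]) - (cnt[2L] + cnt[4L])) / n,
             pct_g_minus_c = 100 * (cnt[3L] - cnt[2L]) / n)
  c(pct, maxrun, di, diffs)
}

pct_pair_type <- function(chars, pairs, type) {
  if (!nrow(pairs)) return(0)
  cls <- pair_class(chars[pairs[, "a"] + 1L], chars[pairs[, "b"] + 1L])
  100 * sum(cls == type) / nrow(pairs)
}

stem_pairs <- function(stem) {
  cbind(a = stem$a5_start + seq_len(stem$L) - 1L,
        b = stem$psum - stem$a5_start - seq_len(stem$L) + 1L)
}

nes_pairs <- function(nes) do.call(rbind, lapply(nes$stems, stem_pairs))

safe_ratio <- function(num, den, what) {
  if (den == 0) {
    warning("zero denominator for ", what, "; feature set to 0",
            call. = FALSE)
    return(0)
  }
  num / den
}

#' Stage-1 feature vector of an exact stem
#'
#' 29 features computed over the stem's two arms concatenated: stem size
#' (bp), duplex deltaG of the arms, nucleotide and dinucleotide
#' composition, maximum homopolymer runs, the percentage of G:U wobbles
#' among the stem's pairs, and the (G+A)-(C+U) and G-C composition
#' differences (as percentages of the arm length, possibly negative).
#'
#' @param stem An `exact_stem`.
#' @param seq The [rna_seq] window it was found in.
#' @param energy An energy backend (default [stacking_energy_backend]).
#' @return A `feature_vector` (stage 1).
#' @export
stage1_features <- function(stem, seq, energy = stacking_energy_backend()) {
  chars <- nt_chars(seq)
  arm5 <- chars[stem$a5_start + seq_len(stem$L)]
  arm3 <- chars[stem$a3_start + seq_len(stem$L)]
  region <- c(arm5, arm3)
  comp <- composition_block(region)
  vals <- c(size = stem$L,
            delta_g = energy$duplex_energy(paste(arm5, collapse = ""),
                                           paste(arm3, collapse = "")),
            comp[1:8],
            pct_gu_pairing = pct_pair_type(chars, stem_pairs(stem), "GU"),
            comp[9:26])
  names(vals) <- feature_names(1L)
  new_feature_vector(vals, 1L)
}

# Shared stage-1-style block recomputed over an arbitrary paired
# structure spanning [start, end) with helix list `helices`.
stage1_block_for <- function(chars, start, end, helices, pairs, energy) {
  region <- chars[(start + 1L):end]
  comp <- composition_block(region)
  vals <- c(size = sum(vapply(helices, `[[`, 0L, "L")),
            delta_g = helices_energy(energy, chars, helices),
            comp[1:8],
            pct_gu_pairing = pct_pair_type(chars, pairs, "GU"),
            comp[9:26])
  names(vals) <- feature_names(1L)
  vals
}

nes_helices <- function(nes) {
  lapply(nes$stems, function(st)
    list(a = st$a5_start, b = st$psum - st$a5_start, L = st$L))
}

#' Stage-2 feature vector of a non-exact stem
#'
#' The stage-1 block recomputed over the region the non-exact stem spans
#' (size becomes the total paired bases, deltaG the summed helix
#' energies, composition over the whole spanned region) plus the
#' percentage of paired nt in the region, the number of exact stems, the
#' mean exact-stem (palindrome) length, and count/mean/max of the
#' symmetric internal loops (all 0 when there is no loop).
#'
#' @inheritParams stage1_features
#' @param nes A `non_exact_stem`.
#' @return A `feature_vector` (stage 2, 35 values).
#' @export
stage2_features <- function(nes, seq, energy = stacking_energy_backend()) {
  chars <- nt_chars(seq)
  start <- nes$stems[[1L]]$a5_start
  end <- nes$psum - start + 1L
  pairs <- nes_pairs(nes)
  lens <- vapply(nes$stems, `[[`, 0L, "L")
  vals <- c(stage1_block_for(chars, start, end, nes_helices(nes), pairs,
                             energy),
            pct_base_pairing = 100 * 2 * nrow(pairs) / (end - start),
            n_exact_stems = length(nes$stems),
            avg_palindrome_size = mean(lens),
            n_sym_loops = length(nes$loops),
            avg_sym_loop = if (length(nes$loops)) mean(nes$loops) else 0,
            max_sym_loop = if (length(nes$loops)) max(nes$loops) else 0)
  names(vals) <- feature_names(2L)
  new_feature_vector(vals, 2L)
}

# nt covered by non-exact-stem regions of a candidate: maximal groups of
# helices chained by symmetric loops only, counting stems plus enclosed
# symmetric loops on both arms.
nes_coverage_nt <- function(cand) {
  H <- cand$helices
  if (!length(H)) return(0L)
  brk <- c(TRUE, vapply(seq_along(H)[-1L], function(k) {
    g5 <- H[[k]]$g5; g3 <- H[[k]]$g3
    !(g5 == g3)          # only symmetric loops keep a group together
  }, TRUE))
  grp <- cumsum(brk)
  tot <- 0L
  for (g in unique(grp)) {
    idx <- which(grp == g)
    first <- H[[idx[1L]]]; last <- H[[idx[length(idx)]]]
    tot <- tot + ((last$a + last$L - 1L) - first$a + 1L) +
                 (first$b - (last$b - last$L + 1L) + 1L)
  }
  tot
}

#' Stage-3 feature vector of a hairpin candidate
#'
#' The stage-2 block recomputed over the full hairpin plus 13
#' hairpin-level features (mean exact-stem size, terminal loop size,
#' percentage of G:C pairs, length-adjusted MFE, percentage of the
#' hairpin covered by non-exact stems, bulge geometry, and the MFE1/MFE2
#' energy indices) and the 32 structure triplet percentages. Left/right
#' are measured relative to the terminal loop (left = 5' arm). MFE1 is
#' the adjusted MFE divided by the G+C percentage and MFE2 the adjusted
#' MFE divided by the number of exact stems; any zero denominator yields
#' 0 with a warning.
#'
#' @inheritParams stage1_features
#' @param cand A `hairpin_candidate`.
#' @return A `feature_vector` (stage 3, 80 values).
#' @export
stage3_features <- function(cand, seq, energy = stacking_energy_backend()) {
  chars <- nt_chars(seq)
  len <- cand$end - cand$start
  pairs <- cand$pairs
  lens <- vapply(cand$helices, `[[`, 0L, "L")
  el <- cand$elements
  loops <- el$g5[el$type == "symmetric_loop"]
  s1 <- stage1_block_for(chars, cand$start, cand$end, cand$helices, pairs,
                         energy)
  s2 <- c(s1,
          pct_base_pairing = 100 * 2 * nrow(pairs) / len,
          n_exact_stems = length(cand$helices),
          avg_palindrome_size = mean(lens),
          n_sym_loops = length(loops),
          avg_sym_loop = if (length(loops)) mean(loops) else 0,
          max_sym_loop = if (length(loops)) max(loops) else 0)

  region <- paste(chars[(cand$start + 1L):cand$end], collapse = "")
  adj_mfe <- 100 * energy$fold_mfe(region) / len
  gc_pct <- 100 * sum(nt_chars(region) %in% c("G", "C")) / len
  is_bulge <- el$type %in% c("bulge_left", "bulge_right")
  asym <- el$type %in% c("bulge_left", "bulge_right", "asymmetric_loop")
  nl <- sum(el$type == "bulge_left")
  nr <- sum(el$type == "bulge_right")
  consec <- if (nrow(el) > 1L)
    sum(is_bulge[-1L] & is_bulge[-length(is_bulge)]) else 0L
  consec_same <- if (nrow(el) > 1L)
    sum(is_bulge[-1L] & is_bulge[-length(is_bulge)] &
        el$type[-1L] == el$type[-nrow(el)]) else 0L

  s3 <- c(s2,
          avg_exact_stem_size = mean(lens),
          terminal_loop_size = cand$terminal_loop,
          pct_gc_pairing = pct_pair_type(chars, pairs, "GC"),
          adj_mfe = adj_mfe,
          pct_nes_coverage = 100 * nes_coverage_nt(cand) / len,
          max_bulge_side_diff = if (any(asym))
            max(abs(el$g5[asym] - el$g3[asym])) else 0,
          max_bulge_left = if (nl) max(el$g5[el$type == "bulge_left"]) else 0,
          max_bulge_right = if (nr) max(el$g3[el$type == "bulge_right"]) else 0,
          bulge_count_diff_lr = nl - nr,
          n_consec_bulges = consec,
          n_consec_bulges_same_side = consec_same,
          mfe1 = safe_ratio(adj_mfe, gc_pct, "MFE1 (%GC = 0)"),
          mfe2 = safe_ratio(adj_mfe, length(cand$helices), "MFE2"),
          triplet_profile(region, cand$structure))
  names(s3) <- feature_names(3L)
  new_feature_vector(s3, 3L)
}
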