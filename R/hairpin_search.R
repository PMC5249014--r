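#' Search configuration
#'
#' Collects the tunable parameters of the hairpin search and scanner with
#' the package defaults: minimum exact-stem size 4 bp, sliding window
#' 150 nt moved in 10-nt steps, candidate size bounds 50-150 nt, stage
#' probability thresholds (0.3, 0.3, 0.7), minimum terminal loop 3 nt,
#' maximum diagonal shift 10 nt and a stage-3 loop penalty of 0.3 per
#' unpaired nt.
#'
#' @param window,step Sliding-window length and step (nt).
#' @param min_exact_stem Minimum exact-stem length (bp) seeding stage 1.
#' @param min_size,max_size Inclusive hairpin size bounds (nt).
#' @param thresholds Numeric length-3 vector of stage probability
#'   thresholds; a candidate passes a stage when P(positive) >= threshold.
#' @param min_loop Minimum terminal-loop size (nt); steric floor for RNA.
#' @param max_shift Maximum unpaired gap per arm admitted in one stage-3
#'   extension step (bounds bulge/asymmetric-loop size).
#' @param loop_penalty Stage-3 score penalty per unpaired nt introduced.
#' @param scan_reverse Also scan the reverse strand (off by default).
#' @return A `scan_config` list.
#' @export
scan_config <- function(window = 150L, step = 10L, min_exact_stem = 4L,
                        min_size = 50L, max_size = 150L,
                        thresholds = c(0.3, 0.3, 0.7), min_loop = 3L,
                        max_shift = 10L, loop_penalty = 0.3,
                        scan_reverse = FALSE) {
  stopifnot(window >= max_size, step >= 1, min_exact_stem >= 1,
            min_size <= max_size, length(thresholds) == 3,
            all(thresholds >= 0 & thresholds <= 1), min_loop >= 0,
            max_shift >= 0, loop_penalty >= 0)
  structure(list(window = as.integer(window), step = as.integer(step),
                 min_exact_stem = as.integer(min_exact_stem),
                 min_size = as.integer(min_size),
                 max_size = as.integer(max_size),
                 thresholds = as.numeric(thresholds),
                 min_loop = as.integer(min_loop),
                 max_shift = as.integer(max_shift),
                 loop_penalty = loop_penalty,
                 scan_reverse = isTRUE(scan_reverse)),
            class = "scan_config")
}

# An exact stem on one diagonal of the pairing matrix, stored 0-based
# half-open. `psum` is the constant a+b of its base pairs (equivalently
# the diagonal id i-j = n-1-psum); arm5 = [a5_start, a5_end) pairs arm3 =
# [a3_start, a3_end) outermost-first.
exact_stem <- function(psum, a0, L, n) {
  structure(list(psum = psum, diag = n - 1L - psum,
                 a5_start = a0, a5_end = a0 + L,
                 a3_start = psum - (a0 + L - 1L), a3_end = psum - a0 + 1L,
                 L = L),
            class = "exact_stem")
}

# Maximal runs of pairable positions on the diagonal with pair sum S,
# restricted to the triangle where the two arms are separated by at least
# min_loop nt. Matrix with columns a0 (outermost 5' position) and L.
# columns: a0 (outermost 5' position), L
diagonal_runs <- function(pm, S, min_loop) {
  out <- cpp_diag_runs(pm$run, as.integer(S), as.integer(min_loop))
  dimnames(out) <- NULL
  out
}

#' Enumerate exact stems in a pairing matrix
#'
#' Finds every maximal run of consecutive positive cells on any diagonal
#' with run length at least `min_len`, the 5' arm strictly before the 3'
#' arm and at least `min_loop` unpaired nt between them (a base cannot
#' pair with itself or across a sterically impossible terminal loop, so
#' runs are clipped at that triangle boundary). Results are sorted by
#' (diagonal id, 5' start).
#'
#' @param pm A [build_pairing_matrix] result.
#' @param min_len Minimum stem length in base pairs (default 4).
#' @param min_loop Minimum arm separation in nt (default 3).
#' @return List of `exact_stem` objects (possibly empty).
#' @examples
#' pm <- build_pairing_matrix(rna_seq("GGGGAAACCCC"))
#' find_exact_stems(pm, min_len = 4)
#' @export
find_exact_stems <- function(pm, min_len = 4L, min_loop = 3L) {
  stopifnot(inherits(pm, "pairing_matrix"), min_len >= 1)
  m <- cpp_all_stems(pm$run, as.integer(min_len), as.integer(min_loop))
  dimnames(m) <- NULL
  lapply(seq_len(nrow(m)), function(k)
    exact_stem(m[k, 1L], m[k, 2L], m[k, 3L], pm$n))
}

# Total base pairs of a structure-like object (exact stem, non-exact
# stem or hairpin candidate).
n_pairs <- function(x) UseMethod("n_pairs")
#' @export
n_pairs.exact_stem <- function(x) x$L
#' @export
n_pairs.non_exact_stem <- function(x) sum(vapply(x$stems, `[[`, 0L, "L"))
#' @export
n_pairs.hairpin_candidate <- function(x) nrow(x$pairs)

#' Extend an exact stem to a non-exact stem along its diagonal
#'
#' Starting from the seed, neighbouring maximal runs on the same diagonal
#' are absorbed greedily in both directions whenever the unpaired gap `g`
#' between the structure's flanking stem (length L1) and the next run
#' (length L2) is a symmetric internal loop smaller than both stems:
#' `g < min(L1, L2)` (strict, per the rule that symmetric loops must be
#' shorter than the surrounding exact stems). Stops when nothing more can
#' be absorbed; the result always contains the seed.
#'
#' @param pm The matrix the seed was found in.
#' @param seed An `exact_stem` from [find_exact_stems] on `pm`.
#' @param min_loop Minimum arm separation (must match the stem search).
#' @return A `non_exact_stem`: ordered stems (outermost first), the
#'   symmetric loop sizes (nt per side) between consecutive stems, and
#'   the seed.
#' @export
extend_to_non_exact_stem <- function(pm, seed, min_loop = 3L) {
  stopifnot(inherits(pm, "pairing_matrix"), inherits(seed, "exact_stem"))
  n <- pm$n
  runs <- diagonal_runs(pm, seed$psum, min_loop)
  ra <- runs[, 1L]; rl <- runs[, 2L]
  hit <- which(ra == seed$a5_start & rl == seed$L)
  if (!length(hit))
    stop("seed stem does not belong to this matrix/diagonal", call. = FALSE)
  lo <- hi <- hit[1L]
  repeat {
    grew <- FALSE
    if (lo > 1L) {
      g <- ra[lo] - (ra[lo - 1L] + rl[lo - 1L])
      if (g < min(rl[lo - 1L], rl[lo])) { lo <- lo - 1L; grew <- TRUE }
    }
    if (hi < length(ra)) {
      g <- ra[hi + 1L] - (ra[hi] + rl[hi])
      if (g < min(rl[hi], rl[hi + 1L])) { hi <- hi + 1L; grew <- TRUE }
    }
    if (!grew) break
  }
  idx <- lo:hi
  stems <- lapply(idx, function(k) exact_stem(seed$psum, ra[k], rl[k], n))
  loops <- if (length(idx) > 1L)
    ra[idx[-1L]] - (ra[head(idx, -1L)] + rl[head(idx, -1L)])
  else integer()
  structure(list(psum = seed$psum, stems = stems, loops = as.integer(loops),
                 seed = seed),
            class = "non_exact_stem")
}

# --- stage 3: best-first hairpin construction -------------------------------

# One helix: outermost pair (a, b) and length L (pairs (a+t, b-t)).
# `helices` are kept ordered outermost-first; consecutive helices are
# separated by per-arm gaps (g5 on the 5' arm, g3 on the 3' arm).

# Best-first tie-breaks among candidate continuations: higher score,
# then smaller total gap, then smaller |g5-g3|, then 5'-most. Takes
# parallel vectors, returns the winning index.
best_gap_choice <- function(a, g5, g3, score) {
  order(-score, g5 + g3, abs(g5 - g3), a)[1L]
}

#' Build a complete hairpin candidate from a non-exact stem
#'
#' The seed's base pairs are anchored and the structure is extended by a
#' deterministic best-first search: first inward (toward the terminal
#' loop), then outward (toward the hairpin base). At each step every gap
#' combination `(g5, g3)` with `0 <= g5, g3 <= max_shift` is scored as
#' `pairs gained - loop_penalty * (g5 + g3)`; the best positive-score
#' continuation is taken (ties: smaller total gap, then smaller
#' `|g5 - g3|`, then 5'-most). Unequal gaps produce asymmetric internal
#' loops, single-sided gaps produce bulges. New helices are truncated so
#' the terminal loop never drops below `min_loop` nt. When nothing can be
#' added the non-exact stem itself, closed by its terminal loop, is the
#' (degenerate) candidate.
#'
#' @param pm The window's pairing matrix.
#' @param nes A `non_exact_stem` from the same matrix.
#' @param config A [scan_config] (uses `max_shift`, `min_loop`,
#'   `loop_penalty`).
#' @return A `hairpin_candidate`: window interval `[start, end)`,
#'   dot-bracket `structure`, `pairs` matrix, ordered `helices` with
#'   per-arm gaps, `elements` decomposition, `terminal_loop` size, the
#'   seed stem, and the window `offset` in the source sequence.
#' @export
build_hairpin <- function(pm, nes, config = scan_config()) {
  stopifnot(inherits(pm, "pairing_matrix"), inherits(nes, "non_exact_stem"))
  n <- pm$n
  ms <- config$max_shift
  pen <- config$loop_penalty
  ml <- config$min_loop
  S <- nes$psum
  helices <- lapply(nes$stems, function(st)
    list(a = st$a5_start, b = S - st$a5_start, L = st$L,
         g5 = NA_integer_, g3 = NA_integer_))
  for (k in seq_along(nes$loops)) {
    helices[[k + 1L]]$g5 <- nes$loops[k]
    helices[[k + 1L]]$g3 <- nes$loops[k]
  }

  gg5 <- rep(0:ms, times = ms + 1L)
  gg3 <- rep(0:ms, each = ms + 1L)
  gsum <- gg5 + gg3

  # inward extension
  repeat {
    h <- helices[[length(helices)]]
    fa <- h$a + h$L - 1L; fb <- h$b - h$L + 1L
    a <- fa + 1L + gg5
    b <- fb - 1L - gg3
    valid <- b - a - 1L >= ml
    if (!any(valid)) break
    L0 <- integer(length(a))
    L0[valid] <- pm$inward[cbind(n - b[valid], a[valid] + 1L)]
    L <- pmin(L0, pmax(0L, (b - a + 1L - ml) %/% 2L))
    score <- L - pen * gsum
    keep <- which(valid & L >= 1L & score > 0)
    if (!length(keep)) break
    w <- keep[best_gap_choice(a[keep], gg5[keep], gg3[keep], score[keep])]
    helices[[length(helices) + 1L]] <-
      list(a = a[w], b = b[w], L = L[w], g5 = gg5[w], g3 = gg3[w])
  }

  # outward extension
  repeat {
    h <- helices[[1L]]
    a <- h$a - 1L - gg5
    b <- h$b + 1L + gg3
    valid <- a >= 0L & b <= n - 1L
    if (!any(valid)) break
    L0 <- integer(length(a))
    L0[valid] <- pm$run[cbind(n - b[valid], a[valid] + 1L)]
    L <- pmin(L0, pmin(a + 1L, n - b))  # stay inside the window
    score <- L - pen * gsum
    keep <- which(valid & L >= 1L & score > 0)
    if (!length(keep)) break
    w <- keep[best_gap_choice(a[keep], gg5[keep], gg3[keep], score[keep])]
    old <- helices[[1L]]
    old$g5 <- gg5[w]
    old$g3 <- gg3[w]
    # the new outermost helix extends outward from (a, b)
    helices <- c(list(list(a = a[w] - (L[w] - 1L), b = b[w] + (L[w] - 1L),
                           L = L[w], g5 = NA_integer_, g3 = NA_integer_),
                      old),
                 helices[-1L])
  }

  finish_hairpin(pm, helices, nes)
}

# Assemble the candidate object from the final helix chain.
finish_hairpin <- function(pm, helices, nes) {
  h1 <- helices[[1L]]
  hk <- helices[[length(helices)]]
  start <- h1$a
  end <- h1$b + 1L
  pairs <- do.call(rbind, lapply(helices, function(h)
    cbind(a = h$a + seq_len(h$L) - 1L, b = h$b - seq_len(h$L) + 1L)))
  term_loop <- (hk$b - hk$L + 1L) - (hk$a + hk$L - 1L) - 1L

  if (length(helices) > 1L) {
    g5 <- vapply(helices[-1L], `[[`, 0L, "g5")
    g3 <- vapply(helices[-1L], `[[`, 0L, "g3")
    type <- ifelse(g5 == 0L | g3 == 0L,
                   ifelse(g5 > 0L, "bulge_left", "bulge_right"),
                   ifelse(g5 == g3, "symmetric_loop", "asymmetric_loop"))
    elements <- data.frame(type = type, g5 = g5, g3 = g3,
                           stringsAsFactors = FALSE)
  } else {
    elements <- data.frame(type = character(), g5 = integer(),
                           g3 = integer(), stringsAsFactors = FALSE)
  }

  cand <- structure(
    list(start = start, end = end,
         pairs = pairs, helices = helices, elements = elements,
         terminal_loop = term_loop, seed = nes$seed, nes = nes,
         seq = substr(pm$seq$residues, start + 1L, end),
         offset = if (!is.null(pm$seq$origin)) pm$seq$origin$offset else 0L,
         source_id = if (!is.null(pm$seq$origin)) pm$seq$origin$source_id
                     else pm$seq$id),
    class = "hairpin_candidate")
  cand$structure <- to_dot_bracket(cand)
  cand
}

#' Hairpin size filter
#'
#' @param cand A `hairpin_candidate`.
#' @param min_size,max_size Inclusive size bounds in nt (defaults 50 and
#'   150, the usual pre-miRNA range).
#' @return `TRUE` when `min_size <= end - start <= max_size`.
#' @export
filter_by_size <- function(cand, min_size = 50L, max_size = 150L) {
  stopifnot(min_size <= max_size)
  len <- cand$end - cand$start
  len >= min_size && len <= max_size
}

#' Dot-bracket string of a candidate
#'
#' One character per nt over the candidate interval; `(`/`)` for the 5'
#' and 3' partner of each base pair, `.` for unpaired positions (Vienna
#' dialect, no pseudoknots by construction).
#'
#' @param cand A `hairpin_candidate`.
#' @return Character scalar of length `end - start`.
#' @export
to_dot_bracket <- function(cand) {
  len <- cand$end - cand$start
  chars <- rep(".", len)
  if (!is.null(cand$pairs) && nrow(cand$pairs)) {
    a <- cand$pairs[, "a"] - cand$start
    b <- cand$pairs[, "b"] - cand$start
    if (any(a < 0) || any(b >= len) || any(a >= b) ||
        anyDuplicated(c(a, b)))
      stop("inconsistent pairing in candidate", call. = FALSE)
    chars[a + 1L] <- "("
    chars[b + 1L] <- ")"
  }
  paste(chars, collapse = "")
}

#' Parse a dot-bracket string into a pair table
#'
#' @param db Dot-bracket string over `(`, `.`, `)`.
#' @return Integer matrix with columns `a`, `b` (0-based positions,
#'   `a < b`), one row per pair, ordered outermost-first.
#' @export
parse_dot_bracket <- function(db) {
  chars <- strsplit(db, "", fixed = TRUE)[[1L]]
  if (any(!chars %in% c("(", ")", ".")))
    stop("invalid dot-bracket character", call. = FALSE)
  stack <- integer()
  out <- matrix(integer(), ncol = 2, dimnames = list(NULL, c("a", "b")))
  for (k in seq_along(chars)) {
    if (chars[k] == "(") stack <- c(stack, k - 1L)
    else if (chars[k] == ")") {
      if (!length(stack)) stop("unbalanced dot-bracket", call. = FALSE)
      out <- rbind(out, c(stack[length(stack)], k - 1L))
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack)) stop("unbalanced dot-bracket", call. = FALSE)
  out[order(out[, "a"]), , drop = FALSE]
}

# Structure validator used by tests and the scanner: pairs are 0-based,
# strictly nested (single stem-loop chain), mutually consistent, and the
# terminal loop respects min_loop.
validate_candidate <- function(cand, min_loop = 3L) {
  p <- cand$pairs
  if (!nrow(p)) return(TRUE)
  a <- p[, "a"]; b <- p[, "b"]
  stopifnot(all(diff(a) > 0), all(diff(b) < 0), all(a < b),
            !anyDuplicated(c(a, b)),
            min(b) - max(a) - 1L >= min_loop,
            min(a) >= cand$start, max(b) < cand$end)
  sdb <- parse_dot_bracket(cand$structure)
  stopifnot(nrow(sdb) == nrow(p),
            all(sdb[, "a"] == a - cand$start),
            all(sdb[, "b"] == b - cand$start))
  TRUE
}
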