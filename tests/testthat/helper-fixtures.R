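# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

# Brute-force oracle for the pairing matrix: every cell recomputed from
# the definition, independent of the C++ fill.
oracle_matrix <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  n <- length(chars)
  comp <- function(a, b) {
    p <- paste(sort(c(a, b)), collapse = "")
    p %in% c("AU", "CG", "GU")
  }
  m <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (comp(chars[j], chars[n + 1L - i])) {
      up <- if (i > 1L && j > 1L) m[i - 1L, j - 1L] else 0L
      m[i, j] <- up + 1L
    }
  }
  m
}

random_rna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# Exhaustive enumeration oracle for the stage-3 search on toy sequences:
# maximum pair count over all single-hairpin (nested chain) structures
# that contain the seed pairs and obey the same gap, loop and
# score-positivity constraints as build_hairpin.
enumerate_best_pairs <- function(seq, seed_pairs, max_shift = 10L,
                                 min_loop = 3L, loop_penalty = 0.3) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  comp <- function(a, b) {
    p <- paste(sort(c(chars[a + 1L], chars[b + 1L])), collapse = "")
    p %in% c("AU", "CG", "GU")
  }
  best <- 0L
  # grow chains inward then outward from the anchored seed helix
  grow_in <- function(a, b, count) {
    best <<- max(best, count)
    for (g5 in 0:max_shift) for (g3 in 0:max_shift) {
      na <- a + 1L + g5; nb <- b - 1L - g3
      if (nb - na - 1L < min_loop) next
      # any helix length from this entry point
      L <- 0L
      while (comp(na + L, nb - L) && (nb - L) - (na + L) - 1L >= min_loop)
        L <- L + 1L
      for (l in seq_len(L)) {
        if (l - loop_penalty * (g5 + g3) <= 0) next
        grow_in(na + l - 1L, nb - l + 1L, count + l)
      }
    }
  }
  grow_out_then_in <- function(oa, ob, ia, ib, count) {
    grow_in(ia, ib, count)
    for (g5 in 0:max_shift) for (g3 in 0:max_shift) {
      na <- oa - 1L - g5; nb <- ob + 1L + g3
      if (na < 0L || nb > n - 1L) next
      L <- 0L
      while (na - L >= 0L && nb + L <= n - 1L && comp(na - L, nb + L))
        L <- L + 1L
      for (l in seq_len(L)) {
        if (l - loop_penalty * (g5 + g3) <= 0) next
        grow_out_then_in(na - l + 1L, nb + l - 1L, ia, ib, count + l)
      }
    }
  }
  sa <- seed_pairs[, "a"]; sb <- seed_pairs[, "b"]
  grow_out_then_in(min(sa), max(sb), max(sa), min(sb), nrow(seed_pairs))
  best
}

stem_pairs_of <- function(st)
  cbind(a = st$a5_start + seq_len(st$L) - 1L,
        b = st$psum - st$a5_start - seq_len(st$L) + 1L)

# A small trained cascade shared across test files (30 + 30 corpus).
tiny_cascade <- function() {
  if (is.null(.fixture_env$cascade)) {
    corpus <- synthetic_training_corpus(30L, 30L, seed = 7L)
    .fixture_env$corpus <- corpus
    .fixture_env$cascade <- suppressWarnings(
      train_cascade(corpus$positives, corpus$negatives,
                    n_trees = 50L, seed = 7L))
  }
  .fixture_env$cascade
}

tiny_corpus <- function() {
  tiny_cascade()
  .fixture_env$corpus
}

# Candidate structures for a toy sequence via the regular pipeline.
toy_candidates <- function(seq, min_len = 2L) {
  pm <- build_pairing_matrix(rna_seq(seq))
  stems <- find_exact_stems(pm, min_len)
  lapply(stems, function(st)
    build_hairpin(pm, extend_to_non_exact_stem(pm, st)))
}
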