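test_that("exact stem enumeration handles the canonical toy cases", {
  pm0 <- build_pairing_matrix(rna_seq("AAAA"))
  expect_length(find_exact_stems(pm0, 1), 0L)

  pm <- build_pairing_matrix(rna_seq("GGGGAAACCCC"))
  st <- find_exact_stems(pm, 4)
  expect_length(st, 1L)
  expect_identical(st[[1]]$a5_start, 0L)
  expect_identical(st[[1]]$a5_end, 4L)
  expect_identical(st[[1]]$a3_start, 7L)
  expect_identical(st[[1]]$a3_end, 11L)
  expect_identical(st[[1]]$L, 4L)

  expect_length(find_exact_stems(pm, 5), 0L)
})

test_that("arms are separated by at least min_loop and ordered", {
  for (k in 1:40) {
    s <- random_rna(sample(20:60, 1), seed = 3000 + k)
    pm <- build_pairing_matrix(rna_seq(s))
    for (st in find_exact_stems(pm, 3)) {
      expect_identical(st$a5_end - st$a5_start, st$L)
      expect_identical(st$a3_end - st$a3_start, st$L)
      expect_gte(st$a3_start - st$a5_end, 3L)
      # paired position sums are constant along the stem
      expect_identical(st$a5_start + st$a3_end - 1L, st$psum)
    }
  }
})

test_that("lowering min_len never removes an exact stem (monotone gating)", {
  for (k in 1:20) {
    s <- random_rna(80, seed = 4000 + k)
    pm <- build_pairing_matrix(rna_seq(s))
    key <- function(st) sprintf("%d:%d:%d", st$psum, st$a5_start, st$L)
    hi <- vapply(find_exact_stems(pm, 5), key, "")
    lo <- vapply(find_exact_stems(pm, 3), key, "")
    expect_true(all(hi %in% lo))
  }
})

test_that("an implanted perfect stem is always found", {
  for (k in 1:20) {
    hp <- generate_hairpin(stem_len = 22, loop_len = 6, seed = 500 + k)
    pm <- build_pairing_matrix(hp)
    st <- find_exact_stems(pm, 4)
    expect_gte(max(vapply(st, `[[`, 0L, "L")), 22L)
  }
})

test_that("non-exact stem absorption follows the strict symmetric-loop rule", {
  # runs of 5 and 4 bridged by a 2-nt symmetric gap: 2 < min(5,4), absorb
  arm <- "GGGGGCCGGGG"  # 5 G, unpairable CC gap, 4 G on the 5' arm
  s <- paste0(arm, "AAAA", "CCCCAACCCCC")
  pm <- build_pairing_matrix(rna_seq(s))
  seeds <- find_exact_stems(pm, 4)
  seed <- seeds[[which.max(vapply(seeds, `[[`, 0L, "L"))]]
  nes <- extend_to_non_exact_stem(pm, seed)
  expect_length(nes$stems, 2L)
  expect_identical(nes$loops, 2L)
  expect_identical(n_pairs(nes), 9L)

  # gap 4 with flanking stems 4 and 6: 4 is not < 4, do not absorb
  arm2 <- "GGGGCCCCGGGGGG"  # 4 G, unpairable CCCC gap, 6 G
  s2 <- paste0(arm2, "AAAA", "CCCCCCAAAACCCC")
  pm2 <- build_pairing_matrix(rna_seq(s2))
  seeds2 <- find_exact_stems(pm2, 4)
  hit2 <- Filter(function(st) st$L == 4L && st$a5_start == 0L &&
                   st$psum == 31L, seeds2)
  expect_length(hit2, 1L)
  seed4 <- hit2[[1]]
  nes2 <- extend_to_non_exact_stem(pm2, seed4)
  expect_length(nes2$stems, 1L)
  expect_identical(nes2$loops, integer())
  # a single-run diagonal keeps only the seed
  nes3 <- extend_to_non_exact_stem(
    build_pairing_matrix(rna_seq("GGGGAAACCCC")),
    find_exact_stems(build_pairing_matrix(rna_seq("GGGGAAACCCC")), 4)[[1]])
  expect_length(nes3$stems, 1L)
})

test_that("seed/matrix mismatch is rejected", {
  pm1 <- build_pairing_matrix(rna_seq("GGGGAAACCCC"))
  pm2 <- build_pairing_matrix(rna_seq("AAAAAAAAAAA"))
  seed <- find_exact_stems(pm1, 4)[[1]]
  expect_error(extend_to_non_exact_stem(pm2, seed), "seed stem")
})

test_that("perfect hairpin closes into the unique consistent structure", {
  pm <- build_pairing_matrix(rna_seq("GGGGAAACCCC"))
  nes <- extend_to_non_exact_stem(pm, find_exact_stems(pm, 4)[[1]])
  cand <- build_hairpin(pm, nes)
  expect_identical(cand$structure, "((((...))))")
  expect_identical(cand$terminal_loop, 3L)
  expect_identical(cand$start, 0L)
  expect_identical(cand$end, 11L)
  expect_identical(nrow(cand$elements), 0L)
})

test_that("anchoring: output pairs always contain the seed pairs", {
  for (k in 1:25) {
    s <- random_rna(60, seed = 6000 + k)
    pm <- build_pairing_matrix(rna_seq(s))
    stems <- find_exact_stems(pm, 4)
    if (!length(stems)) next
    st <- stems[[1]]
    nes <- extend_to_non_exact_stem(pm, st)
    cand <- build_hairpin(pm, nes)
    seedp <- sprintf("%d:%d", st$a5_start + seq_len(st$L) - 1L,
                     st$psum - st$a5_start - seq_len(st$L) + 1L)
    got <- sprintf("%d:%d", cand$pairs[, "a"], cand$pairs[, "b"])
    expect_true(all(seedp %in% got), info = paste("seed", k))
  }
})

test_that("single-bulge fixture is decomposed and matches the enumeration oracle", {
  cands <- toy_candidates("GGAGGAAACCCC", min_len = 2)
  best <- cands[[which.max(vapply(cands, n_pairs, 0L))]]
  expect_identical(best$structure, "((.((...))))")
  expect_identical(nrow(best$elements), 1L)
  expect_identical(best$elements$type, "bulge_left")
  expect_identical(best$elements$g5, 1L)
  # bracket characters = 2 x pairs
  expect_identical(
    sum(strsplit(best$structure, "")[[1]] %in% c("(", ")")),
    2L * n_pairs(best))
})

test_that("pair count equals the exhaustive enumeration optimum on toy fixtures", {
  fixtures <- c("GGGGAAACCCC",        # perfect
                "GGAGGAAACCCC",       # 1-nt 5' bulge
                "GGGAAAUCCC",         # 3' bulge variant
                "GCGCAAAAGCGC",       # loop-limited
                "GGCAGCAAAGCGCC")     # asymmetric interior
  for (s in fixtures) {
    pm <- build_pairing_matrix(rna_seq(s))
    stems <- find_exact_stems(pm, 2)
    for (st in stems) {
      nes <- extend_to_non_exact_stem(pm, st)
      cand <- build_hairpin(pm, nes)
      opt <- enumerate_best_pairs(s, stem_pairs_of(st))
      expect_identical(n_pairs(cand), opt,
                       info = paste(s, "seed at", st$a5_start))
    }
  }
})

test_that("all search outputs are valid nested structures", {
  for (k in 1:30) {
    s <- random_rna(sample(30:90, 1), seed = 7000 + k)
    for (cand in toy_candidates(s, min_len = 3))
      expect_true(mircascade:::validate_candidate(cand))
  }
})

test_that("degenerate case: the non-exact stem itself is returned when nothing extends", {
  pm <- build_pairing_matrix(rna_seq("GGGGAAACCCC"))
  nes <- extend_to_non_exact_stem(pm, find_exact_stems(pm, 4)[[1]])
  cand <- build_hairpin(pm, nes)
  expect_identical(n_pairs(cand), n_pairs(nes))
})

test_that("size filter is inclusive at both bounds", {
  mk <- function(len) structure(list(start = 0L, end = len),
                                class = "hairpin_candidate")
  expect_true(filter_by_size(mk(100), 50, 150))
  expect_false(filter_by_size(mk(49), 50, 150))
  expect_true(filter_by_size(mk(50), 50, 150))
  expect_true(filter_by_size(mk(150), 50, 150))
  expect_false(filter_by_size(mk(151), 50, 150))
})

test_that("dot-bracket round-trips through the parser", {
  cands <- toy_candidates("GGAGGAAACCCC", min_len = 2)
  for (cand in cands) {
    p <- parse_dot_bracket(cand$structure)
    expect_identical(unname(p[, "a"]), unname(cand$pairs[, "a"] - cand$start))
    expect_identical(unname(p[, "b"]), unname(cand$pairs[, "b"] - cand$start))
  }
  expect_identical(nrow(parse_dot_bracket("....")), 0L)
  expect_error(parse_dot_bracket("(()"), "unbalanced")
  expect_error(parse_dot_bracket("())"), "unbalanced")
  expect_error(parse_dot_bracket("(x)"), "invalid")
})

test_that("per-window search time scales no worse than ~cubically", {
  time_windows <- function(m, seeds) {
    # enough repetitions that each measurement is well above clock noise
    t0 <- proc.time()[["elapsed"]]
    for (sd in seeds) {
      s <- random_rna(m, seed = sd)
      pm <- build_pairing_matrix(rna_seq(s))
      stems <- find_exact_stems(pm, 4)
      for (st in stems)
        build_hairpin(pm, extend_to_non_exact_stem(pm, st))
    }
    proc.time()[["elapsed"]] - t0
  }
  seeds <- 8000 + 1:8
  time_windows(60, seeds[1:2])  # warm-up
  t1 <- time_windows(60, seeds)
  t2 <- time_windows(120, seeds)
  expect_lt(t2 / max(t1, 0.02), 10)
})
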