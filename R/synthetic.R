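# Derive a sub-seed from a base seed and an index, kept inside 32-bit
# integer range so set.seed never overflows.
mix_seed <- function(seed, salt, k = 0L)
  as.integer((as.numeric(seed) * 7919 + salt * 104729 + k) %% 2147483629)

sample_nt <- function(n, gc = 0.5) {
  sample(NT_ALPHABET, n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

#' Generate a synthetic hairpin sequence
#'
#' Emits `arm5 + loop + reverse_complement(arm5)` and then degrades the
#' ideal hairpin per the spec: a chosen fraction of stem pairs is turned
#' into G:U wobbles, unpaired bulge nucleotides are inserted into a
#' random arm, and every position is mutated independently at the given
#' rate. Deterministic per seed. The intended (pre-degradation) geometry
#' is attached as attribute `"intended"`.
#'
#' @param stem_len Stem length in base pairs.
#' @param loop_len Terminal loop length in nt (>= 3).
#' @param bulge_sizes Integer vector of bulge sizes to insert (each on a
#'   randomly chosen arm at a random interior position).
#' @param gu_fraction Fraction of stem pairs converted to G:U wobbles.
#' @param mutation_rate Per-position probability of a random substitution.
#' @param gc GC content of the random arm and loop.
#' @param seed Integer seed.
#' @param id Record id.
#' @return An [rna_seq].
#' @export
generate_hairpin <- function(stem_len, loop_len = 8L, bulge_sizes = integer(),
                             gu_fraction = 0, mutation_rate = 0, gc = 0.5,
                             seed = 1L, id = NULL) {
  stopifnot(stem_len >= 1L, loop_len >= 3L,
            gu_fraction >= 0, gu_fraction <= 1,
            mutation_rate >= 0, mutation_rate <= 1)
  bulge_sizes <- as.integer(bulge_sizes)
  if (any(bulge_sizes < 1L) || length(bulge_sizes) > max(0L, stem_len - 2L))
    stop("invalid hairpin spec: bulges exceed the stem", call. = FALSE)
  with_seed(seed, {
    arm5 <- sample_nt(stem_len, gc)
    n_gu <- round(gu_fraction * stem_len)
    if (n_gu > 0L) {
      at <- sample.int(stem_len, n_gu)
      arm5[at] <- "G"
    }
    arm3 <- rev(strsplit(chartr("ACGU", "UGCA",
                                paste(arm5, collapse = "")),
                         "", fixed = TRUE)[[1L]])
    if (n_gu > 0L) arm3[stem_len + 1L - at] <- "U"   # G:C or G:? -> G:U
    loop <- sample_nt(loop_len, gc)
    # bulges: unpaired insertions on one arm only
    for (bs in bulge_sizes) {
      side <- sample(c("5", "3"), 1L)
      ins <- sample_nt(bs, gc)
      if (side == "5") {
        at5 <- sample.int(length(arm5) - 1L, 1L)
        arm5 <- append(arm5, ins, after = at5)
      } else {
        at3 <- sample.int(length(arm3) - 1L, 1L)
        arm3 <- append(arm3, ins, after = at3)
      }
    }
    chars <- c(arm5, loop, arm3)
    if (mutation_rate > 0) {
      hit <- which(runif(length(chars)) < mutation_rate)
      for (h in hit)
        chars[h] <- sample(setdiff(NT_ALPHABET, chars[h]), 1L)
    }
    out <- rna_seq(paste(chars, collapse = ""),
                   id = if (is.null(id))
                     sprintf("hairpin_s%d_l%d_seed%d", stem_len, loop_len,
                             seed)
                   else id)
    attr(out, "intended") <- list(stem_len = stem_len, loop_len = loop_len,
                                  bulge_sizes = bulge_sizes,
                                  gu_fraction = gu_fraction,
                                  mutation_rate = mutation_rate, seed = seed)
    out
  })
}

#' Generate an i.i.d. background sequence
#'
#' @param length Sequence length in nt (>= 1).
#' @param gc GC fraction in [0, 1].
#' @param seed Integer seed.
#' @param id Record id.
#' @return An [rna_seq].
#' @export
generate_negative <- function(length, gc = 0.5, seed = 1L, id = NULL) {
  if (gc < 0 || gc > 1) stop("invalid spec: gc must be in [0,1]",
                             call. = FALSE)
  stopifnot(length >= 1L)
  with_seed(seed,
    rna_seq(paste(sample_nt(length, gc), collapse = ""),
            id = if (is.null(id)) sprintf("background_%d_seed%d",
                                          length, seed) else id))
}

#' Dinucleotide-preserving shuffle
#'
#' Altschul-Erickson shuffle: returns a random sequence with exactly the
#' same dinucleotide (hence mononucleotide) counts, the canonical way to
#' build structured-sequence negatives that keep local composition.
#'
#' @param seq An [rna_seq] or string.
#' @param seed Integer seed.
#' @return An [rna_seq].
#' @export
dinucleotide_shuffle <- function(seq, seed = 1L) {
  id <- if (inherits(seq, "rna_seq")) paste0(seq$id, "_shuf") else "shuffled"
  chars <- nt_chars(seq)
  n <- length(chars)
  if (n < 3L) return(rna_seq(paste(chars, collapse = ""), id = id))
  with_seed(seed, {
    verts <- unique(chars)
    edges <- lapply(setNames(verts, verts),
                    function(v) chars[which(chars[-n] == v) + 1L])
    last <- chars[n]
    repeat {
      # pick a candidate last edge per non-terminal vertex; accept when
      # the last-edge graph converges to the terminal vertex
      pick <- vapply(verts, function(v) {
        if (v == last) NA_character_
        else { e <- edges[[v]]; e[sample.int(length(e), 1L)] }
      }, "")
      ok <- TRUE
      for (v in setdiff(verts, last)) {
        cur <- v; seen <- character()
        while (!is.na(pick[cur]) && !(cur %in% seen) && cur != last) {
          seen <- c(seen, cur); cur <- pick[cur]
        }
        if (cur != last) { ok <- FALSE; break }
      }
      if (ok) break
    }
    shuffled <- lapply(setNames(verts, verts), function(v) {
      e <- edges[[v]]
      if (!is.na(pick[v])) {
        drop <- which(e == pick[v])[1L]
        e <- e[-drop]
      }
      c(if (length(e)) e[sample.int(length(e))], pick[v])
    })
    ptr <- setNames(rep(1L, length(verts)), verts)
    out <- character(n)
    out[1L] <- chars[1L]
    cur <- chars[1L]
    for (k in 2:n) {
      nxt <- shuffled[[cur]][ptr[cur]]
      ptr[cur] <- ptr[cur] + 1L
      out[k] <- nxt
      cur <- nxt
    }
    rna_seq(paste(out, collapse = ""), id = id)
  })
}

#' Implant synthetic hairpins into a background genome
#'
#' Generates an i.i.d. background of the requested length and overwrites
#' it at random, non-overlapping positions (pairwise gaps and distance
#' from the ends of at least `spacing` nt) with hairpins generated from
#' the given specs. Deterministic per seed.
#'
#' @param genome_length Total genome length (nt).
#' @param specs List of argument lists for [generate_hairpin] (field
#'   `seed` is derived from `seed` when absent).
#' @param seed Integer seed.
#' @param gc Background GC fraction.
#' @param spacing Minimum gap between implants and to the ends (nt).
#' @return A `synthetic_genome`: `seq` (an [rna_seq]), `truth` (data
#'   frame `seqid`, `start`, `end`, `name`, 0-based half-open), `seed`.
#' @export
implant <- function(genome_length, specs, seed = 1L, gc = 0.5,
                    spacing = 50L) {
  hairpins <- lapply(seq_along(specs), function(k) {
    args <- specs[[k]]
    if (is.null(args$seed)) args$seed <- mix_seed(seed, 11L, k)
    if (is.null(args$id)) args$id <- sprintf("implant_%02d", k)
    do.call(generate_hairpin, args)
  })
  lens <- vapply(hairpins, `[[`, 0L, "n")
  k <- length(hairpins)
  free <- genome_length - sum(lens) - spacing * (k + 1L)
  if (k > 0L && free < 0L)
    stop("placement error: hairpins do not fit with ", spacing,
         "-nt spacing", call. = FALSE)
  with_seed(seed, {
    chars <- sample_nt(genome_length, gc)
    starts <- integer(0)
    if (k > 0L) {
      cuts <- sort(sample.int(free + 1L, k, replace = TRUE) - 1L)
      starts <- spacing + cuts + cumsum(c(0L, head(lens, -1L) + spacing))
    }
    truth <- data.frame(seqid = rep("synthetic_genome", k),
                        start = integer(k), end = integer(k),
                        name = vapply(hairpins, `[[`, "", "id"),
                        stringsAsFactors = FALSE)
    for (j in seq_len(k)) {
      truth$start[j] <- starts[j]
      truth$end[j] <- starts[j] + lens[j]
      chars[(starts[j] + 1L):(starts[j] + lens[j])] <-
        nt_chars(hairpins[[j]])
    }
    structure(list(seq = rna_seq(paste(chars, collapse = ""),
                                 id = "synthetic_genome"),
                   truth = truth, seed = as.integer(seed)),
              class = "synthetic_genome")
  })
}

#' Write truth intervals as BED6
#'
#' @param truth Truth data frame from [implant].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_bed <- function(truth, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = truth$seqid,
    ranges = IRanges::IRanges(start = truth$start + 1L, end = truth$end),
    strand = "+")
  gr$name <- truth$name
  gr$score <- 0L
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Build a synthetic training corpus
#'
#' Positives are hairpins with randomized stem/loop geometry and mild
#' degradation; negatives mix dinucleotide-preserving shuffles of the
#' positives (structured but not hairpin-like) with i.i.d. background,
#' mirroring the usual ncRNA/pseudo-hairpin negative mix in spirit.
#'
#' @param n_pos,n_neg Class sizes.
#' @param seed Integer seed.
#' @return List with `positives` and `negatives` (lists of [rna_seq]).
#' @export
synthetic_training_corpus <- function(n_pos = 100L, n_neg = 100L,
                                      seed = 1L) {
  pos <- lapply(seq_len(n_pos), function(k)
    with_seed(mix_seed(seed, 1L, k), {
      stem <- sample(22:45, 1L)
      loop <- sample(4:12, 1L)
      nb <- sample(0:2, 1L)
      generate_hairpin(stem_len = stem, loop_len = loop,
                       bulge_sizes = if (nb) sample(1:2, nb, replace = TRUE)
                                     else integer(),
                       gu_fraction = runif(1L, 0, 0.15),
                       mutation_rate = runif(1L, 0, 0.05),
                       seed = mix_seed(seed, 2L, k),
                       id = sprintf("pos_%03d", k))
    }))
  neg <- lapply(seq_len(n_neg), function(k) {
    if (k %% 2L == 0L) {
      src <- pos[[((k - 1L) %% length(pos)) + 1L]]
      out <- dinucleotide_shuffle(src, seed = mix_seed(seed, 3L, k))
      out$id <- sprintf("neg_%03d", k)
      out
    } else
      generate_negative(with_seed(mix_seed(seed, 4L, k),
                                  sample(60:140, 1L)),
                        gc = 0.5, seed = mix_seed(seed, 5L, k),
                        id = sprintf("neg_%03d", k))
  })
  list(positives = pos, negatives = neg)
}
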