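# 4x4 lookup of pair classes by nucleotide code (A,C,G,U order);
# rank 3 = GC, 2 = AU, 1 = GU, 0 = unpairable.
PAIR_RANK <- matrix(0L, 4L, 4L, dimnames = list(NT_ALPHABET, NT_ALPHABET))
PAIR_RANK["C", "G"] <- PAIR_RANK["G", "C"] <- 3L
PAIR_RANK["A", "U"] <- PAIR_RANK["U", "A"] <- 2L
PAIR_RANK["G", "U"] <- PAIR_RANK["U", "G"] <- 1L

pair_rank <- function(x, y)
  PAIR_RANK[cbind(match(x, NT_ALPHABET), match(y, NT_ALPHABET))]

pair_class <- function(x, y)
  c("none", "GU", "AU", "GC")[pair_rank(x, y) + 1L]

#' Stacking-count energy backend
#'
#' A dependency-free thermodynamic stand-in: each stack of two adjacent
#' base pairs contributes -2 kcal/mol when a G:C pair is involved,
#' -1 when an A:U pair (and no G:C) is involved, and -0.5 when both pairs
#' are G:U wobbles. `fold_mfe()` minimizes total energy over all nested
#' structures (per-pair energies GC -2, AU -1, GU -0.5, terminal loops of
#' at least 3 nt) by dynamic programming. Energies are always <= 0 and
#' exactly 0 when no pair is possible. An adapter wrapping an external
#' thermodynamic folder can replace this backend: any list with the same
#' two functions satisfies the contract, and swapping backends changes
#' only the energy-derived features (deltaG, adjusted MFE, MFE1, MFE2).
#'
#' @return An `energy_backend` list with functions
#'   `duplex_energy(arm5, arm3)` (kcal/mol for two antiparallel,
#'   fully-paired arms; positions that cannot pair break the stacks) and
#'   `fold_mfe(seq)` (kcal/mol for the best nested structure).
#' @examples
#' be <- stacking_energy_backend()
#' be$duplex_energy("GGGG", "CCCC")
#' @export
stacking_energy_backend <- function() {
  duplex <- function(arm5, arm3) {
    x <- nt_chars(arm5)
    y <- rev(nt_chars(arm3))
    L <- min(length(x), length(y))
    if (L < 2L) return(0)
    rk <- pair_rank(x[seq_len(L)], y[seq_len(L)])
    r1 <- rk[-L]; r2 <- rk[-1L]
    both <- r1 > 0L & r2 > 0L
    sum(c(0, -0.5, -1, -2)[pmax(r1, r2)[both] + 1L])
  }
  fold <- function(seq) cpp_fold_mfe(nt_codes(seq), 3L)
  structure(list(name = "stacking", duplex_energy = duplex, fold_mfe = fold),
            class = "energy_backend")
}

# deltaG of a pair chain: sum of duplex energies of its exact helices.
helices_energy <- function(backend, chars, helices) {
  e <- 0
  for (h in helices) {
    a5 <- paste(chars[h$a + seq_len(h$L)], collapse = "")
    a3 <- paste(chars[h$b - h$L + 1L + seq_len(h$L)], collapse = "")
    e <- e + backend$duplex_energy(a5, a3)
  }
  e
}
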