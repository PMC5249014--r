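#' Test base complementarity
#'
#' Watson-Crick pairs plus the G:U wobble, the pair set used throughout
#' the hairpin search (wobble pairs are needed for the "percentage of GU
#' pairing" feature to be meaningful).
#'
#' @param a,b Single nucleotide characters in `A/C/G/U`.
#' @return Logical scalar; symmetric in its arguments.
#' @examples
#' is_complementary("G", "C")
#' is_complementary("G", "U")
#' @export
is_complementary <- function(a, b) {
  if (!is.character(a) || !is.character(b) ||
      any(!c(a, b) %in% NT_ALPHABET))
    stop("nucleotides must be single characters in {A,C,G,U}", call. = FALSE)
  key <- paste(pmin(a, b), pmax(a, b))
  key %in% c("A U", "C G", "G U")
}

#' Build the triangular base-pairing matrix of a window
#'
#' For a window sequence `s[0..n-1]`, column `j` represents `s[j]` and row
#' `i` represents `s[n-1-i]`. A cell is zero when the two bases cannot
#' pair; otherwise it extends the run of its up-left neighbour by one, so
#' positive values measure the length of the contiguous paired region
#' ending at the cell along its diagonal. Runs of positive cells on one
#' diagonal are exactly the exact stems the stage-1 search enumerates.
#'
#' @param seq An [rna_seq] window (or a plain string, normalized on the
#'   fly).
#' @return Object of class `pairing_matrix` with fields `n`, `run` (the
#'   matrix described above), `inward` (companion matrix counting the run
#'   continuing toward the terminal loop, used by the stage-3 search),
#'   `codes` (integer-encoded residues) and `seq`.
#' @examples
#' pm <- build_pairing_matrix(rna_seq("GGGGAAACCCC"))
#' diag(pm$run)[1:4]   # the 4-bp stem accumulates 1,2,3,4
#' @export
build_pairing_matrix <- function(seq) {
  if (!inherits(seq, "rna_seq")) seq <- rna_seq(seq)
  codes <- nt_codes(seq)
  mats <- cpp_pairing_runs(codes)
  structure(list(n = seq$n, run = mats$run, inward = mats$inward,
                 codes = codes, seq = seq),
            class = "pairing_matrix")
}

#' @export
print.pairing_matrix <- function(x, ...) {
  cat(sprintf("<pairing_matrix> %d x %d for %s\n", x$n, x$n, x$seq$id))
  invisible(x)
}

# Value of cell (i, j) in 0-based matrix coordinates; used by tests and
# the brute-force oracle comparisons.
pm_cell <- function(pm, i, j) pm$run[i + 1L, j + 1L]

# Length of the contiguous paired run starting at sequence pair (a, b),
# 0-based, stepping inward (a+1, b-1). 0 when a and b cannot pair.
inward_run <- function(pm, a, b) {
  i <- pm$n - 1L - b
  pm$inward[i + 1L, a + 1L]
}

pair_ok <- function(pm, a, b) inward_run(pm, a, b) > 0L
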