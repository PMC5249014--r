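#' Construct a normalized RNA sequence record
#'
#' Wraps a nucleotide string together with an identifier and optional
#' provenance. DNA input is accepted: the sequence is upper-cased and
#' `T` is mapped to `U`. Any residue outside `A/C/G/U` after
#' normalization (IUPAC ambiguity codes included) is rejected with an
#' error naming the record and the offending position.
#'
#' @param residues Character scalar of nucleotides (`A/C/G/U/T`, any case).
#' @param id Text label for the record.
#' @param origin Optional list with `source_id`, `offset` (0-based start in
#'   the source sequence) and `strand`, recorded when a window is cut out of
#'   a longer sequence.
#' @return An object of class `rna_seq` with fields `id`, `residues`
#'   (normalized string), `n` (length in nt) and `origin`.
#' @examples
#' rna_seq("GGGGAAACCCC", id = "toy")
#' @export
rna_seq <- function(residues, id = "seq", origin = NULL) {
  if (!is.character(residues) || length(residues) != 1L || is.na(residues))
    stop("`residues` must be a single character string", call. = FALSE)
  res <- chartr("t", "u", chartr("T", "U", toupper(residues)))
  if (nchar(res) < 1L)
    stop("empty sequence in record '", id, "'", call. = FALSE)
  chars <- strsplit(res, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% NT_ALPHABET)
  if (length(bad))
    stop("record '", id, "': invalid residue '", chars[bad[1L]],
         "' at position ", bad[1L], " (IUPAC ambiguity codes and gaps ",
         "are not supported)", call. = FALSE)
  structure(list(id = id, residues = res, n = nchar(res), origin = origin),
            class = "rna_seq")
}

#' @export
print.rna_seq <- function(x, ...) {
  shown <- if (x$n > 60L) paste0(substr(x$residues, 1L, 57L), "...")
           else x$residues
  cat(sprintf("<rna_seq> %s (%d nt)\n  %s\n", x$id, x$n, shown))
  invisible(x)
}

# integer codes 0=A 1=C 2=G 3=U for the C++ kernels
nt_codes <- function(seq) {
  if (inherits(seq, "rna_seq")) seq <- seq$residues
  match(strsplit(seq, "", fixed = TRUE)[[1L]], NT_ALPHABET) - 1L
}

nt_chars <- function(seq) {
  if (inherits(seq, "rna_seq")) seq <- seq$residues
  if (length(seq) > 1L) return(seq)   # already a character vector
  strsplit(seq, "", fixed = TRUE)[[1L]]
}

#' Reverse complement of an RNA string
#'
#' @param seq Character scalar or `rna_seq`.
#' @return Character scalar (RNA alphabet).
#' @export
reverse_complement <- function(seq) {
  if (inherits(seq, "rna_seq")) seq <- seq$residues
  paste(rev(strsplit(chartr("ACGU", "UGCA", seq), "", fixed = TRUE)[[1L]]),
        collapse = "")
}

#' Read sequences from a FASTA file
#'
#' Multi-record and gzip-transparent (via [Biostrings::readBStringSet]).
#' Records are normalized to the RNA alphabet; ambiguity codes raise an
#' error naming the record and position.
#'
#' @param path Path to a (possibly gzipped) FASTA file.
#' @return List of [rna_seq] records.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  out <- vector("list", length(set))
  for (k in seq_along(set))
    out[[k]] <- rna_seq(as.character(set[[k]]), id = ids[k])
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs List of [rna_seq] records (or a single record).
#' @param path Output path.
#' @param structures Optional character vector of dot-bracket strings, one
#'   per record; when given, each record is written as two lines (sequence,
#'   structure) after its header, the usual structure-FASTA convention.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, structures = NULL) {
  if (inherits(seqs, "rna_seq")) seqs <- list(seqs)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(seqs)) {
    writeLines(paste0(">", seqs[[k]]$id), con)
    writeLines(seqs[[k]]$residues, con)
    if (!is.null(structures)) writeLines(structures[[k]], con)
  }
  invisible(path)
}

# Cut a window [start, start+width) (0-based) out of a source record.
window_seq <- function(seq, start, width) {
  rna_seq(substr(seq$residues, start + 1L, start + width),
          id = sprintf("%s:%d-%d", seq$id, start, start + width),
          origin = list(source_id = seq$id, offset = start, strand = "+"))
}
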