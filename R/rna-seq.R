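#' RNA sequence with a native coordinate offset
#'
#' Container for a single RNA sequence over the alphabet `A`, `C`, `G`, `U`
#' plus `0` for an abasic residue (intact backbone, no base; used in probe
#' designs that delete N-site bases).  The `offset` records the native
#' 1-based coordinate of the first residue so that matches on an excised
#' oligonucleotide can be reported in full-length numbering, and so that
#' mRNA 5' windows can carry negative UTR coordinates.  mRNA-style numbering
#' has no position 0: with a negative offset, -1 is directly adjacent to +1
#' (see [to_native()]).
#'
#' DNA input is normalised silently: `T`/`t` become `U`, case is folded to
#' upper.  Any other character is rejected.
#'
#' @param id Sequence identifier (non-empty string).
#' @param residues Residue string; normalised as described above.
#' @param offset Native coordinate of the first residue (default 1).
#'   May be negative (not below -10000) for UTR numbering; never 0.
#' @return An object of class `rna_seq`: a list with elements `id`,
#'   `residues` and `offset`.
#' @examples
#' s <- rna_seq("oxyS_arn", "UCAACUCGAAUAACUAAAGCCAACGUGAAC", offset = 57)
#' to_native(s, 3)  # 59
#' @seealso [read_fasta()], [to_native()]
#' @export
rna_seq <- function(id, residues, offset = 1L) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("'id' must be a non-empty string")
  if (!is.character(residues) || length(residues) != 1L || !nzchar(residues))
    stop("sequence '", id, "': residues must be a non-empty string")
  residues <- normalize_residues(residues, id = id)
  offset <- as.integer(offset)
  if (is.na(offset) || offset == 0L || offset < -10000L)
    stop("sequence '", id, "': offset must be a non-zero integer >= -10000")
  structure(list(id = id, residues = residues, offset = offset),
            class = "rna_seq")
}

RNA_ALPHABET <- c("A", "C", "G", "U", "0")

# Uppercase, T->U; reject anything outside {A,C,G,U,0}, naming the position.
normalize_residues <- function(residues, id = "?") {
  x <- toupper(residues)
  x <- chartr("T", "U", x)
  chars <- strsplit(x, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% RNA_ALPHABET)
  if (length(bad))
    stop("sequence '", id, "': illegal character '", chars[bad[1L]],
         "' at position ", bad[1L], call. = FALSE)
  x
}

#' @export
print.rna_seq <- function(x, ...) {
  n <- nchar(x$residues)
  shown <- if (n > 60) paste0(substr(x$residues, 1, 57), "...") else x$residues
  cat(sprintf("<rna_seq> %s  (%d nt, offset %d)\n  %s\n",
              x$id, n, x$offset, shown))
  invisible(x)
}

#' @export
length.rna_seq <- function(x) nchar(x$residues)

seq_chars <- function(seq) strsplit(seq$residues, "", fixed = TRUE)[[1L]]

#' Convert a local position to native numbering
#'
#' Maps a 1-based position within the stored residues to the sequence's
#' native coordinate system.  For non-negative offsets this is plain
#' arithmetic (`offset + local_pos - 1`).  When the offset is negative the
#' numbering follows the mRNA convention in which position 0 does not
#' exist, so crossing the origin adds 1 (e.g. a 19-nt window starting at
#' -14 ends at +5, not +4).
#'
#' @param seq An [rna_seq()] object.
#' @param local_pos Integer vector of 1-based positions within the sequence.
#' @return Integer vector of native coordinates (never 0).
#' @examples
#' to_native(rna_seq("x", "AAAA", offset = -2), 1:4)  # -2 -1  1  2
#' @export
to_native <- function(seq, local_pos) {
  stopifnot(inherits(seq, "rna_seq"))
  local_pos <- as.integer(local_pos)
  if (any(is.na(local_pos)) || any(local_pos < 1L) ||
      any(local_pos > nchar(seq$residues)))
    stop("local_pos out of range for sequence '", seq$id, "'")
  raw <- seq$offset + local_pos - 1L
  ifelse(seq$offset < 0L & raw >= 0L, raw + 1L, raw)
}

#' Convert a native coordinate back to a local position
#'
#' Inverse of [to_native()]: honours the missing position 0 for
#' negative-offset (mRNA window) sequences.
#'
#' @inheritParams to_native
#' @param native_pos Integer vector of native coordinates.
#' @return Integer vector of 1-based local positions.
#' @export
to_local <- function(seq, native_pos) {
  stopifnot(inherits(seq, "rna_seq"))
  native_pos <- as.integer(native_pos)
  if (any(native_pos == 0L))
    stop("native position 0 does not exist")
  raw <- ifelse(seq$offset < 0L & native_pos > 0L, native_pos - 1L, native_pos)
  local <- raw - seq$offset + 1L
  if (any(local < 1L) || any(local > nchar(seq$residues)))
    stop("native position out of range for sequence '", seq$id, "'")
  local
}

#' Number of positions strictly between two native coordinates
#'
#' Counts the residues between `a` and `b` (exclusive) on a coordinate line
#' that skips 0, the convention used for mRNA 5' windows where -1 abuts +1.
#'
#' @param a,b Native coordinates, `a < b`, neither 0.
#' @return Integer count of intervening positions.
#' @examples
#' native_gap(-55, -10)  # 44
#' native_gap(-3, 2)     # 3  (-2, -1, +1)
#' @export
native_gap <- function(a, b) {
  a <- as.integer(a); b <- as.integer(b)
  stopifnot(length(a) == length(b), all(a != 0L), all(b != 0L), all(a < b))
  b - a - 1L - as.integer(a < 0L & b > 0L)
}

WC_PAIR <- c(A = "U", U = "A", G = "C", C = "G", `0` = NA_character_)

#' Reverse complement of an RNA residue string
#'
#' Watson-Crick complement (A:U, G:C), reversed.  The abasic residue `0`
#' has no complement and is preserved as `0`.
#'
#' @param residues Residue string over the package alphabet.
#' @return The reverse-complemented string.
#' @export
reverse_complement <- function(residues) {
  chars <- rev(strsplit(toupper(residues), "", fixed = TRUE)[[1L]])
  out <- WC_PAIR[chars]
  out[is.na(out)] <- "0"
  paste0(out, collapse = "")
}
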