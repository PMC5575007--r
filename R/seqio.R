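#' Read sequences from a FASTA file
#'
#' Parses a (possibly multi-record) FASTA file into a list of [rna_seq()]
#' objects.  Sequences are normalised on input: case is folded to upper,
#' `T` becomes `U`, the abasic marker `0` is preserved, and any other
#' character raises an error naming the offending position.  An optional
#' header token `offset=<int>` sets the native coordinate of the first
#' residue, so that an excised oligonucleotide reports matches in
#' full-length numbering:
#'
#' ```
#' >oxyS_arn offset=57
#' UCAACUCGAAUAACUAAAGCCAACGUGAAC
#' ```
#'
#' @param path Path to a FASTA file.
#' @return Named list of `rna_seq` objects (names are the sequence ids).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e)
                    stop("malformed FASTA '", path, "': ", conditionMessage(e),
                         call. = FALSE))
  if (length(set) == 0L) stop("no sequences in FASTA '", path, "'")
  headers <- names(set)
  out <- vector("list", length(set))
  ids <- character(length(set))
  for (i in seq_along(set)) {
    fields <- strsplit(trimws(headers[i]), "\\s+")[[1L]]
    id <- fields[1L]
    if (is.na(id) || !nzchar(id))
      stop("malformed FASTA '", path, "': record ", i, " has an empty id")
    offset <- 1L
    tok <- grep("^offset=", fields[-1L], value = TRUE)
    if (length(tok)) {
      offset <- suppressWarnings(as.integer(sub("^offset=", "", tok[1L])))
      if (is.na(offset))
        stop("sequence '", id, "': unparseable offset token '", tok[1L], "'")
    }
    out[[i]] <- rna_seq(id, as.character(set[[i]]), offset = offset)
    ids[i] <- id
  }
  names(out) <- ids
  out
}

#' Write sequences to a FASTA file
#'
#' Inverse of [read_fasta()]; offsets other than 1 are recorded as an
#' `offset=<int>` header token so that a read/write round trip is lossless
#' on normalised sequences.
#'
#' @param seqs A single `rna_seq` or a list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  seqs <- as_seq_list(seqs)
  headers <- vapply(seqs, function(s)
    if (s$offset == 1L) s$id else sprintf("%s offset=%d", s$id, s$offset),
    character(1))
  set <- Biostrings::BStringSet(vapply(seqs, `[[`, character(1), "residues"))
  names(set) <- headers
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

as_seq_list <- function(seqs) {
  if (inherits(seqs, "rna_seq")) seqs <- list(seqs)
  if (!length(seqs) || !all(vapply(seqs, inherits, logical(1), "rna_seq")))
    stop("expected an rna_seq or a list of rna_seq objects")
  seqs
}

#' Read a multiple sequence alignment
#'
#' Reads an alignment of sRNA homologs from aligned FASTA or Clustal
#' format.  Rows are normalised like sequences (upper case, `T` to `U`);
#' the gap character is `-`.
#'
#' @param path Path to the alignment file.
#' @param format `"fasta"` (aligned FASTA) or `"clustal"`.
#' @return An object of class `rna_alignment`: list with `ids` (character)
#'   and `rows` (character vector of equal-length gapped sequences).
#' @export
read_alignment <- function(path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (format == "fasta") {
    set <- Biostrings::readBStringSet(path)
    ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
    rows <- as.character(set)
  } else {
    aln <- seqinr::read.alignment(path, format = "clustal")
    ids <- aln$nam
    rows <- unlist(aln$seq, use.names = FALSE)
  }
  rna_alignment(ids, rows)
}

#' Construct an alignment object
#'
#' @param ids Row identifiers.
#' @param rows Gapped residue strings, all the same length, gap `-`.
#' @return An `rna_alignment` object.
#' @export
rna_alignment <- function(ids, rows) {
  stopifnot(length(ids) == length(rows), length(rows) >= 1L)
  rows <- unname(toupper(rows))
  rows <- chartr("T", "U", rows)
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L)
    stop("alignment rows differ in length")
  ok <- grepl("^[ACGU0.-]*$", rows)
  if (!all(ok))
    stop("alignment row '", ids[which(!ok)[1L]], "' has illegal characters")
  rows <- gsub(".", "-", rows, fixed = TRUE)
  structure(list(ids = as.character(ids), rows = rows),
            class = "rna_alignment")
}

#' @export
print.rna_alignment <- function(x, ...) {
  cat(sprintf("<rna_alignment> %d rows x %d columns\n",
              length(x$rows), nchar(x$rows[1L])))
  invisible(x)
}

#' Read Vienna dot-bracket structures
#'
#' Parses a Vienna-style file of records `>id` followed by an optional
#' sequence line and one structure line over `(`, `)` and `.`.  Brackets
#' must balance.
#'
#' @param path Path to the dot-bracket file.
#' @return Named list of `dot_bracket` objects.
#' @export
read_dotbracket <- function(path) {
  if (!file.exists(path)) stop("structure file not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!startsWith(lines[i], ">"))
      stop("dot-bracket parse error at line ", i, ": expected '>' header")
    id <- strsplit(sub("^>", "", lines[i]), "\\s+")[[1L]][1L]
    i <- i + 1L
    struct <- NULL
    while (i <= length(lines) && !startsWith(lines[i], ">")) {
      if (grepl("^[().]+$", lines[i])) { struct <- lines[i]; }
      else if (!grepl("^[ACGUTacgut0]+$", lines[i]))
        stop("dot-bracket parse error at line ", i)
      i <- i + 1L
    }
    if (is.null(struct))
      stop("no structure line for record '", id, "'")
    out[[id]] <- dot_bracket(id, struct)
  }
  out
}

#' Construct a dot-bracket structure object
#'
#' @param seq_id Identifier of the sequence the structure belongs to.
#' @param brackets String over `(`, `)`, `.`; parentheses must balance.
#' @return A `dot_bracket` object.
#' @export
dot_bracket <- function(seq_id, brackets) {
  stopifnot(is.character(brackets), length(brackets) == 1L)
  if (!grepl("^[().]*$", brackets))
    stop("structure contains characters other than '(', ')', '.'")
  depth <- 0L
  for (ch in strsplit(brackets, "", fixed = TRUE)[[1L]]) {
    if (ch == "(") depth <- depth + 1L
    else if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("unbalanced structure: ')' without '('")
    }
  }
  if (depth != 0L) stop("unbalanced structure: ", depth, " unclosed '('")
  structure(list(seq_id = seq_id, brackets = brackets),
            class = "dot_bracket")
}

#' Write motif regions to TSV or BED
#'
#' TSV output has columns `seq_id`, `start`, `end`, `n_arn`,
#' `n_nonfunctional`, `n_gaps` with 1-based inclusive coordinates (the
#' convention used throughout the package).  BED output is 0-based
#' half-open, i.e. `start - 1`, `end`.
#'
#' @param regions A region data frame as produced by [merge_matches()] or
#'   [scan_set()] (columns `seq_id`, `start`, `end` required; count columns
#'   filled with `NA` when absent).
#' @param path Output path.
#' @param format `"tsv"` or `"bed"`.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  regions <- as.data.frame(regions)
  for (col in c("n_arn", "n_nonfunctional", "n_gaps"))
    if (is.null(regions[[col]]))
      regions[[col]] <- rep(NA_integer_, nrow(regions))
  if (nrow(regions))
    regions <- regions[order(regions$seq_id, regions$start, regions$end), ,
                       drop = FALSE]
  if (format == "tsv") {
    utils::write.table(
      regions[, c("seq_id", "start", "end",
                  "n_arn", "n_nonfunctional", "n_gaps"), drop = FALSE],
      path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    bed <- data.frame(chrom = regions$seq_id,
                      chromStart = regions$start - 1L,
                      chromEnd = regions$end)
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a region TSV written by [write_regions()]
#'
#' @param path Path to the TSV file.
#' @return Data frame of regions (1-based inclusive coordinates).
#' @export
read_regions <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Read an mRNA annotation table
#'
#' Tab-separated columns `gene_id`, `utr_start`, `cds_start`.  `utr_start`
#' is the (negative) native coordinate where the annotated 5' UTR begins,
#' or `NA` when unannotated; `cds_start` is the 1-based local position of
#' the first coding nucleotide within the supplied mRNA sequence.
#'
#' @param path Path to the annotation TSV.
#' @return Data frame with one row per gene.
#' @export
read_annotation <- function(path) {
  ann <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("gene_id", "utr_start", "cds_start")
  if (!all(need %in% names(ann)))
    stop("annotation must have columns: ", paste(need, collapse = ", "))
  ann
}

#' Oligonucleotides printed in the source study
#'
#' The study's synthetic probes, reconstructed from their printed designs,
#' serve as small built-in inputs: the OxyS-derived 30-mer (nucleotides
#' 57-86 of full-length OxyS, hence offset 57), its abasic variant Oxy0
#' (printed as 29 nt; kept verbatim), the fhlA fusion oligo joining the two
#' (ARN)X regions of the fhlA 5' region, the homo-oligomers A20/A30, and
#' the `(AAN)6AA` designs including the abasic 'AA0'.
#'
#' @return Named list of `rna_seq` objects.
#' @examples
#' scan_set(printed_oligos()["oxyS_arn"])
#' @export
printed_oligos <- function() {
  reps <- function(unit, n, tail = "AA") paste0(strrep(unit, n), tail)
  list(
    oxyS_arn = rna_seq("oxyS_arn", "UCAACUCGAAUAACUAAAGCCAACGUGAAC",
                       offset = 57L),
    oxy0     = rna_seq("oxy0", "UCAA0UC0AA0AA0UAA0GCCAA0GU0AA",
                       offset = 57L),
    fhlA_arn = rna_seq("fhlA_arn", "CUAAUAAAAUUCUACCUAGAAGAACAAAAUGUC"),
    A20      = rna_seq("A20", strrep("A", 20L)),
    A30      = rna_seq("A30", strrep("A", 30L)),
    AA0      = rna_seq("AA0", reps("AA0", 6L)),
    AAC      = rna_seq("AAC", reps("AAC", 6L)),
    AAU      = rna_seq("AAU", reps("AAU", 6L)),
    AAG      = rna_seq("AAG", reps("AAG", 6L))
  )
}
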