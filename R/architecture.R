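#' Pairing table of a dot-bracket structure
#'
#' @param structure A [dot_bracket()] object.
#' @return Integer vector: `pt[i]` is the partner of position `i`, or
#'   `NA` if unpaired.
#' @export
pairing_table <- function(structure) {
  stopifnot(inherits(structure, "dot_bracket"))
  chars <- strsplit(structure$brackets, "", fixed = TRUE)[[1L]]
  pt <- rep(NA_integer_, length(chars))
  stack <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") stack <- c(stack, i)
    else if (chars[i] == ")") {
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j; pt[j] <- i
    }
  }
  pt
}

#' Find innermost hairpins in a secondary structure
#'
#' An innermost hairpin is a helix whose enclosed region contains no
#' further base pairs.  Each hairpin is reported with its two stem arms
#' (extended outward while the pairs stack contiguously, so both arms have
#' equal length) and its loop interval.
#'
#' @param structure A [dot_bracket()] object.
#' @return List of `hairpin` objects: lists with `stem5`, `loop`, `stem3`
#'   (integer `c(start, end)` intervals, 1-based).
#' @examples
#' find_hairpins(dot_bracket("x", "((((....))))"))
#' @export
find_hairpins <- function(structure) {
  pt <- pairing_table(structure)
  L <- length(pt)
  out <- list()
  for (i in seq_len(L)) {
    j <- pt[i]
    if (is.na(j) || j <= i) next
    # innermost pair: nothing paired strictly inside (i, j)
    inner <- if (j - i >= 2L) (i + 1L):(j - 1L) else integer(0)
    if (length(inner) && any(!is.na(pt[inner]))) next
    # extend the helix outward while pairs stack directly
    t <- 0L
    while (i - t - 1L >= 1L && j + t + 1L <= L &&
           !is.na(pt[i - t - 1L]) && pt[i - t - 1L] == j + t + 1L)
      t <- t + 1L
    hp <- list(stem5 = c(i - t, i), loop = c(i + 1L, j - 1L),
               stem3 = c(j, j + t))
    class(hp) <- "hairpin"
    out[[length(out) + 1L]] <- hp
  }
  out
}

#' @export
print.hairpin <- function(x, ...) {
  cat(sprintf("<hairpin> stem5 %d-%d | loop %d-%d | stem3 %d-%d\n",
              x$stem5[1], x$stem5[2], x$loop[1], x$loop[2],
              x$stem3[1], x$stem3[2]))
  invisible(x)
}

#' Structural context of a motif region
#'
#' Locates the nearest hairpin entirely 5' of the region and the nearest
#' entirely 3' of it, and reports whether the region itself is
#' predominantly unpaired.  A region with a hairpin on both sides is
#' "embraced" -- the arrangement shared by the OxyS-like sRNAs.
#'
#' @param region Integer `c(start, end)` in local coordinates, or a
#'   one-row `motif_regions` data frame (its `local_start`/`local_end`
#'   are used).
#' @param structure A [dot_bracket()] object covering the sequence.
#' @param unpaired_min Fraction of region positions that must be unpaired
#'   for the `unpaired` flag (default 0.9).
#' @return List with `flank5`, `flank3` (hairpin objects or `NULL`),
#'   `unpaired_fraction`, `unpaired` (logical) and `context`, one of
#'   `"embraced"`, `"flank5_only"`, `"flank3_only"`, `"none"`.
#' @export
motif_context <- function(region, structure, unpaired_min = 0.9) {
  region <- region_bounds(region)
  pt <- pairing_table(structure)
  if (region[2L] > length(pt)) stop("region exceeds structure length")
  hp <- find_hairpins(structure)
  before <- Filter(function(h) h$stem3[2L] < region[1L], hp)
  after <- Filter(function(h) h$stem5[1L] > region[2L], hp)
  flank5 <- if (length(before))
    before[[which.max(vapply(before, function(h) h$stem3[2L], integer(1)))]]
  flank3 <- if (length(after))
    after[[which.min(vapply(after, function(h) h$stem5[1L], integer(1)))]]
  idx <- region[1L]:region[2L]
  unpaired_fraction <- mean(is.na(pt[idx]))
  context <- if (!is.null(flank5) && !is.null(flank3)) "embraced"
             else if (!is.null(flank5)) "flank5_only"
             else if (!is.null(flank3)) "flank3_only"
             else "none"
  list(flank5 = flank5, flank3 = flank3,
       unpaired_fraction = unpaired_fraction,
       unpaired = unpaired_fraction >= unpaired_min,
       context = context)
}

region_bounds <- function(region) {
  if (is.data.frame(region)) {
    stopifnot(nrow(region) == 1L)
    return(c(region$local_start, region$local_end))
  }
  region <- as.integer(region)
  stopifnot(length(region) == 2L, region[1L] >= 1L, region[1L] <= region[2L])
  region
}

#' Distance from a motif region to the 3' poly(U) tail
#'
#' Rho-independent terminators leave a U-rich 3' end; operationally the
#' tail is the U-run of at least `min_u_run` consecutive U closest to the
#' 3' terminus that starts within the final `search_window` nucleotides.
#' The distance is the number of nucleotides between the region end and
#' the first U of that run.
#'
#' @param seq An [rna_seq()] object.
#' @param region Region in local coordinates (`c(start, end)` or a
#'   one-row `motif_regions` data frame).
#' @param min_u_run Minimum run length to qualify as a tail (default 4).
#' @param search_window The run must begin within this many nucleotides of
#'   the 3' end (default 15).
#' @return Integer distance in nt, or `NA` if no qualifying U-run exists.
#' @export
polyU_distance <- function(seq, region, min_u_run = 4L, search_window = 15L) {
  stopifnot(inherits(seq, "rna_seq"))
  region <- region_bounds(region)
  chars <- seq_chars(seq)
  L <- length(chars)
  r <- rle(chars == "U")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  qual <- which(r$values & r$lengths >= min_u_run &
                starts >= L - search_window + 1L)
  if (!length(qual)) return(NA_integer_)
  tail_start <- starts[qual[length(qual)]]   # run closest to the 3' end
  if (tail_start <= region[2L]) return(NA_integer_)
  tail_start - region[2L] - 1L
}

#' Extract an mRNA 5' analysis window
#'
#' Cuts the analysis window spanning the 5' UTR and the first 80 coding
#' nucleotides out of a full mRNA sequence, numbering positions relative
#' to the start codon (+1 is the first coding nucleotide; there is no
#' position 0, so -1 abuts +1).  When no 5' UTR annotation is available,
#' -80 is used as the default upstream boundary.  Windows exceeding the
#' supplied sequence are clipped with a warning.
#'
#' @param seq An [rna_seq()] object holding the mRNA (or enough of it).
#' @param cds_start Local 1-based position of the first coding nucleotide
#'   within `seq`.
#' @param utr_start Native (negative) coordinate where the annotated 5'
#'   UTR begins, or `NA` for unannotated (default -80 is used).
#' @param cds_nt Number of coding nucleotides to include (default 80).
#' @param gene_id Identifier for the windowed sequence (defaults to
#'   `<seq id>_window`).
#' @return An `rna_seq` whose offset encodes the UTR numbering, with
#'   attribute `window` (list: `gene_id`, `utr_start`, `from`, `to`).
#' @export
mrna_window <- function(seq, cds_start, utr_start = NA, cds_nt = 80L,
                        gene_id = NULL) {
  stopifnot(inherits(seq, "rna_seq"))
  cds_start <- as.integer(cds_start)
  L <- nchar(seq$residues)
  if (cds_start < 1L || cds_start > L)
    stop("cds_start outside the supplied sequence")
  if (is.na(utr_start)) utr_start <- -80L
  utr_start <- as.integer(utr_start)
  if (utr_start >= 0L) stop("utr_start must be a negative coordinate")
  lo <- cds_start + utr_start            # local position of utr_start
  hi <- cds_start + cds_nt - 1L
  if (lo < 1L) {
    warning("window clipped at the 5' end of the supplied sequence")
    lo <- 1L
  }
  if (hi > L) {
    warning("window clipped at the 3' end of the supplied sequence")
    hi <- L
  }
  from <- lo - cds_start                 # native coordinate of first residue
  if (from >= 0L) {
    from <- from + 1L                    # inside the CDS; skip 0
    if (lo == cds_start) warning("window begins at the start codon")
  }
  id <- gene_id %||% paste0(seq$id, "_window")
  out <- rna_seq(id, substr(seq$residues, lo, hi), offset = from)
  attr(out, "window") <- list(gene_id = id, utr_start = utr_start,
                              from = from, to = to_native(out, hi - lo + 1L))
  out
}

#' Candidate bipartite (ARN)X regions in an mRNA window
#'
#' Target-mRNA 5' regions typically carry two shorter (ARN)X regions --
#' one near the start codon/RBS, one further upstream -- roughly 60 nt
#' apart.  For each consecutive region pair this reports the inter-region
#' spacing (counted on the mRNA coordinate line, which has no position 0)
#' and flags pairs whose spacing falls within a configurable band.
#'
#' @param regions A `motif_regions` data frame from one mRNA window
#'   (native, possibly negative, coordinates).
#' @param band Numeric `c(lo, hi)` spacing band in nt (default 40-80; a
#'   description of the typical spacing, not a filter).
#' @return Data frame with one row per consecutive pair: both region
#'   intervals, `spacing_nt` and `candidate_bipartite`.
#' @export
bipartite_regions <- function(regions, band = c(40L, 80L)) {
  regions <- as.data.frame(regions)
  if (nrow(regions) < 2L)
    return(data.frame(start1 = integer(0), end1 = integer(0),
                      start2 = integer(0), end2 = integer(0),
                      spacing_nt = integer(0),
                      candidate_bipartite = logical(0)))
  regions <- regions[order(regions$local_start %||% regions$start), ,
                     drop = FALSE]
  i <- seq_len(nrow(regions) - 1L)
  spacing <- native_gap(regions$end[i], regions$start[i + 1L])
  data.frame(start1 = regions$start[i], end1 = regions$end[i],
             start2 = regions$start[i + 1L], end2 = regions$end[i + 1L],
             spacing_nt = spacing,
             candidate_bipartite = spacing >= band[1L] & spacing <= band[2L])
}

#' A/R-site positions of a motif region
#'
#' Returns the local positions, within a match tiling, that are A-sites
#' (first triplet base) or R-sites (second base) of ARN elements -- the
#' positions whose identity the motif constrains and whose conservation is
#' informative.
#'
#' @param match One row of a `motif_matches` data frame (with its
#'   `tiling`), or a tiling data frame itself.
#' @return Data frame with columns `pos` (local) and `site` (`"A"`/`"R"`).
#' @export
arn_sites <- function(match) {
  tiling <- if (is.data.frame(match) && !is.null(match$class)) match
            else match$tiling[[1L]]
  arn <- tiling[tiling$class == "ARN", , drop = FALSE]
  data.frame(pos = c(arn$start, arn$start + 1L),
             site = rep(c("A", "R"), each = nrow(arn)))[
               order(c(arn$start, arn$start + 1L)), ]
}

#' Conservation of a motif region across an alignment
#'
#' Maps a motif region, given in ungapped coordinates of a reference row,
#' through the alignment columns and asks how well the other sequences
#' preserve the ARN constraint: per A-site column, the fraction of rows
#' carrying `A`; per R-site column, the fraction carrying `A` or `G`; and
#' a row-level *persistence*, the fraction of rows that still satisfy the
#' class at every A/R position of the region.  Rows whose region is
#' entirely gapped are excluded from persistence; columns where all
#' non-reference rows are gapped are flagged rather than dropped.
#'
#' @param alignment An [rna_alignment()].
#' @param reference_id Row id providing the coordinate frame.
#' @param region `c(start, end)` in ungapped reference coordinates.
#' @param sites Optional data frame from [arn_sites()] giving A/R
#'   positions (ungapped reference coordinates).  When `NULL`, the
#'   reference region is re-scanned with [find_matches()] and the sites of
#'   the best-supported match tilings are used.
#' @param conserved_min Fraction of rows above which a column is labelled
#'   conserved (default 0.8; presentation only).
#' @return List with `columns` (data frame: `column`, `ref_pos`, `site`,
#'   `conservation`, `conserved`, `flagged`) and `persistence` (scalar).
#' @export
conservation_profile <- function(alignment, reference_id, region,
                                 sites = NULL, conserved_min = 0.8) {
  stopifnot(inherits(alignment, "rna_alignment"))
  ri <- match(reference_id, alignment$ids)
  if (is.na(ri)) stop("reference row '", reference_id, "' not in alignment")
  region <- as.integer(region)
  rows <- lapply(alignment$rows, function(r) strsplit(r, "", fixed = TRUE)[[1L]])
  ref <- rows[[ri]]
  ungapped_cols <- which(ref != "-")          # column of each reference pos
  if (region[2L] > length(ungapped_cols))
    stop("region exceeds the ungapped reference length")
  if (is.null(sites)) {
    ref_seq <- rna_seq(reference_id, paste0(ref[ref != "-"], collapse = ""))
    mm <- find_matches(ref_seq)
    mm <- mm[mm$local_start <= region[2L] & mm$local_end >= region[1L], ,
             drop = FALSE]
    if (!nrow(mm)) stop("no motif match found in the reference region; ",
                        "supply 'sites' explicitly")
    sites <- unique(do.call(rbind, lapply(seq_len(nrow(mm)), function(i)
      arn_sites(mm[i, , drop = FALSE]))))
    sites <- sites[sites$pos >= region[1L] & sites$pos <= region[2L], ,
                   drop = FALSE]
  }
  nrows <- length(rows)
  cols <- ungapped_cols[sites$pos]
  per_col <- lapply(seq_along(cols), function(k) {
    col <- cols[k]
    residues <- vapply(rows, `[[`, character(1), col)
    hit <- if (sites$site[k] == "A") residues == "A"
           else residues %in% c("A", "G")
    flagged <- all(residues[-ri] == "-") && nrows > 1L
    data.frame(column = col, ref_pos = sites$pos[k], site = sites$site[k],
               conservation = mean(hit), flagged = flagged)
  })
  columns <- do.call(rbind, per_col)
  columns$conserved <- columns$conservation >= conserved_min
  # row persistence on rows with any residue in the region
  region_cols <- ungapped_cols[region[1L]:region[2L]]
  persists <- vapply(seq_len(nrows), function(r) {
    residues <- vapply(cols, function(col) rows[[r]][col], character(1))
    if (all(vapply(region_cols, function(col) rows[[r]][col] == "-",
                   logical(1))))
      return(NA)                                # fully gapped: excluded
    all(ifelse(columns$site == "A", residues == "A",
               residues %in% c("A", "G")))
  }, logical(1))
  list(columns = columns, persistence = mean(persists, na.rm = TRUE))
}

#' Folding-constraint string protecting motif regions
#'
#' Produces a Vienna-style constraint line with `x` (forced unpaired) at
#' every motif position and `.` elsewhere, for use with constrained
#' folding engines so that (ARN)X motifs are kept free of base pairing.
#'
#' @param regions A `motif_regions` data frame, a list of `c(start, end)`
#'   pairs, or a single `c(start, end)` (local coordinates).
#' @param seq_len Length of the sequence to fold.
#' @return A string of length `seq_len` over `{x, .}`.
#' @examples
#' folding_constraints(c(3, 5), 8)  # "..xxx..."
#' @export
folding_constraints <- function(regions, seq_len) {
  seq_len <- as.integer(seq_len)
  if (is.data.frame(regions))
    regions <- lapply(seq_len(nrow(regions)), function(i)
      c(regions$local_start[i], regions$local_end[i]))
  else if (!is.list(regions)) regions <- list(regions)
  mask <- rep(".", seq_len)
  for (r in regions) {
    r <- region_bounds(r)
    if (r[2L] > seq_len) stop("region exceeds sequence length")
    mask[r[1L]:r[2L]] <- "x"
  }
  paste0(mask, collapse = "")
}
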