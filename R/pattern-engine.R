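#' @section Triplet classes:
#' An ARN triplet is the three-nucleotide unit bound by one subunit of the
#' Hfq hexamer's distal face: an A-site that accepts only adenine, an
#' R-site that accepts either purine (A or G), and an N-site whose base is
#' flipped away from the protein and is unconstrained.  Any other 3-mer is
#' "non-functional".
#' @name triplet-classes
NULL

ELEMENT_SPAN <- c(ARN = 3L, NF = 3L, GAP = 1L)

#' Classify a 3-mer as ARN or non-functional
#'
#' A 3-mer is an ARN triplet iff position 1 is `A` and position 2 is `A` or
#' `G`.  The N position accepts any residue, including the abasic marker
#' `0` (probe designs delete exactly this base); `0` at the A or R
#' position fails the triplet, since those bases contact the protein.
#'
#' @param triplet Character vector of 3-mers.
#' @return `"ARN"` or `"NONFUNCTIONAL"` per element.
#' @export
classify_triplet <- function(triplet) {
  ifelse(is_arn_triplet(triplet), "ARN", "NONFUNCTIONAL")
}

#' @rdname classify_triplet
#' @return `is_arn_triplet`: logical vector.
#' @export
is_arn_triplet <- function(triplet) {
  stopifnot(all(nchar(triplet) == 3L))
  t1 <- substr(triplet, 1L, 1L)
  t2 <- substr(triplet, 2L, 2L)
  t1 == "A" & (t2 == "A" | t2 == "G")
}

# Logical vector over positions 1..(L-2): does an ARN triplet begin here?
# (padded with FALSE to length L for convenient indexing)
arn_start_vector <- function(chars) {
  L <- length(chars)
  out <- logical(L)
  if (L >= 3L) {
    idx <- seq_len(L - 2L)
    out[idx] <- chars[idx] == "A" & (chars[idx + 1L] %in% c("A", "G"))
  }
  out
}

#' Total nucleotide span of a pattern layout
#'
#' Triplet elements (`ARN`, `NF`) span 3 nt, a `GAP` spans 1 nt.
#'
#' @param layout Character vector over `"ARN"`, `"NF"`, `"GAP"`.
#' @return Integer span in nucleotides.
#' @export
layout_span <- function(layout) sum(ELEMENT_SPAN[layout])

layout_valid <- function(layout) {
  n <- length(layout)
  if (n == 0L || layout[1L] != "ARN" || layout[n] != "ARN") return(FALSE)
  if (n > 1L) {
    prev <- layout[-n]; nxt <- layout[-1L]
    if (any(prev == "NF" & nxt == "NF")) return(FALSE)
    if (any(prev == "GAP" & nxt == "GAP")) return(FALSE)
  }
  TRUE
}

#' Enumerate all permuted pattern layouts for given element counts
#'
#' Generates every distinct ordering of `n_arn` ARN triplets, `n_nf`
#' non-functional triplets and `n_gaps` single-nucleotide gaps that
#' satisfies the layout rules: the pattern begins and ends with an ARN
#' triplet, no two non-functional triplets abut, and no two gaps abut
#' (`NF-GAP-NF` is allowed: the gap restores a backbone spacer).  This is
#' the permutation machinery used to build comprehensive degenerate
#' pattern sets before matching.
#'
#' @param n_arn Number of ARN triplets (>= 1).
#' @param n_nf Number of non-functional triplets.
#' @param n_gaps Number of single-nucleotide gaps.
#' @param gaps_next_to_arn If `TRUE`, additionally require every gap to
#'   abut at least one ARN triplet (the stricter of the two gap-placement
#'   conventions; the default allows gaps anywhere interior).
#' @return List of layouts (character vectors), deduplicated, in
#'   lexicographic order of their element strings.  Unsatisfiable
#'   definitions (`n_arn < 2` with any NF or gap) yield an empty list with
#'   a warning.
#' @examples
#' length(enumerate_layouts(6, 0, 0))  # 1: the conservative pattern
#' length(enumerate_layouts(6, 1, 0))  # 5: NF in any interior slot
#' length(enumerate_layouts(2, 2, 0))  # 0: two NFs would have to abut
#' @export
enumerate_layouts <- function(n_arn, n_nf = 0L, n_gaps = 0L,
                              gaps_next_to_arn = FALSE) {
  n_arn <- as.integer(n_arn); n_nf <- as.integer(n_nf)
  n_gaps <- as.integer(n_gaps)
  stopifnot(n_arn >= 1L, n_nf >= 0L, n_gaps >= 0L)
  if (n_arn < 2L && (n_nf > 0L || n_gaps > 0L)) {
    warning("boundary rule unsatisfiable: n_arn < 2 with non-ARN elements")
    return(list())
  }
  acc <- list()
  build <- function(prefix, a, f, g) {
    if (a + f + g == 0L) {
      if (prefix[length(prefix)] == "ARN") acc[[length(acc) + 1L]] <<- prefix
      return(invisible())
    }
    last <- if (length(prefix)) prefix[length(prefix)] else ""
    remaining_last <- (a + f + g == 1L)
    # try elements in lexicographic order: ARN < GAP < NF
    if (a > 0L) build(c(prefix, "ARN"), a - 1L, f, g)
    if (g > 0L && last != "GAP" && length(prefix) && !remaining_last)
      build(c(prefix, "GAP"), a, f, g - 1L)
    if (f > 0L && last != "NF" && length(prefix) && !remaining_last)
      build(c(prefix, "NF"), a, f - 1L, g)
  }
  build(character(0), n_arn, n_nf, n_gaps)
  if (gaps_next_to_arn && length(acc)) {
    keep <- vapply(acc, function(lay) {
      gp <- which(lay == "GAP")
      all(vapply(gp, function(i) {
        (i > 1L && lay[i - 1L] == "ARN") ||
          (i < length(lay) && lay[i + 1L] == "ARN")
      }, logical(1)))
    }, logical(1))
    acc <- acc[keep]
  }
  acc
}

#' Pattern-set ensembles by ambiguity class
#'
#' The explorative phase of motif definition proceeds from a conservative
#' pattern (six consecutive ARN triplets) through progressively more
#' permissive definitions; each class below names one rung of that ladder
#' and expands to the union of [enumerate_layouts()] calls over the
#' corresponding element-count combinations.
#'
#' * `CONSERVATIVE` - six consecutive ARN triplets, nothing else.
#' * `NF_TRIPLETS` - one or two non-functional triplets allowed.
#' * `GAPS_ADJACENT` - one or two single gaps, each next to an ARN triplet.
#' * `GAPS_ANYWHERE` - one or two single gaps anywhere interior.
#' * `COMBINED` - non-functional triplets and gaps together.
#'
#' @param ambiguity_class One of the classes above.
#' @param n_arn Number of ARN triplets per layout (default 6, the
#'   conservative starting point).
#' @param max_nf,max_gaps Upper bounds on non-functional triplets / gaps
#'   (defaults 2 and 2).
#' @return List of layouts (union over count combinations, deduplicated).
#' @export
pattern_set <- function(ambiguity_class = c("CONSERVATIVE", "NF_TRIPLETS",
                                            "GAPS_ADJACENT", "GAPS_ANYWHERE",
                                            "COMBINED"),
                        n_arn = 6L, max_nf = 2L, max_gaps = 2L) {
  ambiguity_class <- match.arg(ambiguity_class)
  combos <- switch(ambiguity_class,
    CONSERVATIVE  = list(c(0L, 0L)),
    NF_TRIPLETS   = lapply(1:max_nf, function(f) c(f, 0L)),
    GAPS_ADJACENT = lapply(1:max_gaps, function(g) c(0L, g)),
    GAPS_ANYWHERE = lapply(1:max_gaps, function(g) c(0L, g)),
    COMBINED      = {
      grid <- expand.grid(f = 0:max_nf, g = 0:max_gaps)
      lapply(seq_len(nrow(grid)), function(i) c(grid$f[i], grid$g[i]))
    })
  adjacent <- ambiguity_class == "GAPS_ADJACENT"
  out <- list()
  for (fg in combos)
    out <- c(out, enumerate_layouts(n_arn, fg[1L], fg[2L],
                                    gaps_next_to_arn = adjacent))
  unique(out)
}

#' Test whether a layout matches a sequence at a position
#'
#' Tiles the layout over the residues starting at `pos`: each `ARN` slot
#' must be an ARN triplet, an `NF` slot consumes any 3-mer (including one
#' that happens to be ARN), a `GAP` slot consumes one residue of any
#' identity.  Positions are local (1-based within the stored residues).
#' Out-of-range placements return `FALSE` rather than erroring.
#'
#' @param layout Character vector over `"ARN"`, `"NF"`, `"GAP"`.
#' @param seq An [rna_seq()] object.
#' @param pos Local start position.
#' @return `TRUE`/`FALSE`, with attribute `elements` (data frame of
#'   element class and local start/end) when `TRUE`.
#' @export
layout_matches_at <- function(layout, seq, pos) {
  stopifnot(inherits(seq, "rna_seq"))
  pos <- as.integer(pos)
  span <- layout_span(layout)
  L <- nchar(seq$residues)
  if (pos < 1L || pos + span - 1L > L) return(FALSE)
  chars <- seq_chars(seq)
  p <- pos
  starts <- integer(length(layout)); ends <- integer(length(layout))
  for (i in seq_along(layout)) {
    w <- ELEMENT_SPAN[[layout[i]]]
    if (layout[i] == "ARN" &&
        !is_arn_triplet(paste0(chars[p:(p + 2L)], collapse = "")))
      return(FALSE)
    starts[i] <- p; ends[i] <- p + w - 1L
    p <- p + w
  }
  structure(TRUE, elements = data.frame(class = layout, start = starts,
                                        end = ends))
}

#' Search parameters for the refined motif scan
#'
#' The refined motif definition: at least `n_arn_min` ARN triplets within a
#' match span of at most `window_nt` nucleotides, allowing at most `max_nf`
#' non-adjacent non-functional triplets and at most `max_gaps` separated
#' single-nucleotide gaps; matches begin and end with an ARN triplet.  With
#' the defaults the window is exactly saturable: 4x3 + 2x3 + 2x1 = 20 nt.
#'
#' @param n_arn_min Minimum number of ARN triplets per match (default 4;
#'   mRNA 5'-window scans conventionally relax this to 3).
#' @param max_nf Maximum non-functional triplets (default 2).
#' @param max_gaps Maximum single gaps (default 2).
#' @param window_nt Maximum span of a single match (default 20).  Longer
#'   motif regions arise only by merging overlapping matches.
#' @return A `pattern_params` object (named list).
#' @export
pattern_params <- function(n_arn_min = 4L, max_nf = 2L, max_gaps = 2L,
                           window_nt = 20L) {
  p <- list(n_arn_min = as.integer(n_arn_min), max_nf = as.integer(max_nf),
            max_gaps = as.integer(max_gaps), window_nt = as.integer(window_nt))
  if (p$n_arn_min < 1L || p$max_nf < 0L || p$max_gaps < 0L ||
      p$window_nt < 3L * p$n_arn_min)
    stop("invalid pattern parameters (window must fit n_arn_min triplets)")
  class(p) <- "pattern_params"
  p
}

#' Read pattern parameters from a YAML config file
#'
#' Recognised keys: `n_arn_min`, `max_nonfunctional`, `max_gaps`,
#' `window_nt` (missing keys take the package defaults).
#'
#' @param path Path to a YAML file.
#' @return A [pattern_params()] object.
#' @export
read_pattern_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  pattern_params(
    n_arn_min = cfg$n_arn_min %||% 4L,
    max_nf = cfg$max_nonfunctional %||% 2L,
    max_gaps = cfg$max_gaps %||% 2L,
    window_nt = cfg$window_nt %||% 20L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Compile every layout consistent with the search parameters: a from
# n_arn_min up to the window capacity, all NF/gap counts within bounds,
# total span within the window.  Memoised per parameter set.
.layout_cache <- new.env(parent = emptyenv())

compile_layouts <- function(params) {
  key <- paste(params$n_arn_min, params$max_nf, params$max_gaps,
               params$window_nt, sep = "|")
  if (!is.null(.layout_cache[[key]])) return(.layout_cache[[key]])
  out <- list()
  a_max <- params$window_nt %/% 3L
  for (a in params$n_arn_min:a_max)
    for (f in 0:params$max_nf)
      for (g in 0:params$max_gaps) {
        if (3L * a + 3L * f + g > params$window_nt) next
        out <- c(out, enumerate_layouts(a, f, g))
      }
  .layout_cache[[key]] <- out
  out
}

#' Export a layout set as a data frame
#'
#' One row per layout with its element string (e.g. `"ARN|NF|ARN|GAP|ARN"`)
#' and derived counts; suitable for writing to TSV for inspection.
#'
#' @param layouts List of layouts from [enumerate_layouts()] or
#'   [pattern_set()].
#' @return Data frame with columns `elements`, `n_arn`, `n_nf`, `n_gaps`,
#'   `span_nt`.
#' @export
layouts_table <- function(layouts) {
  data.frame(
    elements = vapply(layouts, paste, character(1), collapse = "|"),
    n_arn = vapply(layouts, function(l) sum(l == "ARN"), integer(1)),
    n_nf = vapply(layouts, function(l) sum(l == "NF"), integer(1)),
    n_gaps = vapply(layouts, function(l) sum(l == "GAP"), integer(1)),
    span_nt = vapply(layouts, layout_span, integer(1)))
}
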