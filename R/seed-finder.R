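#' Find minimal complementary seed regions between an sRNA and an mRNA
#'
#' Enumerates antiparallel complementary duplexes between the two
#' sequences that satisfy the minimal seed definition: either seven
#' consecutive base pairs (`SEVEN_BP`), or six consecutive pairs, a single
#' unpaired (bulged) nucleotide on one strand, and two further pairs
#' (`SIX_GAP_TWO`).  Complementarity is Watson-Crick (A:U, G:C) by
#' default; G:U wobble pairs can be enabled.  The abasic residue `0` never
#' pairs.
#'
#' Perfect matches are reported as maximal duplexes (a 7-bp hit inside a
#' longer perfect duplex reports the full duplex); set
#' `report_maximal = FALSE` to list every minimal 7-bp window instead.
#' Bulged matches are assembled from two *maximal* complementary runs on
#' adjacent pairing diagonals separated by exactly one bulged nucleotide,
#' so the bulge genuinely cannot pair in place; the bulge may sit on
#' either strand and the 6+gap+2 layout is searched in both reading
#' orders, each configurable.
#'
#' @param srna,mrna [rna_seq()] objects.  Coordinates in the result are
#'   native (so an mRNA 5' window with a negative offset reports UTR
#'   numbering).
#' @param allow_wobble Also count G:U as paired (default `FALSE`).
#' @param report_maximal Collapse sliding 7-mer redundancy into maximal
#'   perfect duplexes (default `TRUE`).
#' @param gap_on Which strand may carry the bulge: `"both"` (default),
#'   `"srna"` or `"mrna"`.
#' @param orders Reading order of the bulged layout along the sRNA:
#'   `"both"` (default), `"6_then_2"` or `"2_then_6"`.
#' @return Data frame of class `seed_matches`, sorted by (sRNA start,
#'   mRNA start): columns `srna_id`, `srna_start`, `srna_end`, `mrna_id`,
#'   `mrna_start`, `mrna_end` (native coordinates), `kind`, `gap_strand`
#'   (`NONE`/`SRNA`/`MRNA`), `n_pairs`, `pair_string` (textual duplex,
#'   sRNA 5'->3' over mRNA 3'->5').
#' @examples
#' find_seeds(rna_seq("s", "GGGGGGG"), rna_seq("m", "AACCCCCCCAA"))
#' @export
find_seeds <- function(srna, mrna, allow_wobble = FALSE,
                       report_maximal = TRUE,
                       gap_on = c("both", "srna", "mrna"),
                       orders = c("both", "6_then_2", "2_then_6")) {
  stopifnot(inherits(srna, "rna_seq"), inherits(mrna, "rna_seq"))
  gap_on <- match.arg(gap_on)
  orders <- match.arg(orders)
  s <- seq_chars(srna); m <- seq_chars(mrna)
  n <- length(s); M <- length(m)
  runs <- pairing_runs(s, m, allow_wobble)

  hits <- list()
  add <- function(ss, se, ms, me, kind, gap_strand, n_pairs, bulge_local) {
    hits[[length(hits) + 1L]] <<- list(ss = ss, se = se, ms = ms, me = me,
                                       kind = kind, gap_strand = gap_strand,
                                       n_pairs = n_pairs,
                                       bulge_local = bulge_local)
  }

  for (r in runs) {
    len <- r$i1 - r$i0 + 1L
    if (len < 7L) next
    if (report_maximal) {
      add(r$i0, r$i1, r$c - r$i1, r$c - r$i0, "SEVEN_BP", "NONE", len, NA)
    } else {
      for (k in 0:(len - 7L))
        add(r$i0 + k, r$i0 + k + 6L, r$c - (r$i0 + k + 6L), r$c - (r$i0 + k),
            "SEVEN_BP", "NONE", 7L, NA)
    }
  }

  ok_order <- function(l1, l2) {
    a <- (l1 >= 6L && l2 >= 2L) && orders %in% c("both", "6_then_2")
    b <- (l1 >= 2L && l2 >= 6L) && orders %in% c("both", "2_then_6")
    a || b
  }
  by_diag <- split(runs, vapply(runs, `[[`, integer(1), "c"))
  for (r1 in runs) {
    l1 <- r1$i1 - r1$i0 + 1L
    # bulge on the sRNA strand: second run one diagonal up, sRNA skips 1 nt
    if (gap_on %in% c("both", "srna")) {
      for (r2 in by_diag[[as.character(r1$c + 1L)]] %||% list()) {
        if (r2$i0 != r1$i1 + 2L) next
        l2 <- r2$i1 - r2$i0 + 1L
        if (!ok_order(l1, l2)) next
        add(r1$i0, r2$i1, r1$c + 1L - r2$i1, r1$c - r1$i0,
            "SIX_GAP_TWO", "SRNA", l1 + l2, r1$i1 + 1L)
      }
    }
    # bulge on the mRNA strand: second run one diagonal down, mRNA skips 1 nt
    if (gap_on %in% c("both", "mrna")) {
      for (r2 in by_diag[[as.character(r1$c - 1L)]] %||% list()) {
        if (r2$i0 != r1$i1 + 1L) next
        l2 <- r2$i1 - r2$i0 + 1L
        if (!ok_order(l1, l2)) next
        add(r1$i0, r2$i1, r1$c - 1L - r2$i1, r1$c - r1$i0,
            "SIX_GAP_TWO", "MRNA", l1 + l2, r1$c - r1$i1 - 1L)
      }
    }
  }

  if (!length(hits)) return(empty_seeds(srna$id, mrna$id))
  df <- do.call(rbind, lapply(hits, function(h)
    data.frame(ls = h$ss, le = h$se, lm = h$ms, lme = h$me, kind = h$kind,
               gap_strand = h$gap_strand, n_pairs = h$n_pairs,
               bulge_local = h$bulge_local, stringsAsFactors = FALSE)))
  df <- df[!duplicated(df[, c("ls", "le", "lm", "lme", "kind",
                              "gap_strand")]), , drop = FALSE]
  df <- df[order(df$ls, df$lm, df$kind), , drop = FALSE]
  out <- data.frame(
    srna_id = srna$id,
    srna_start = to_native(srna, df$ls), srna_end = to_native(srna, df$le),
    mrna_id = mrna$id,
    mrna_start = to_native(mrna, df$lm), mrna_end = to_native(mrna, df$lme),
    kind = df$kind, gap_strand = df$gap_strand, n_pairs = df$n_pairs,
    pair_string = vapply(seq_len(nrow(df)), function(i)
      render_duplex(s, m, df$ls[i], df$le[i], df$lm[i], df$lme[i],
                    df$gap_strand[i], df$bulge_local[i]), character(1)),
    stringsAsFactors = FALSE)
  attr(out, "srna_local") <- df[, c("ls", "le")]
  attr(out, "mrna_local") <- df[, c("lm", "lme")]
  class(out) <- c("seed_matches", "data.frame")
  out
}

empty_seeds <- function(srna_id, mrna_id) {
  out <- data.frame(srna_id = character(0), srna_start = integer(0),
                    srna_end = integer(0), mrna_id = character(0),
                    mrna_start = integer(0), mrna_end = integer(0),
                    kind = character(0), gap_strand = character(0),
                    n_pairs = integer(0), pair_string = character(0),
                    stringsAsFactors = FALSE)
  class(out) <- c("seed_matches", "data.frame")
  out
}

base_pairs <- function(a, b, allow_wobble = FALSE) {
  wc <- (a == "A" & b == "U") | (a == "U" & b == "A") |
        (a == "G" & b == "C") | (a == "C" & b == "G")
  if (allow_wobble)
    wc <- wc | (a == "G" & b == "U") | (a == "U" & b == "G")
  wc
}

# Maximal antiparallel complementary runs.  sRNA position i pairs mRNA
# position j; the next pair is (i+1, j-1), so a run lives on a constant
# antidiagonal c = i + j.  Returns a list of (c, i0, i1).
pairing_runs <- function(s, m, allow_wobble = FALSE) {
  n <- length(s); M <- length(m)
  runs <- list()
  for (c in 2L:(n + M)) {
    i_lo <- max(1L, c - M); i_hi <- min(n, c - 1L)
    if (i_lo > i_hi) next
    i <- i_lo:i_hi
    p <- base_pairs(s[i], m[c - i], allow_wobble)
    r <- rle(p)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      runs[[length(runs) + 1L]] <-
        list(c = c, i0 = i_lo + starts[k] - 1L, i1 = i_lo + ends[k] - 1L)
    }
  }
  runs
}

# Textual duplex: sRNA 5'->3' on top, mRNA 3'->5' underneath; '-' marks
# the strand opposite a bulged nucleotide.
render_duplex <- function(s, m, ls, le, lm, lme, gap_strand, bulge_local) {
  top <- s[ls:le]
  bottom <- rev(m[lm:lme])
  if (gap_strand == "SRNA") {
    bottom <- append(bottom, "-", after = bulge_local - ls)
  } else if (gap_strand == "MRNA") {
    # bulge_local is the skipped mRNA position; in 3'->5' rendering it sits
    # after the first run's columns
    col <- lme - bulge_local
    top <- append(top, "-", after = col)
  }
  paste0("5'-", paste0(top, collapse = ""), "-3'/3'-",
         paste0(bottom, collapse = ""), "-5'")
}

#' Overlay seed matches on motif regions and secondary structure
#'
#' Classifies each seed's sRNA-side interval relative to each (ARN)X motif
#' region on the same sequence -- `upstream`, `overlapping` or
#' `downstream` -- and, when a dot-bracket structure is supplied, whether
#' the seed lies entirely inside a hairpin loop (the arrangement in which
#' seed regions sit at the tips of stem-loops flanking the motif).
#'
#' @param seeds A `seed_matches` data frame from [find_seeds()].
#' @param motif_regions A `motif_regions` data frame from
#'   [merge_matches()] for the same sRNA.
#' @param structure Optional [dot_bracket()] structure of the sRNA.
#' @return Data frame with one row per (seed, region) pair: seed and
#'   region coordinates, `position` classification and `in_loop`
#'   (`NA` when no structure is given).
#' @export
map_seeds_to_regions <- function(seeds, motif_regions, structure = NULL) {
  stopifnot(inherits(seeds, "seed_matches"))
  motif_regions <- as.data.frame(motif_regions)
  if (nrow(seeds) && nrow(motif_regions) &&
      !all(seeds$srna_id %in% motif_regions$seq_id))
    stop("mismatched sequence ids between seeds and motif regions")
  if (!is.null(structure) && nrow(seeds) &&
      structure$seq_id != seeds$srna_id[1L])
    stop("mismatched sequence ids between seeds and structure")
  loops <- NULL
  if (!is.null(structure)) {
    hp <- find_hairpins(structure)
    loops <- lapply(hp, `[[`, "loop")
  }
  srna_local <- attr(seeds, "srna_local")
  rows <- list()
  for (i in seq_len(nrow(seeds))) {
    for (j in seq_len(nrow(motif_regions))) {
      ss <- seeds$srna_start[i]; se <- seeds$srna_end[i]
      rs <- motif_regions$start[j]; re <- motif_regions$end[j]
      position <- if (se < rs) "upstream"
                  else if (ss > re) "downstream"
                  else "overlapping"
      in_loop <- NA
      if (!is.null(loops)) {
        lls <- srna_local$ls[i]; lle <- srna_local$le[i]
        in_loop <- any(vapply(loops, function(lp)
          lls >= lp[1L] && lle <= lp[2L], logical(1)))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        srna_id = seeds$srna_id[i], seed_start = ss, seed_end = se,
        kind = seeds$kind[i], region_start = rs, region_end = re,
        position = position, in_loop = in_loop, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(srna_id = character(0), seed_start = integer(0),
                      seed_end = integer(0), kind = character(0),
                      region_start = integer(0), region_end = integer(0),
                      position = character(0), in_loop = logical(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
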