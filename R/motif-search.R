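#' Find all maximal (ARN)X motif matches in one sequence
#'
#' Scans the sequence with the complete permuted layout set implied by the
#' search parameters (see [pattern_params()] and [compile_layouts]) and
#' returns every *maximal* match: a matched interval is reported unless a
#' valid match strictly contains it.  Matches begin and end with an ARN
#' triplet; every start position opening an ARN triplet is considered.
#' Where several element tilings produce the same interval, the reported
#' element breakdown prefers more ARN triplets, then fewer gaps, then the
#' lexicographically earliest element string; the interval itself never
#' depends on this tie-break.
#'
#' @param seq An [rna_seq()] object.
#' @param params A [pattern_params()] object (defaults: >= 4 ARN triplets
#'   within 20 nt, <= 2 non-adjacent NF triplets, <= 2 separated gaps).
#' @return A data frame of class `motif_matches`, one row per maximal
#'   match, sorted by (start, end): columns `seq_id`, `start`, `end`
#'   (native coordinates), `local_start`, `local_end`, `n_arn`,
#'   `n_nonfunctional`, `n_gaps`, `elements` (element string such as
#'   `"ARN|GAP|ARN|NF|ARN|ARN"`), plus a list column `tiling` of per-element
#'   local intervals.  Sequences shorter than `3 * n_arn_min` yield zero
#'   rows.
#' @examples
#' find_matches(rna_seq("a12", strrep("A", 12)))
#' @export
find_matches <- function(seq, params = pattern_params()) {
  stopifnot(inherits(seq, "rna_seq"), inherits(params, "pattern_params"))
  L <- nchar(seq$residues)
  empty <- empty_matches(seq$id)
  if (L < 3L * params$n_arn_min) return(empty)
  chars <- seq_chars(seq)
  arn_ok <- arn_start_vector(chars)
  layouts <- compile_layouts(params)

  hits_s <- integer(0); hits_e <- integer(0); hits_l <- integer(0)
  for (li in seq_along(layouts)) {
    lay <- layouts[[li]]
    span <- layout_span(lay)
    if (span > L) next
    widths <- ELEMENT_SPAN[lay]
    offs <- c(0L, cumsum(widths))[seq_along(lay)]   # 0-based element offsets
    arn_offs <- offs[lay == "ARN"]
    cand <- seq_len(L - span + 1L)
    ok <- rep(TRUE, length(cand))
    for (o in arn_offs) ok <- ok & arn_ok[cand + o]
    s <- cand[ok]
    if (length(s)) {
      hits_s <- c(hits_s, s)
      hits_e <- c(hits_e, s + span - 1L)
      hits_l <- c(hits_l, rep.int(li, length(s)))
    }
  }
  if (!length(hits_s)) return(empty)

  # best tiling per distinct interval: more ARN, fewer gaps, earliest string
  key <- paste(hits_s, hits_e)
  lt <- layouts_table(layouts)
  pref <- order(key, -lt$n_arn[hits_l], lt$n_gaps[hits_l],
                lt$elements[hits_l])
  first <- pref[!duplicated(key[pref])]
  s <- hits_s[first]; e <- hits_e[first]; li <- hits_l[first]

  # maximal filter: drop intervals strictly contained in another interval
  keep <- vapply(seq_along(s), function(i) {
    !any(s <= s[i] & e >= e[i] & (s < s[i] | e > e[i]))
  }, logical(1))
  s <- s[keep]; e <- e[keep]; li <- li[keep]
  ord <- order(s, e)
  s <- s[ord]; e <- e[ord]; li <- li[ord]

  tilings <- lapply(seq_along(s), function(i) {
    lay <- layouts[[li[i]]]
    widths <- ELEMENT_SPAN[lay]
    st <- s[i] + c(0L, cumsum(widths))[seq_along(lay)]
    data.frame(class = lay, start = st, end = st + widths - 1L)
  })
  out <- data.frame(
    seq_id = seq$id,
    start = to_native(seq, s), end = to_native(seq, e),
    local_start = s, local_end = e,
    n_arn = lt$n_arn[li], n_nonfunctional = lt$n_nf[li],
    n_gaps = lt$n_gaps[li], elements = lt$elements[li],
    stringsAsFactors = FALSE)
  out$tiling <- tilings
  class(out) <- c("motif_matches", "data.frame")
  attr(out, "seq") <- seq
  out
}

empty_matches <- function(seq_id) {
  out <- data.frame(seq_id = character(0), start = integer(0),
                    end = integer(0), local_start = integer(0),
                    local_end = integer(0), n_arn = integer(0),
                    n_nonfunctional = integer(0), n_gaps = integer(0),
                    elements = character(0), stringsAsFactors = FALSE)
  out$tiling <- list()
  class(out) <- c("motif_matches", "data.frame")
  out
}

#' Merge overlapping motif matches into (ARN)X regions
#'
#' Overlapping matches (>= 1 nt shared) from a single sequence are merged
#' into one motif region, the unit reported per sRNA.  Book-ended matches
#' (abutting with zero overlap) remain separate regions.  Motif regions
#' longer than the single-match window arise only through this merging.
#'
#' @param matches A `motif_matches` data frame from [find_matches()] (all
#'   rows from one sequence).
#' @return Data frame of class `motif_regions`, sorted and pairwise
#'   non-overlapping: columns `seq_id`, `start`, `end` (native),
#'   `local_start`, `local_end`, `n_matches`, `max_arn` (largest ARN count
#'   among supporting matches), `n_arn`, `n_nonfunctional`, `n_gaps` (from
#'   the best supporting match: most ARN, then fewest gaps).
#' @examples
#' m <- find_matches(printed_oligos()$oxyS_arn)
#' merge_matches(m)  # one region starting at 59 in full-length numbering
#' @export
merge_matches <- function(matches) {
  stopifnot(inherits(matches, "motif_matches"))
  if (length(unique(matches$seq_id)) > 1L)
    stop("merge_matches expects matches from a single sequence")
  empty <- data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), local_start = integer(0),
                      local_end = integer(0), n_matches = integer(0),
                      max_arn = integer(0), n_arn = integer(0),
                      n_nonfunctional = integer(0), n_gaps = integer(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("motif_regions", "data.frame")
  if (!nrow(matches)) return(empty)
  seq <- attr(matches, "seq")
  m <- matches[order(matches$local_start, matches$local_end), , drop = FALSE]
  grp <- integer(nrow(m)); g <- 1L; grp[1L] <- 1L
  hi <- m$local_end[1L]
  for (i in seq_len(nrow(m))[-1L]) {
    if (m$local_start[i] <= hi) {           # >= 1 nt overlap
      grp[i] <- g
      hi <- max(hi, m$local_end[i])
    } else {
      g <- g + 1L; grp[i] <- g; hi <- m$local_end[i]
    }
  }
  rows <- lapply(split(seq_len(nrow(m)), grp), function(idx) {
    sub <- m[idx, , drop = FALSE]
    best <- sub[order(-sub$n_arn, sub$n_gaps, sub$elements)[1L], ]
    ls <- min(sub$local_start); le <- max(sub$local_end)
    data.frame(seq_id = sub$seq_id[1L],
               start = if (!is.null(seq)) to_native(seq, ls) else min(sub$start),
               end = if (!is.null(seq)) to_native(seq, le) else max(sub$end),
               local_start = ls, local_end = le,
               n_matches = nrow(sub), max_arn = max(sub$n_arn),
               n_arn = best$n_arn, n_nonfunctional = best$n_nonfunctional,
               n_gaps = best$n_gaps, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out <- out[order(out$local_start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("motif_regions", "data.frame")
  attr(out, "seq") <- seq
  out
}

#' Scan a set of sequences and summarise regions per sequence
#'
#' Applies [find_matches()] and [merge_matches()] to every sequence and
#' tabulates how many merged (ARN)X regions each sequence carries, binned
#' as 0, 1, 2, 3, 4 and 5-or-more regions (the cohort-summary convention).
#'
#' @param seqs List of [rna_seq()] objects (or a single one).  Duplicate
#'   ids are an error.
#' @param params A [pattern_params()] object.
#' @return Object of class `arn_scan`: list with `regions` (all merged
#'   regions, one data frame), `per_seq` (data frame `seq_id`, `length_nt`,
#'   `n_regions`), `histogram` (named integer vector over bins
#'   `0,1,2,3,4,5+`), `params`, and `matches` (per-sequence match tables).
#' @examples
#' scan_set(list(rna_seq("a20", strrep("A", 20)),
#'               rna_seq("c20", strrep("C", 20))))
#' @export
scan_set <- function(seqs, params = pattern_params()) {
  seqs <- as_seq_list(seqs)
  ids <- vapply(seqs, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  matches <- lapply(seqs, find_matches, params = params)
  regions <- lapply(matches, merge_matches)
  names(matches) <- ids; names(regions) <- ids
  all_regions <- do.call(rbind, c(lapply(regions, as.data.frame),
                                  list(make.row.names = FALSE)))
  n_regions <- vapply(regions, nrow, integer(1))
  per_seq <- data.frame(seq_id = ids,
                        length_nt = vapply(seqs, function(s)
                          nchar(s$residues), integer(1)),
                        n_regions = n_regions, stringsAsFactors = FALSE)
  bins <- c("0", "1", "2", "3", "4", "5+")
  histogram <- stats::setNames(integer(6), bins)
  binned <- ifelse(n_regions >= 5L, "5+", as.character(n_regions))
  tab <- table(binned)
  histogram[names(tab)] <- as.integer(tab)
  structure(list(regions = all_regions, per_seq = per_seq,
                 histogram = histogram, params = params, matches = matches),
            class = "arn_scan")
}

#' @export
print.arn_scan <- function(x, ...) {
  cat(sprintf("<arn_scan> %d sequences, %d merged (ARN)X regions\n",
              nrow(x$per_seq), nrow(x$regions)))
  cat("regions per sequence:\n")
  print(x$histogram)
  invisible(x)
}

#' @export
#' @method summary arn_scan
summary.arn_scan <- function(object, ...) {
  print(object)
  if (nrow(object$regions)) {
    cat("\nregions:\n")
    print(object$regions[, c("seq_id", "start", "end", "n_matches",
                             "max_arn")], row.names = FALSE)
  }
  invisible(object)
}
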