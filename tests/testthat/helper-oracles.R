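# Independent brute-force oracles.  These deliberately take different
# algorithmic routes from the package implementation: the motif oracle is
# an exhaustive per-start DFS over element tilings (the implementation
# compiles layout sets and slides them); the layout-count oracle places
# elements by position combinations; the seed oracle enumerates interval
# pairs with explicit boundary checks (the implementation assembles
# matches from maximal pairing runs); the hairpin oracle builds a nesting
# tree by recursive descent (the implementation walks a pairing table).

# All maximal motif-match intervals by exhaustive DFS over tilings.
oracle_find_matches <- function(residues, n_arn_min = 4L, max_nf = 2L,
                                max_gaps = 2L, window_nt = 20L) {
  chars <- strsplit(residues, "", fixed = TRUE)[[1L]]
  L <- length(chars)
  is_arn_at <- function(p)
    p + 2L <= L && chars[p] == "A" && chars[p + 1L] %in% c("A", "G")
  found <- list()
  dfs <- function(s, pos, last, a, f, g) {
    if (last == "ARN" && a >= n_arn_min)
      found[[length(found) + 1L]] <<- c(s, pos - 1L)
    if (pos + 2L <= L && pos + 2L - s + 1L <= window_nt) {
      if (is_arn_at(pos)) dfs(s, pos + 3L, "ARN", a + 1L, f, g)
      if (last != "NF" && f < max_nf) dfs(s, pos + 3L, "NF", a, f + 1L, g)
    }
    if (pos <= L && pos - s + 1L <= window_nt && last != "GAP" &&
        g < max_gaps)
      dfs(s, pos + 1L, "GAP", a, f, g + 1L)
  }
  for (s in seq_len(L))
    if (is_arn_at(s)) dfs(s, s + 3L, "ARN", 1L, 0L, 0L)
  if (!length(found))
    return(data.frame(start = integer(0), end = integer(0)))
  iv <- unique(do.call(rbind, found))
  keep <- vapply(seq_len(nrow(iv)), function(i)
    !any(iv[, 1L] <= iv[i, 1L] & iv[, 2L] >= iv[i, 2L] &
         (iv[, 1L] < iv[i, 1L] | iv[, 2L] > iv[i, 2L])), logical(1))
  iv <- iv[keep, , drop = FALSE]
  iv <- iv[order(iv[, 1L], iv[, 2L]), , drop = FALSE]
  data.frame(start = iv[, 1L], end = iv[, 2L])
}

# Count legal layouts by placing NF/GAP elements at position combinations.
oracle_layout_count <- function(n_arn, n_nf, n_gaps) {
  if (n_arn < 2L && (n_nf > 0L || n_gaps > 0L)) return(0L)
  n <- n_arn + n_nf + n_gaps
  if (n == 1L) return(1L)
  slots <- seq_len(n)
  count <- 0L
  nf_sets <- if (n_nf > 0L) utils::combn(slots, n_nf, simplify = FALSE)
             else list(integer(0))
  for (nf in nf_sets) {
    rest <- setdiff(slots, nf)
    gap_sets <- if (n_gaps > 0L) utils::combn(rest, n_gaps, simplify = FALSE)
                else list(integer(0))
    for (gp in gap_sets) {
      lay <- rep("ARN", n)
      lay[nf] <- "NF"; lay[gp] <- "GAP"
      ok <- lay[1L] == "ARN" && lay[n] == "ARN" &&
        !any(lay[-n] == "NF" & lay[-1L] == "NF") &&
        !any(lay[-n] == "GAP" & lay[-1L] == "GAP")
      if (ok) count <- count + 1L
    }
  }
  count
}

oracle_pairs <- function(a, b, wobble = FALSE) {
  (a == "A" & b == "U") | (a == "U" & b == "A") |
    (a == "G" & b == "C") | (a == "C" & b == "G") |
    (wobble & ((a == "G" & b == "U") | (a == "U" & b == "G")))
}

# Exhaustive seed-duplex enumeration: every antiparallel interval pair
# with <= 1 bulge, each candidate validated by explicit pair checks plus
# non-extension predicates at all four boundaries (so only maximal
# segment decompositions survive, matching the reported semantics).
# Returns find_seeds-style columns in local coordinates.
oracle_find_seeds <- function(srna_res, mrna_res, wobble = FALSE) {
  s <- strsplit(srna_res, "", fixed = TRUE)[[1L]]
  m <- strsplit(mrna_res, "", fixed = TRUE)[[1L]]
  n <- length(s); M <- length(m)
  p <- function(i, j) {
    if (i < 1L || i > n || j < 1L || j > M) return(FALSE)
    oracle_pairs(s[i], m[j], wobble)
  }
  run_fwd <- function(i, j) {           # pairs along the antidiagonal
    k <- 0L
    while (p(i + k, j - k)) k <- k + 1L
    k
  }
  rows <- list()
  rec <- function(ss, se, ms, me, kind, gap_strand)
    rows[[length(rows) + 1L]] <<- data.frame(
      srna_start = ss, srna_end = se, mrna_start = ms, mrna_end = me,
      kind = kind, gap_strand = gap_strand, stringsAsFactors = FALSE)
  for (i in seq_len(n)) for (jhi in seq_len(M)) {
    if (!p(i, jhi) || p(i - 1L, jhi + 1L)) next   # duplex must open here
    L0 <- run_fwd(i, jhi)
    for (L in seq_len(L0)) {
      if (L >= 7L && !p(i + L, jhi - L))          # perfect, right-maximal
        rec(i, i + L - 1L, jhi - L + 1L, jhi, "SEVEN_BP", "NONE")
    }
    for (l1 in seq_len(L0)) {
      if (l1 < 2L || p(i + l1, jhi - l1)) next    # run1 must end here
      # bulge on sRNA: run2 opens at (i + l1 + 1, jhi - l1)
      if (!p(i + l1, jhi - l1 + 1L)) {            # run2 cannot reach back
        l2max <- run_fwd(i + l1 + 1L, jhi - l1)
        for (l2 in seq_len(l2max)) {
          if (l2 < 2L || p(i + l1 + 1L + l2, jhi - l1 - l2)) next
          if ((l1 >= 6L && l2 >= 2L) || (l1 >= 2L && l2 >= 6L))
            rec(i, i + l1 + l2, jhi - l1 - l2 + 1L, jhi,
                "SIX_GAP_TWO", "SRNA")
        }
      }
      # bulge on mRNA: run2 opens at (i + l1, jhi - l1 - 1)
      if (!p(i + l1 - 1L, jhi - l1)) {            # run2 cannot reach back
        l2max <- run_fwd(i + l1, jhi - l1 - 1L)
        for (l2 in seq_len(l2max)) {
          if (l2 < 2L || p(i + l1 + l2, jhi - l1 - 1L - l2)) next
          if ((l1 >= 6L && l2 >= 2L) || (l1 >= 2L && l2 >= 6L))
            rec(i, i + l1 + l2 - 1L, jhi - l1 - l2, jhi,
                "SIX_GAP_TWO", "MRNA")
        }
      }
    }
  }
  if (!length(rows))
    return(data.frame(srna_start = integer(0), srna_end = integer(0),
                      mrna_start = integer(0), mrna_end = integer(0),
                      kind = character(0), gap_strand = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out), , drop = FALSE]
  out[order(out$srna_start, out$mrna_start, out$kind, out$gap_strand), ,
      drop = FALSE]
}

# Hairpins via an independently built nesting tree (recursive descent).
oracle_hairpins <- function(brackets) {
  chars <- strsplit(brackets, "", fixed = TRUE)[[1L]]
  parse_children <- function(lo, hi) {
    kids <- list(); i <- lo
    while (i <= hi) {
      if (chars[i] == "(") {
        depth <- 1L; j <- i
        while (depth > 0L) {
          j <- j + 1L
          if (chars[j] == "(") depth <- depth + 1L
          if (chars[j] == ")") depth <- depth - 1L
        }
        kids[[length(kids) + 1L]] <- list(i = i, j = j)
        i <- j + 1L
      } else i <- i + 1L
    }
    kids
  }
  hairpins <- list()
  walk <- function(i, j, stem_outer_i, stem_outer_j, stem_len) {
    kids <- parse_children(i + 1L, j - 1L)
    if (length(kids) == 0L) {
      hairpins[[length(hairpins) + 1L]] <<- list(
        stem5 = c(i - stem_len + 1L, i), loop = c(i + 1L, j - 1L),
        stem3 = c(j, j + stem_len - 1L))
    } else if (length(kids) == 1L && kids[[1L]]$i == i + 1L &&
               kids[[1L]]$j == j - 1L) {
      walk(kids[[1L]]$i, kids[[1L]]$j, stem_outer_i, stem_outer_j,
           stem_len + 1L)
    } else {
      for (k in kids) walk(k$i, k$j, k$i, k$j, 1L)
    }
  }
  for (k in parse_children(1L, length(chars)))
    walk(k$i, k$j, k$i, k$j, 1L)
  hairpins
}

# Deterministic random RNA for property tests.
random_rna <- function(len, probs = c(A = .3, C = .23, G = .23, U = .24))
  paste0(sample(names(probs), len, replace = TRUE, prob = probs),
         collapse = "")

# Deterministic filler sequence with no RNG dependency (cycling ACGU,
# A-poor enough not to spawn motifs on its own is not guaranteed; use only
# where motif content is irrelevant).
random_rna_fixed <- function(len)
  paste0(rep(c("G", "C", "U", "A"), length.out = len), collapse = "")
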