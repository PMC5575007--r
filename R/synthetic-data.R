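#' @section Reproducibility:
#' Every generator takes a mandatory `rng_seed`; the global RNG state is
#' saved and restored around each call, so generation is reproducible and
#' side-effect free.
#' @name synthetic-data
NULL

with_seed <- function(rng_seed, code) {
  if (is.null(rng_seed) || is.na(rng_seed))
    stop("an explicit rng_seed is required for reproducible generation")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(rng_seed))
  force(code)
}

DEFAULT_BG <- c(A = 0.2, C = 0.8 / 3, G = 0.8 / 3, U = 0.8 / 3)
DEPLETED_BG <- c(A = 0.1, C = 0.3, G = 0.3, U = 0.3)

random_residues <- function(n, probs = DEFAULT_BG) {
  if (n <= 0L) return(character(0))
  sample(names(probs), n, replace = TRUE, prob = probs)
}

#' Specification of a motif to plant
#'
#' Describes the (ARN)X motif a generator should embed: element counts
#' plus the base preferences at each triplet site.  The R site prefers
#' adenine (default probability 0.8, guanine otherwise), reflecting the
#' A-preference observed in conserved motifs; the N site is free.
#'
#' @param n_arn,n_nf,n_gaps Element counts (NF and gaps each at most 2;
#'   the implied layout must satisfy the layout rules).
#' @param p_A_at_R Probability of A (vs G) at R sites (default 0.8).
#' @param n_probs Base distribution at N sites (default uniform A/C/G/U).
#' @return A `motif_spec` object.
#' @export
motif_spec <- function(n_arn = 4L, n_nf = 0L, n_gaps = 0L, p_A_at_R = 0.8,
                       n_probs = c(A = .25, C = .25, G = .25, U = .25)) {
  stopifnot(n_nf <= 2L, n_gaps <= 2L, n_arn >= 1L,
            p_A_at_R >= 0, p_A_at_R <= 1)
  if (length(enumerate_layouts(n_arn, n_nf, n_gaps)) == 0L)
    stop("no legal layout exists for these element counts")
  p <- list(n_arn = as.integer(n_arn), n_nf = as.integer(n_nf),
            n_gaps = as.integer(n_gaps), p_A_at_R = p_A_at_R,
            n_probs = n_probs)
  class(p) <- "motif_spec"
  p
}

# Draw a concrete motif instance: a random legal layout realised as
# residues.  NF triplets are rejection-sampled to be genuinely non-ARN.
realize_motif <- function(spec) {
  layouts <- enumerate_layouts(spec$n_arn, spec$n_nf, spec$n_gaps)
  layout <- layouts[[sample.int(length(layouts), 1L)]]
  parts <- lapply(layout, function(el) {
    switch(el,
      ARN = c("A",
              sample(c("A", "G"), 1L,
                     prob = c(spec$p_A_at_R, 1 - spec$p_A_at_R)),
              sample(names(spec$n_probs), 1L, prob = spec$n_probs)),
      NF = {
        repeat {
          t <- random_residues(3L, DEFAULT_BG)
          if (!is_arn_triplet(paste0(t, collapse = ""))) break
        }
        t
      },
      GAP = random_residues(1L, DEFAULT_BG))
  })
  list(residues = unlist(parts), layout = layout,
       span = layout_span(layout))
}

#' Plant an (ARN)X motif in random background sequence
#'
#' Embeds a motif drawn from `spec` at a random position in background
#' sequence of configurable composition.  The default background is
#' mildly A-depleted (A frequency 0.2); `deplete_A = TRUE` lowers it to
#' 0.1, reducing spurious motif hits (A-rich background produces them
#' readily -- that false-positive behaviour is itself worth measuring, see
#' [shuffle_hit_rate()]).  The planted subsequence satisfies the refined
#' pattern by construction, so an exact scan recovers it always.
#'
#' @param spec A [motif_spec()].
#' @param background_len Total sequence length (must exceed the planted
#'   span by at least 6 nt).
#' @param rng_seed Mandatory integer seed.
#' @param bg_probs Background base distribution.
#' @param deplete_A Use the A-depleted background.
#' @param id Sequence id.
#' @return List with `seq` (an [rna_seq()]) and `truth` (list: `motif`
#'   interval `c(start, end)`, `layout`, `span`).
#' @export
plant_motif <- function(spec, background_len, rng_seed,
                        bg_probs = DEFAULT_BG, deplete_A = FALSE,
                        id = "synthetic") {
  stopifnot(inherits(spec, "motif_spec"))
  if (deplete_A) bg_probs <- DEPLETED_BG
  with_seed(rng_seed, {
    inst <- realize_motif(spec)
    if (background_len < inst$span + 6L)
      stop("background_len must be at least planted span + 6")
    pos <- sample.int(background_len - inst$span + 1L, 1L)
    bg <- random_residues(background_len, bg_probs)
    bg[pos:(pos + inst$span - 1L)] <- inst$residues
    list(seq = rna_seq(id, paste0(bg, collapse = "")),
         truth = list(motif = c(pos, pos + inst$span - 1L),
                      layout = inst$layout, span = inst$span))
  })
}

#' Specification of an OxyS-like sRNA architecture
#'
#' Layout generated 5' to 3': leader | stem-loop | spacer | (ARN)X motif |
#' spacer | stem-loop | filler | poly(U).  `spacer_to_polyU` is the total
#' number of nucleotides between the motif end and the first U of the
#' tail (the 3' hairpin sits inside it), drawn uniformly from 20-40 nt
#' when not given -- the spacing band observed for OxyS-like sRNAs.
#'
#' @param stem5_len,loop5_len 5' hairpin arm and loop lengths.
#' @param motif A [motif_spec()].
#' @param stem3_len,loop3_len 3' hairpin arm and loop lengths.
#' @param spacer_to_polyU Motif-end to poly(U) distance in nt, or `NA` to
#'   draw uniformly from `c(20, 40)`.  Must be able to contain the 3'
#'   hairpin.
#' @param polyU_len Length of the 3' poly(U) tail (>= 4, default 6).
#' @param seed5,seed3 Optional seed sequences to embed in the 5'/3' loops
#'   (must fit the loop).
#' @param leader_len 5' leader length (default 5).
#' @return An `srna_spec` object.
#' @export
srna_spec <- function(stem5_len = 6L, loop5_len = 7L,
                      motif = motif_spec(5L, 0L, 1L),
                      stem3_len = 5L, loop3_len = 7L,
                      spacer_to_polyU = NA, polyU_len = 6L,
                      seed5 = NULL, seed3 = NULL, leader_len = 5L) {
  stopifnot(inherits(motif, "motif_spec"), polyU_len >= 4L,
            stem5_len >= 3L, stem3_len >= 3L, loop5_len >= 3L,
            loop3_len >= 3L)
  if (!is.null(seed5) && nchar(seed5) > loop5_len)
    stop("seed5 longer than the 5' loop")
  if (!is.null(seed3) && nchar(seed3) > loop3_len)
    stop("seed3 longer than the 3' loop")
  p <- list(stem5_len = as.integer(stem5_len),
            loop5_len = as.integer(loop5_len), motif = motif,
            stem3_len = as.integer(stem3_len),
            loop3_len = as.integer(loop3_len),
            spacer_to_polyU = spacer_to_polyU,
            polyU_len = as.integer(polyU_len),
            seed5 = seed5, seed3 = seed3,
            leader_len = as.integer(leader_len))
  class(p) <- "srna_spec"
  p
}

#' Generate an OxyS-like synthetic sRNA with ground truth
#'
#' Emits a sequence realising the architecture in [srna_spec()], the
#' corresponding dot-bracket structure (planted stems paired, everything
#' else unpaired), and a ground-truth record of every planted feature.
#' Stem arms avoid adenine (and their complements therefore avoid 3' U
#' runs) and the filler before the tail avoids U, so the poly(U) tail is
#' the only qualifying U-run near the 3' end and
#' [polyU_distance()] recovers the planted spacing exactly; seed
#' sequences embedded in loops may contain any residues.
#'
#' @param spec An [srna_spec()].
#' @param rng_seed Mandatory integer seed.
#' @param id Sequence id.
#' @return List with `seq` ([rna_seq()]), `structure` ([dot_bracket()])
#'   and `truth` (list of intervals: `motif`, `hairpin5`, `hairpin3`
#'   (each `stem5`/`loop`/`stem3`), `seed5`, `seed3`, `polyU`, and the
#'   realised `spacer_to_polyU`).
#' @export
make_srna <- function(spec, rng_seed, id = "synthetic_srna") {
  stopifnot(inherits(spec, "srna_spec"))
  with_seed(rng_seed, {
    spacer <- spec$spacer_to_polyU
    if (is.na(spacer)) spacer <- sample(20:40, 1L)
    spacer <- as.integer(spacer)
    hp3_len <- 2L * spec$stem3_len + spec$loop3_len
    if (spacer < hp3_len)
      stop("spacer_to_polyU (", spacer, ") cannot contain the 3' hairpin (",
           hp3_len, " nt)")
    no_A <- c(C = 1 / 3, G = 1 / 3, U = 1 / 3)
    no_U <- c(A = 0.1, C = 0.45, G = 0.45)
    make_loop <- function(len, seed_seq) {
      if (is.null(seed_seq)) return(random_residues(len, DEPLETED_BG))
      seed_chars <- strsplit(normalize_residues(seed_seq), "", fixed = TRUE)[[1L]]
      pad <- len - length(seed_chars)
      lead <- pad %/% 2L
      c(random_residues(lead, DEPLETED_BG), seed_chars,
        random_residues(pad - lead, DEPLETED_BG))
    }
    arm5 <- random_residues(spec$stem5_len, no_A)
    arm3 <- random_residues(spec$stem3_len, no_A)
    loop5 <- make_loop(spec$loop5_len, spec$seed5)
    loop3 <- make_loop(spec$loop3_len, spec$seed3)
    comp <- function(x) rev(unname(WC_PAIR[x]))
    motif <- realize_motif(spec$motif)
    leader <- random_residues(spec$leader_len, DEPLETED_BG)
    pre <- random_residues(2L, c(C = .5, G = .5))  # hairpin/motif separators
    filler <- random_residues(spacer - hp3_len, no_U)

    segs <- list(leader = leader,
                 stem5a = arm5, loop5 = loop5, stem5b = comp(arm5),
                 pre = pre,
                 motif = motif$residues,
                 stem3a = arm3, loop3 = loop3, stem3b = comp(arm3),
                 filler = filler,
                 polyU = rep("U", spec$polyU_len))
    lens <- vapply(segs, length, integer(1))
    ends <- cumsum(lens)
    starts <- ends - lens + 1L
    at <- function(nm) c(starts[[nm]], ends[[nm]])
    residues <- paste0(unlist(segs), collapse = "")

    db <- rep(".", sum(lens))
    db[starts[["stem5a"]]:ends[["stem5a"]]] <- "("
    db[starts[["stem5b"]]:ends[["stem5b"]]] <- ")"
    db[starts[["stem3a"]]:ends[["stem3a"]]] <- "("
    db[starts[["stem3b"]]:ends[["stem3b"]]] <- ")"

    seed_iv <- function(nm, seed_seq) {
      if (is.null(seed_seq)) return(NULL)
      pad <- lens[[nm]] - nchar(seed_seq)
      lead <- pad %/% 2L
      c(starts[[nm]] + lead, starts[[nm]] + lead + nchar(seed_seq) - 1L)
    }
    truth <- list(
      motif = at("motif"), layout = motif$layout,
      hairpin5 = list(stem5 = at("stem5a"), loop = at("loop5"),
                      stem3 = at("stem5b")),
      hairpin3 = list(stem5 = at("stem3a"), loop = at("loop3"),
                      stem3 = at("stem3b")),
      seed5 = seed_iv("loop5", spec$seed5),
      seed3 = seed_iv("loop3", spec$seed3),
      polyU = at("polyU"),
      spacer_to_polyU = spacer)
    list(seq = rna_seq(id, residues),
         structure = dot_bracket(id, paste0(db, collapse = "")),
         truth = truth)
  })
}

#' Embed seed complements in a synthetic target mRNA
#'
#' Builds a background sequence carrying the reverse complements of the
#' given seed sequences at well-separated random positions, so that
#' [find_seeds()] against the sRNA recovers exactly the planted pairs.
#'
#' @param seeds Character vector of seed sequences (as they read on the
#'   sRNA, 5'->3').
#' @param background_len Total length.
#' @param rng_seed Mandatory integer seed.
#' @param id Sequence id.
#' @param bg_probs Background base distribution (default A-depleted).
#' @return List with `seq` and `truth` (list of planted complement
#'   intervals, in input order).
#' @export
make_target_mrna <- function(seeds, background_len, rng_seed,
                             id = "synthetic_mrna", bg_probs = DEPLETED_BG) {
  with_seed(rng_seed, {
    comps <- lapply(seeds, function(s)
      strsplit(reverse_complement(normalize_residues(s)), "",
               fixed = TRUE)[[1L]])
    total <- sum(lengths(comps))
    if (background_len < total + 4L * length(comps))
      stop("background too short for the requested seed complements")
    bg <- random_residues(background_len, bg_probs)
    # place left to right in equal-sized slots, jittered
    slot <- background_len %/% length(comps)
    truth <- vector("list", length(comps))
    for (k in seq_along(comps)) {
      w <- length(comps[[k]])
      lo <- (k - 1L) * slot + 1L
      hi <- k * slot - w + 1L
      pos <- if (hi > lo) sample(lo:hi, 1L) else lo
      bg[pos:(pos + w - 1L)] <- comps[[k]]
      truth[[k]] <- c(pos, pos + w - 1L)
    }
    list(seq = rna_seq(id, paste0(bg, collapse = "")), truth = truth)
  })
}

#' Composition-preserving shuffle of a sequence
#'
#' `mononucleotide` mode permutes residues uniformly.  `dinucleotide`
#' mode uses an Eulerian-path shuffle (random arborescence toward the
#' terminal residue, then randomised edge orderings) that preserves all
#' 16 dinucleotide counts and the first and last residue -- the standard
#' null model when local composition matters.
#'
#' @param seq An [rna_seq()] object.
#' @param mode `"mononucleotide"` or `"dinucleotide"`.
#' @param rng_seed Mandatory integer seed.
#' @return A shuffled `rna_seq` (id suffixed `_shuf`).
#' @export
shuffle_null <- function(seq, mode = c("mononucleotide", "dinucleotide"),
                         rng_seed) {
  stopifnot(inherits(seq, "rna_seq"))
  mode <- match.arg(mode)
  chars <- seq_chars(seq)
  if (mode == "dinucleotide" && length(chars) < 2L)
    stop("dinucleotide shuffle needs at least 2 residues")
  with_seed(rng_seed, {
    shuffled <- if (mode == "mononucleotide") sample(chars)
                else euler_shuffle(chars)
    rna_seq(paste0(seq$id, "_shuf"), paste0(shuffled, collapse = ""),
            offset = seq$offset)
  })
}

# Altschul-Erickson dinucleotide shuffle.  Vertices are residues, edges
# the observed dinucleotides; pick, for each non-terminal vertex, a random
# "last exit" edge such that the chosen edges form an arborescence toward
# the terminal vertex, shuffle the remaining out-edges, then walk the
# Eulerian path from the first residue.
euler_shuffle <- function(chars) {
  n <- length(chars)
  from <- chars[-n]; to <- chars[-1L]
  verts <- unique(chars)
  last <- chars[n]
  out_edges <- split(to, factor(from, levels = verts))
  repeat {
    exit <- vapply(verts, function(v) {
      e <- out_edges[[v]]
      if (v == last || !length(e)) NA_character_
      else e[sample.int(length(e), 1L)]
    }, character(1))
    # do the chosen exits reach the terminal vertex from every vertex?
    ok <- TRUE
    for (v in verts) {
      if (v == last || is.na(exit[[v]])) next
      cur <- v; seen <- character(0)
      while (cur != last && !cur %in% seen) {
        seen <- c(seen, cur)
        cur <- exit[[cur]]
        if (is.na(cur)) break
      }
      if (is.na(cur) || cur != last) { ok <- FALSE; break }
    }
    if (ok) break
  }
  ordered <- lapply(verts, function(v) {
    e <- out_edges[[v]]
    if (!length(e)) return(character(0))
    if (v == last || is.na(exit[[v]])) return(sample(e))
    picked <- which(e == exit[[v]])[1L]
    rest <- e[-picked]
    c(if (length(rest)) sample(rest) else character(0), e[picked])
  })
  names(ordered) <- verts
  ptr <- stats::setNames(rep(1L, length(verts)), verts)
  path <- character(n)
  path[1L] <- chars[1L]
  cur <- chars[1L]
  for (k in 2:n) {
    nxt <- ordered[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    path[k] <- nxt
    cur <- nxt
  }
  path
}

#' Background hit rate under a shuffle null
#'
#' Shuffles a sequence `n` times and reports the fraction of shuffles in
#' which the motif scan still finds at least one merged region -- a
#' measured background rate for the combinatorial pattern (the scan
#' itself attaches no significance values).
#'
#' @param seq An [rna_seq()] object.
#' @param n Number of shuffles (default 100).
#' @param mode Shuffle mode, see [shuffle_null()].
#' @param params [pattern_params()] for the scan.
#' @param rng_seed Mandatory integer seed.
#' @return List: `hit_rate`, `n`, `n_hit`, and `regions_per_shuffle`.
#' @export
shuffle_hit_rate <- function(seq, n = 100L,
                             mode = c("mononucleotide", "dinucleotide"),
                             params = pattern_params(), rng_seed) {
  mode <- match.arg(mode)
  seeds <- with_seed(rng_seed, sample.int(.Machine$integer.max, n))
  counts <- vapply(seeds, function(s) {
    shuf <- shuffle_null(seq, mode, rng_seed = s)
    nrow(merge_matches(find_matches(shuf, params)))
  }, integer(1))
  list(hit_rate = mean(counts > 0L), n = n, n_hit = sum(counts > 0L),
       regions_per_shuffle = counts)
}

#' Simulate an alignment of homologs around a reference
#'
#' Emulates a homolog alignment: the reference is row 1; each further row
#' substitutes residues independently at `mutation_rate` per position
#' (uniform choice among the three alternatives), except that positions
#' listed in `protect` mutate at `protected_rate` when
#' `protect_motif = TRUE` -- mimicking purifying selection on the A/R
#' sites of a motif.  Optional deletions at `indel_rate` appear as `-`.
#'
#' @param reference An [rna_seq()] or residue string.
#' @param n_rows Total rows including the reference.
#' @param mutation_rate Per-position substitution probability.
#' @param protect_motif Protect the positions in `protect`.
#' @param protect Integer positions (e.g. `arn_sites()$pos`) to protect.
#' @param protected_rate Substitution rate at protected positions
#'   (default `mutation_rate / 10`).
#' @param indel_rate Per-position deletion probability (default 0).
#' @param rng_seed Mandatory integer seed.
#' @return An [rna_alignment()] with ids `ref`, `row2`, ..., `row<n>`.
#' @export
make_alignment <- function(reference, n_rows, mutation_rate,
                           protect_motif = FALSE, protect = integer(0),
                           protected_rate = mutation_rate / 10,
                           indel_rate = 0, rng_seed) {
  ref <- if (inherits(reference, "rna_seq")) reference$residues
         else normalize_residues(reference)
  stopifnot(n_rows >= 1L, mutation_rate >= 0, mutation_rate <= 1,
            indel_rate >= 0, indel_rate <= 1)
  chars <- strsplit(ref, "", fixed = TRUE)[[1L]]
  L <- length(chars)
  rate <- rep(mutation_rate, L)
  if (protect_motif && length(protect)) rate[protect] <- protected_rate
  bases <- c("A", "C", "G", "U")
  with_seed(rng_seed, {
    rows <- vapply(seq_len(n_rows - 1L), function(r) {
      x <- chars
      mut <- stats::runif(L) < rate & x %in% bases
      if (any(mut))
        x[mut] <- vapply(x[mut], function(b)
          sample(setdiff(bases, b), 1L), character(1))
      if (indel_rate > 0) {
        del <- stats::runif(L) < indel_rate
        x[del] <- "-"
      }
      paste0(x, collapse = "")
    }, character(1))
    rna_alignment(c("ref", paste0("row", seq_len(n_rows - 1L) + 1L)),
                  c(ref, rows))
  })
}
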