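test_that("perfect 7-bp seeds are found and reported maximally", {
  hits <- find_seeds(rna_seq("s", "GGGGGGG"), rna_seq("m", "AACCCCCCCAA"))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$kind, "SEVEN_BP")
  expect_equal(c(hits$srna_start, hits$srna_end), c(1L, 7L))
  expect_equal(c(hits$mrna_start, hits$mrna_end), c(3L, 9L))
  au <- find_seeds(rna_seq("s", "AAAAAAA"), rna_seq("m", "UUUUUUU"))
  expect_equal(nrow(au), 1L)
  expect_equal(au$n_pairs, 7L)
})

test_that("a longer perfect duplex is one maximal hit or many minimal ones", {
  s <- rna_seq("s", "GACGUGACG")           # 9 pairs in a single register
  m <- rna_seq("m", reverse_complement("GACGUGACG"))
  maximal <- find_seeds(s, m)
  expect_equal(nrow(maximal), 1L)
  expect_equal(maximal$n_pairs, 9L)
  minimal <- find_seeds(s, m, report_maximal = FALSE)
  expect_equal(nrow(minimal), 3L)          # sliding 7-windows
  expect_true(all(minimal$n_pairs == 7L))
  # a homopolymeric duplex pairs in every register: one maximal duplex per
  # pairing diagonal with >= 7 pairs (frozen from the enumeration oracle)
  homo <- find_seeds(rna_seq("s", strrep("G", 9)),
                     rna_seq("m", strrep("C", 9)))
  expect_equal(sort(homo$n_pairs), c(7L, 7L, 8L, 8L, 9L))
})

test_that("the bulged 6+gap+2 layout is detected on the mRNA strand", {
  hits <- find_seeds(rna_seq("s", "GGGGGGGG"),
                     rna_seq("m", "CCACCCCCC"))   # CC + bulged A + CCCCCC
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$kind, "SIX_GAP_TWO")
  expect_equal(hits$gap_strand, "MRNA")
  expect_equal(c(hits$srna_start, hits$srna_end), c(1L, 8L))
  expect_equal(c(hits$mrna_start, hits$mrna_end), c(1L, 9L))
  expect_equal(hits$n_pairs, 8L)
  expect_match(hits$pair_string, "-")              # bulge rendered
})

test_that("the bulge may sit on the sRNA and both strand modes filter", {
  s <- rna_seq("s", "GGGGGGAGG")           # 6 G, bulged A, 2 G
  m <- rna_seq("m", "CCCCCCCC")
  hits <- find_seeds(s, m)
  expect_equal(hits$gap_strand, "SRNA")
  expect_equal(nrow(find_seeds(s, m, gap_on = "mrna")), 0L)
  expect_equal(nrow(find_seeds(s, m, gap_on = "srna")), 1L)
})

test_that("wobble pairs count only when enabled", {
  s <- rna_seq("s", "GGGGGGG")
  m <- rna_seq("m", "UUUUUUU")
  expect_equal(nrow(find_seeds(s, m)), 0L)
  expect_equal(nrow(find_seeds(s, m, allow_wobble = TRUE)), 1L)
})

test_that("abasic residues never pair", {
  expect_equal(nrow(find_seeds(rna_seq("s", "GGG0GGG"),
                               rna_seq("m", "CCCCCCC"))), 0L)
})

test_that("every reported seed has at least 7 pairs and WC mode is sound", {
  set.seed(555)
  n_with_hits <- 0L
  for (rep in 1:30) {
    sres <- random_rna(sample(15:30, 1))
    mres <- random_rna(sample(15:30, 1))
    if (rep <= 5) {   # guarantee some duplexes: plant a complement
      ins <- reverse_complement(substr(sres, 3, 3 + 6 + rep))
      substr(mres, 4, 4 + nchar(ins) - 1) <- ins
    }
    hits <- find_seeds(rna_seq("s", sres), rna_seq("m", mres))
    if (!nrow(hits)) next
    n_with_hits <- n_with_hits + 1L
    expect_true(all(hits$n_pairs >= 7L))
    perfect <- hits[hits$kind == "SEVEN_BP", , drop = FALSE]
    for (i in seq_len(nrow(perfect)))
      expect_equal(
        substr(sres, perfect$srna_start[i], perfect$srna_end[i]),
        reverse_complement(substr(mres, perfect$mrna_start[i],
                                  perfect$mrna_end[i])))
  }
  expect_gte(n_with_hits, 5L)
})

test_that("find_seeds is symmetric in its two sequences", {
  set.seed(808)
  for (rep in 1:20) {
    a <- rna_seq("a", random_rna(sample(15:28, 1)))
    b <- rna_seq("b", random_rna(sample(15:28, 1)))
    ab <- find_seeds(a, b)
    ba <- find_seeds(b, a)
    expect_equal(nrow(ab), nrow(ba))
    if (!nrow(ab)) next
    swapped <- data.frame(
      srna_start = ba$mrna_start, srna_end = ba$mrna_end,
      mrna_start = ba$srna_start, mrna_end = ba$srna_end,
      kind = ba$kind,
      gap_strand = c(NONE = "NONE", SRNA = "MRNA",
                     MRNA = "SRNA")[ba$gap_strand])
    ord <- function(d) d[order(d$srna_start, d$mrna_start, d$kind,
                               d$gap_strand), , drop = FALSE]
    got <- ord(as.data.frame(ab)[, names(swapped)])
    want <- ord(swapped)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("find_seeds equals exhaustive duplex enumeration on random pairs", {
  set.seed(2024)
  for (rep in 1:40) {
    sres <- random_rna(sample(12:30, 1))
    mres <- random_rna(sample(12:30, 1))
    got <- find_seeds(rna_seq("s", sres), rna_seq("m", mres))
    want <- oracle_find_seeds(sres, mres)
    cols <- c("srna_start", "srna_end", "mrna_start", "mrna_end", "kind",
              "gap_strand")
    got <- as.data.frame(got)[, cols]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want, info = paste(sres, mres))
  }
})

test_that("seed overlay classifies position relative to the motif", {
  regions <- data.frame(seq_id = "s", start = 20L, end = 40L,
                        local_start = 20L, local_end = 40L)
  class(regions) <- c("motif_regions", "data.frame")
  seeds <- find_seeds(rna_seq("s", paste0(strrep("C", 9), "GGGGGGG",
                                          strrep("C", 30))),
                      rna_seq("m", "AACCCCCCCAA"))
  expect_equal(c(seeds$srna_start, seeds$srna_end), c(10L, 16L))
  ov <- map_seeds_to_regions(seeds, regions)
  expect_equal(ov$position, "upstream")
  # shift the region to overlap, then far upstream of the seed
  regions$start <- 14L; regions$local_start <- 14L
  expect_equal(map_seeds_to_regions(seeds, regions)$position, "overlapping")
  regions$start <- 2L; regions$end <- 8L
  regions$local_start <- 2L; regions$local_end <- 8L
  expect_equal(map_seeds_to_regions(seeds, regions)$position, "downstream")
})

test_that("seed overlay flags seeds inside hairpin loops", {
  # seed GGGGGGG sits in the loop of a planted hairpin
  sim <- make_srna(srna_spec(loop5_len = 9L, seed5 = "GGGGGGG"),
                   rng_seed = 6L)  # loop padding cannot extend the duplex
  seeds <- find_seeds(sim$seq, rna_seq("m", "AACCCCCCCAA"))
  planted <- sim$truth$seed5
  row <- which(seeds$srna_start == planted[1L] &
               seeds$srna_end == planted[2L])
  expect_equal(length(row), 1L)
  regions <- data.frame(seq_id = sim$seq$id,
                        start = sim$truth$motif[1L],
                        end = sim$truth$motif[2L],
                        local_start = sim$truth$motif[1L],
                        local_end = sim$truth$motif[2L])
  class(regions) <- c("motif_regions", "data.frame")
  ov <- map_seeds_to_regions(seeds, regions, sim$structure)
  expect_true(ov$in_loop[row])
  expect_equal(ov$position[row], "upstream")
  bad <- dot_bracket("other", sim$structure$brackets)
  expect_error(map_seeds_to_regions(seeds, regions, bad), "ismatch")
})
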