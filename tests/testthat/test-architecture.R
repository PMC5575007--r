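test_that("hairpin detection handles the canonical shapes", {
  hp <- find_hairpins(dot_bracket("x", "((((....))))"))
  expect_equal(length(hp), 1L)
  expect_equal(hp[[1L]]$loop, c(5L, 8L))
  expect_equal(hp[[1L]]$stem5, c(1L, 4L))
  expect_equal(hp[[1L]]$stem3, c(9L, 12L))
  expect_equal(find_hairpins(dot_bracket("x", "............")), list())
  two <- find_hairpins(dot_bracket("x", "((..))..((...))"))
  expect_equal(length(two), 2L)
  expect_equal(two[[1L]]$loop, c(3L, 4L))
  expect_equal(two[[2L]]$loop, c(11L, 13L))
})

test_that("hairpins agree with the nesting-tree oracle on varied structures", {
  cases <- c("((((....))))", "((..))..((...))",
             "((..((...))..((....))..))",        # multiloop
             "(((..(((...)))..)))",              # interrupted stem
             "(.((...)).)", "()", "...((((...))))...")
  for (rep in 1:20)     # plus generated OxyS-like structures
    cases <- c(cases, make_srna(srna_spec(), rng_seed = rep)$structure$brackets)
  for (b in cases) {
    got <- find_hairpins(dot_bracket("x", b))
    want <- oracle_hairpins(b)
    expect_equal(length(got), length(want), info = b)
    for (k in seq_along(got)) {
      expect_equal(got[[k]]$stem5, want[[k]]$stem5, info = b)
      expect_equal(got[[k]]$loop, want[[k]]$loop, info = b)
      expect_equal(got[[k]]$stem3, want[[k]]$stem3, info = b)
    }
    # stems and loops are pairwise disjoint and consistent with brackets
    ch <- strsplit(b, "")[[1L]]
    for (h in got) {
      expect_true(all(ch[h$stem5[1L]:h$stem5[2L]] == "("))
      expect_true(all(ch[h$stem3[1L]:h$stem3[2L]] == ")"))
      if (h$loop[2L] >= h$loop[1L])
        expect_true(all(ch[h$loop[1L]:h$loop[2L]] == "."))
    }
  }
})

test_that("motif context reports flanking hairpins and pairing state", {
  # hairpin at 1-8, unpaired motif at 11-16, hairpin at 19-27
  db <- dot_bracket("x", paste0("(((..)))..", "......", "..",
                                "(((...)))", "..."))
  ctx <- motif_context(c(11L, 16L), db)
  expect_equal(ctx$context, "embraced")
  expect_equal(ctx$flank5$stem3[2L], 8L)
  expect_equal(ctx$flank3$stem5[1L], 19L)
  expect_equal(ctx$unpaired_fraction, 1)
  expect_true(ctx$unpaired)
  # motif at the 5' end: only a 3' flank
  ctx2 <- motif_context(c(1L, 6L), dot_bracket("x", "......((...))"))
  expect_equal(ctx2$context, "flank3_only")
  # fully paired motif: unpaired flag off
  ctx3 <- motif_context(c(1L, 3L), dot_bracket("x", "(((...)))"))
  expect_equal(ctx3$unpaired_fraction, 0)
  expect_false(ctx3$unpaired)
})

test_that("poly(U) distance measures to the 3'-terminal qualifying run", {
  seq <- rna_seq("x", paste0(strrep("A", 12), strrep("C", 2),
                             strrep("G", 30), strrep("U", 6)))  # tail at 45
  expect_equal(polyU_distance(seq, c(1L, 20L), search_window = 15L), 24L)
  # constructed example: region ends 50, tail starts at 81 -> 30 between
  s2 <- rna_seq("y", paste0(strrep("A", 50), strrep("C", 30), strrep("U", 6)))
  expect_equal(polyU_distance(s2, c(31L, 50L), search_window = 40L), 30L)
  # no qualifying run
  expect_equal(polyU_distance(rna_seq("z", strrep("A", 30)), c(1L, 12L)),
               NA_integer_)
  # a 3-U run does not qualify under the default minimum of 4
  s3 <- rna_seq("w", paste0(strrep("A", 20), "CCUUUCC"))
  expect_equal(polyU_distance(s3, c(1L, 12L)), NA_integer_)
})

test_that("mRNA windows carry UTR numbering with no position 0", {
  mrna <- rna_seq("fhlA_full", random_rna_fixed(300))
  w <- mrna_window(mrna, cds_start = 150L, utr_start = -120L)
  expect_equal(w$offset, -120L)
  expect_equal(nchar(w$residues), 200L)          # 120 UTR + 80 CDS
  expect_equal(attr(w, "window")$to, 80L)
  # every windowed position maps to the annotated coordinate; 0 skipped
  nat <- to_native(w, seq_len(nchar(w$residues)))
  expect_equal(nat, c(-120:-1, 1:80))
  # unannotated: default -80
  w2 <- mrna_window(mrna, cds_start = 150L)
  expect_equal(w2$offset, -80L)
  expect_equal(nchar(w2$residues), 160L)
  # degenerate: start codon at sequence start -> clipped with warning
  expect_warning(expect_warning(w3 <- mrna_window(mrna, cds_start = 1L),
                                "clip"), "start codon")
  expect_equal(w3$offset, 1L)
  expect_equal(nchar(w3$residues), 80L)
})

test_that("bipartite spacing is counted across the missing position 0", {
  regions <- data.frame(seq_id = "m", start = c(-70L, -10L),
                        end = c(-55L, 5L),
                        local_start = c(11L, 71L), local_end = c(26L, 85L))
  rep <- bipartite_regions(regions)
  expect_equal(nrow(rep), 1L)
  expect_equal(rep$spacing_nt, 44L)     # (-54..-11), brute-force countable
  expect_true(rep$candidate_bipartite)
  # brute-force coordinate walk honouring the 0 skip
  line <- c(-80:-1, 1:80)
  expect_equal(rep$spacing_nt,
               sum(line > -55L & line < -10L))
  expect_equal(nrow(bipartite_regions(regions[1, ])), 0L)
  three <- rbind(regions,
                 data.frame(seq_id = "m", start = 60L, end = 75L,
                            local_start = 139L, local_end = 154L))
  expect_equal(nrow(bipartite_regions(three)), 2L)
})

test_that("conservation profiles count row agreement at A/R columns", {
  # 10 identical rows except one A->C at an A-site column
  ref <- "GGAAUAACAAGAAUGG"   # motif region 3..14 hand-tiled: AAU AAC AAG AAU
  rows <- rep(ref, 10)
  substr(rows[4], 3, 3) <- "C"
  aln <- rna_alignment(c("ref", paste0("r", 2:10)), rows)
  sites <- data.frame(pos = c(3, 4, 6, 7, 9, 10, 12, 13),
                      site = rep(c("A", "R"), 4))
  prof <- conservation_profile(aln, "ref", c(3L, 14L), sites = sites)
  expect_equal(prof$columns$conservation[1L], 0.9)
  expect_true(all(prof$columns$conservation[-1L] == 1))
  expect_equal(prof$persistence, 0.9)
  # identical rows: persistence 1, sites derived from the scan itself
  aln2 <- rna_alignment(c("ref", "r2", "r3"), rep(ref, 3))
  prof2 <- conservation_profile(aln2, "ref", c(3L, 14L))
  expect_equal(prof2$persistence, 1)
  expect_true(all(prof2$columns$conservation == 1))
})

test_that("gap columns are flagged and gapped rows leave persistence", {
  aln <- rna_alignment(c("ref", "r2", "r3"),
                       c("AAUAACAAGAAU",
                         "AAUAA-AAGAAU",     # gap at an N column
                         "------------"))    # fully gapped row
  prof <- conservation_profile(aln, "ref", c(1L, 12L),
                               sites = data.frame(pos = c(1, 2, 4, 5),
                                                  site = c("A", "R", "A", "R")))
  expect_equal(prof$persistence, 1)          # computed on the two real rows
  # a column where all non-reference rows are gapped gets flagged
  aln2 <- rna_alignment(c("ref", "r2"), c("AAU", "-AU"))
  prof2 <- conservation_profile(aln2, "ref", c(1L, 3L),
                                sites = data.frame(pos = 1, site = "A"))
  expect_true(prof2$columns$flagged[1L])
  expect_equal(prof2$columns$conservation[1L], 0.5)
})

test_that("persistence never increases as mutated rows accumulate", {
  ref <- "GGAAUAACAAGAAUGG"
  sites <- data.frame(pos = c(3, 4, 6, 7, 9, 10, 12, 13),
                      site = rep(c("A", "R"), 4))
  rows <- rep(ref, 8)
  vals <- numeric(0)
  for (k in 2:8) {
    if (k > 2) substr(rows[k], 3 + 3 * ((k - 3) %% 4), 3 + 3 * ((k - 3) %% 4)) <- "C"
    aln <- rna_alignment(paste0("r", 1:k), rows[1:k])
    vals <- c(vals, conservation_profile(aln, "r1", c(3L, 14L),
                                         sites = sites)$persistence)
  }
  expect_true(all(diff(vals) <= 1e-12))
})

test_that("folding constraints mask motif positions", {
  expect_equal(folding_constraints(c(3L, 5L), 8L), "..xxx...")
  expect_equal(folding_constraints(c(1L, 6L), 6L), "xxxxxx")
  expect_equal(folding_constraints(list(c(1L, 2L), c(5L, 6L)), 7L),
               "xx..xx.")
  regs <- data.frame(local_start = c(2L, 6L), local_end = c(3L, 7L))
  expect_equal(folding_constraints(regs, 8L), ".xx..xx.")
  expect_error(folding_constraints(c(5L, 9L), 8L), "exceeds")
})
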