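test_that("planted motifs are recovered and spans follow the layout", {
  res <- plant_motif(motif_spec(4, 0, 0), background_len = 60L, rng_seed = 7L)
  regs <- merge_matches(find_matches(res$seq))
  expect_true(any(regs$local_start <= res$truth$motif[2L] &
                  regs$local_end >= res$truth$motif[1L]))
  # a fully loaded plant spans exactly the 20-nt window
  full <- plant_motif(motif_spec(4, 2, 2), background_len = 40L, rng_seed = 9L)
  expect_equal(full$truth$span, 20L)
  expect_equal(diff(full$truth$motif) + 1L, 20L)
  expect_error(plant_motif(motif_spec(4, 0, 0), background_len = 12L,
                           rng_seed = 1L), "span")
})

test_that("generation is reproducible under a seed and leaves the RNG alone", {
  a <- plant_motif(motif_spec(5, 1, 1), 80L, rng_seed = 42L)
  b <- plant_motif(motif_spec(5, 1, 1), 80L, rng_seed = 42L)
  expect_identical(a, b)
  c <- plant_motif(motif_spec(5, 1, 1), 80L, rng_seed = 43L)
  expect_false(identical(a$seq$residues, c$seq$residues))
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(plant_motif(motif_spec(4), 60L, rng_seed = 5L))
  expect_identical(runif(1), before)   # global stream untouched
  expect_error(plant_motif(motif_spec(4), 60L, rng_seed = NULL), "seed")
})

test_that("OxyS-like architectures carry their planted features", {
  sim <- make_srna(srna_spec(spacer_to_polyU = 25L), rng_seed = 11L)
  expect_equal(nchar(sim$seq$residues), nchar(sim$structure$brackets))
  ctx <- motif_context(sim$truth$motif, sim$structure)
  expect_equal(ctx$context, "embraced")
  expect_true(ctx$unpaired)
  expect_equal(polyU_distance(sim$seq, sim$truth$motif), 25L)
  # drawn spacing stays in the 20-40 nt band and is reported exactly
  sim2 <- make_srna(srna_spec(), rng_seed = 12L)
  expect_true(sim2$truth$spacer_to_polyU >= 20L &&
              sim2$truth$spacer_to_polyU <= 40L)
  expect_equal(polyU_distance(sim2$seq, sim2$truth$motif),
               sim2$truth$spacer_to_polyU)
  expect_error(make_srna(srna_spec(spacer_to_polyU = 10L), rng_seed = 1L),
               "hairpin")
  expect_error(srna_spec(loop5_len = 5L, seed5 = "GGGGGGG"), "longer")
})

test_that("planted seed complements are found between sRNA and target", {
  sim <- make_srna(srna_spec(loop5_len = 9L, seed5 = "GAGAGGG",
                             loop3_len = 9L, seed3 = "GGUGGGC"),
                   rng_seed = 21L)
  tgt <- make_target_mrna(c("GAGAGGG", "GGUGGGC"), 60L, rng_seed = 22L)
  hits <- find_seeds(sim$seq, tgt$seq)
  for (planted in list(sim$truth$seed5, sim$truth$seed3)) {
    expect_true(any(hits$srna_start <= planted[1L] &
                    hits$srna_end >= planted[2L]),
                info = paste(planted, collapse = "-"))
  }
  # ... and the oracle agrees with the implementation on this instance
  want <- oracle_find_seeds(sim$seq$residues, tgt$seq$residues)
  expect_equal(as.data.frame(hits)[, c("srna_start", "srna_end")],
               want[, c("srna_start", "srna_end")],
               ignore_attr = TRUE)
})

test_that("shuffles preserve composition as promised", {
  expect_equal(shuffle_null(rna_seq("a", "AAAA"), "mononucleotide",
                            rng_seed = 3L)$residues, "AAAA")
  expect_equal(shuffle_null(rna_seq("a", "AAAA"), "dinucleotide",
                            rng_seed = 3L)$residues, "AAAA")
  dinuc_counts <- function(res) {
    ch <- strsplit(res, "")[[1L]]
    table(paste0(ch[-length(ch)], ch[-1L]))
  }
  set.seed(606)
  for (rep in 1:20) {
    res <- random_rna(sample(10:60, 1))
    s <- rna_seq("r", res)
    mono <- shuffle_null(s, "mononucleotide", rng_seed = rep)
    expect_equal(sort(strsplit(mono$residues, "")[[1L]]),
                 sort(strsplit(res, "")[[1L]]))
    di <- shuffle_null(s, "dinucleotide", rng_seed = rep)
    expect_equal(dinuc_counts(di$residues), dinuc_counts(res))
    expect_equal(substr(di$residues, 1, 1), substr(res, 1, 1))
    n <- nchar(res)
    expect_equal(substr(di$residues, n, n), substr(res, n, n))
  }
  expect_error(shuffle_null(rna_seq("x", "A"), "dinucleotide", rng_seed = 1L),
               "at least 2")
})

test_that("shuffle hit rates are a measured fraction in [0, 1]", {
  sim <- plant_motif(motif_spec(5, 1, 1), 80L, rng_seed = 77L)
  hr <- shuffle_hit_rate(sim$seq, n = 20L, mode = "mononucleotide",
                         rng_seed = 88L)
  expect_equal(hr$n, 20L)
  expect_equal(length(hr$regions_per_shuffle), 20L)
  expect_equal(hr$hit_rate, hr$n_hit / hr$n)
  expect_true(hr$hit_rate >= 0 && hr$hit_rate <= 1)
})

test_that("simulated alignments respect rates and match a recount oracle", {
  ref <- plant_motif(motif_spec(5, 0, 0), 60L, rng_seed = 14L)
  sites <- ref$truth$motif[1L] + sort(unlist(lapply(
    seq(0, by = 3, length.out = 5), function(o) o + 0:1)))
  # zero mutation rate: perfect persistence
  aln0 <- make_alignment(ref$seq, n_rows = 5L, mutation_rate = 0,
                         rng_seed = 2L)
  prof0 <- conservation_profile(aln0, "ref", ref$truth$motif,
                                sites = data.frame(pos = sites,
                                                   site = rep(c("A", "R"), 5)))
  expect_equal(prof0$persistence, 1)
  # persistence equals an independent per-row recount
  aln <- make_alignment(ref$seq, n_rows = 12L, mutation_rate = 0.15,
                        rng_seed = 4L)
  prof <- conservation_profile(aln, "ref", ref$truth$motif,
                               sites = data.frame(pos = sites,
                                                  site = rep(c("A", "R"), 5)))
  recount <- mean(vapply(aln$rows, function(r) {
    ch <- strsplit(r, "")[[1L]]
    all(ch[sites[c(TRUE, FALSE)]] == "A") &&
      all(ch[sites[c(FALSE, TRUE)]] %in% c("A", "G"))
  }, logical(1)))
  expect_equal(prof$persistence, recount)
  # protected motif columns stay more conserved than background columns
  alnp <- make_alignment(ref$seq, n_rows = 40L, mutation_rate = 0.5,
                         protect_motif = TRUE, protect = sites,
                         rng_seed = 6L)
  rows <- lapply(alnp$rows, function(r) strsplit(r, "")[[1L]])
  refc <- rows[[1L]]
  col_cons <- function(cols) mean(vapply(cols, function(cc)
    mean(vapply(rows, function(r) r[cc] == refc[cc], logical(1))),
    numeric(1)))
  bg_cols <- setdiff(seq_along(refc), sites)
  expect_gt(col_cons(sites), col_cons(bg_cols))
})
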