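# Binding-site prediction: seed anchors, hybrid alignment scoring,
# nearest-neighbor duplex energies, thresholding and overlap resolution.

test_that("an 8mer anchor is found at the manual reverse complement of the seed", {
  # miRNA positions 2-8 = GGAAUGU -> target site 5'-ACAUUCCA-3'
  mir <- paste0("C", "GGAAUGU", strrep("C", 14))
  target <- paste0(strrep("C", 20), "ACAUUCCA", strrep("C", 20))
  hits <- find_seed_sites(mir, target)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 21)
  expect_equal(hits$end, 28)
  expect_equal(hits$seed_class, "8mer")
})

test_that("a poly-A target yields no anchors for a non-U-only seed", {
  mir <- paste0("C", "GGAAUGU", strrep("C", 14))
  expect_equal(nrow(find_seed_sites(mir, strrep("A", 100))), 0)
})

test_that("short miRNAs and bad alphabets are rejected; T converts to U", {
  expect_error(find_seed_sites("ACGUACGUACGU", strrep("A", 50)), ">= 19")
  mir <- paste0("C", "GGAAUGU", strrep("C", 14))
  expect_error(find_seed_sites(mir, "ACGX"), "non-RNA")
  expect_warning(h <- find_seed_sites(mir, paste0(strrep("C", 10), "ACATTCCA")),
                 "converting to U")
})

test_that("seed anchors equal an exhaustive window-scan oracle on random pairs", {
  set.seed(19)
  for (i in 1:30) {
    mir <- random_rna(22)
    target <- random_rna(300)
    got <- find_seed_sites(mir, target)
    want <- seed_scan_oracle(mir, target)
    rownames(got) <- rownames(want) <- NULL
    expect_identical(got, want)
  }
})

test_that("reversing the target destroys its anchors", {
  mir <- paste0("C", "GGAAUGU", strrep("C", 14))
  target <- paste0(strrep("C", 20), "ACAUUCCA", strrep("C", 20))
  rev_target <- paste(rev(strsplit(target, "")[[1]]), collapse = "")
  expect_equal(nrow(find_seed_sites(mir, rev_target)), 0)
})

test_that("alignment scores follow the stated scheme with 5' dominance", {
  set.seed(5)
  # perfectly complementary 22-mer: 22 matches x5 plus doubled seed = 145
  mir <- random_rna(22)
  target <- revcomp_chr(mir)
  a <- find_seed_sites(mir, target)
  aln <- extend_alignment(mir, target, a[1, ])
  expect_equal(aln$score, 145)
  # seed-only pairing (positions 2-8), mismatching flanks: 7 x 10 = 70
  mir2 <- strrep("A", 22)
  target2 <- paste0(strrep("G", 10), strrep("U", 7), strrep("G", 10))
  a2 <- find_seed_sites(mir2, target2)
  aln2 <- extend_alignment(mir2, target2, a2[1, ])
  expect_equal(aln2$score, 70)
})

test_that("adding 3' complementarity never lowers the alignment score", {
  set.seed(23)
  for (i in 1:10) {
    mir <- random_rna(22)
    seed_site <- paste0(revcomp_chr(substr(mir, 2, 8)), "A")
    full_site <- paste0(revcomp_chr(substr(mir, 2, 22)), "A")
    flank <- random_rna(30)
    t_seed <- paste0(flank, seed_site, flank)
    t_full <- paste0(flank, full_site, flank)
    s_seed <- max(0, vapply(seq_len(nrow(find_seed_sites(mir, t_seed))),
                            function(r) extend_alignment(mir, t_seed,
                              find_seed_sites(mir, t_seed)[r, ])$score,
                            numeric(1)))
    s_full <- max(vapply(seq_len(nrow(find_seed_sites(mir, t_full))),
                         function(r) extend_alignment(mir, t_full,
                           find_seed_sites(mir, t_full)[r, ])$score,
                         numeric(1)))
    expect_gte(s_full, s_seed)
    expect_gte(s_full, 140)
  }
})

test_that("duplex energies are additive over the stack decomposition", {
  # two-pair helix: initiation + one 5'GC/3'CG stack (frozen table values)
  expect_equal(duplex_energy("GC", "CG"), 4.09 - 3.42, tolerance = 1e-12)
  # five-pair alternating G-C helix, hand summation of its four stacks
  expect_equal(duplex_energy("GCGCG", "CGCGC"),
               4.09 - 3.42 - 2.36 - 3.42 - 2.36, tolerance = 1e-12)
  # G:U wobble pairs stack
  expect_lt(duplex_energy("GGUC", "UCAG"), 4.09)
})

test_that("appending a G-C stack strictly stabilizes any helix", {
  helices <- list(c("GCAU", "CGUA"), c("AUGC", "UACG"), c("GGGG", "CCCC"))
  for (h in helices) {
    expect_lt(duplex_energy(paste0(h[1], "G"), paste0(h[2], "C")),
              duplex_energy(h[1], h[2]))
  }
})

test_that("duplexes without a 2-stack helix are rejected", {
  # isolated single pairs separated by a mismatch
  expect_true(is.na(duplex_energy("GAC", "CGG")))
  expect_error(duplex_energy("GC", "CGA"), "equal length")
})

test_that("internal loops are penalized linearly", {
  # two G-C helices around a 2x2 mismatch loop (A-A columns):
  # init + 2 stacks + opening penalty + 4 unpaired nt
  expect_equal(duplex_energy("GCAAGC", "CGAACG"),
               4.09 - 3.42 - 3.42 + 3.0 + 0.3 * 4, tolerance = 1e-12)
})

test_that("planted sites pass default thresholds with exact coordinates", {
  cfg <- sim_config(seed = 7)
  sim <- simulate_sequences(cfg)
  ps <- sim$truth$planted_sites
  pools <- c(mRNA_3UTR = "mrna", circRNA = "circrna", lncRNA = "lncrna")
  for (cls in unique(ps$target_class)) {
    sub <- ps[ps$target_class == cls, ]
    got <- predict_targets(sim$sequences$mirna,
                           sim$sequences[[pools[[cls]]]], cls)
    for (i in seq_len(nrow(sub))) {
      expect_true(any(got$mirna == sub$mirna[i] & got$target == sub$target[i] &
                        got$start == sub$start[i] & got$end == sub$end[i]),
                  label = sprintf("site %s on %s recovered", sub$mirna[i],
                                  sub$target[i]))
    }
    expect_true(all(got$energy <= -10))
  }
})

test_that("a sponge with five planted sites yields exactly five predictions", {
  cfg <- sim_config(n_triples_planted = 1, sites_per_pair = 5,
                    sponge_length = 800, seed = 33)
  sim <- simulate_sequences(cfg)
  tri <- sim$truth$planted_triples[1, ]
  sponge_pool <- if (tri$sponge_class == "circRNA") "circrna" else "lncrna"
  got <- predict_targets(sim$sequences$mirna[tri$mirna],
                         sim$sequences[[sponge_pool]][tri$sponge],
                         tri$sponge_class)
  expect_equal(nrow(got), 5)
})

test_that("an infinite score threshold empties the output", {
  cfg <- sim_config(n_triples_planted = 2, seed = 11)
  sim <- simulate_sequences(cfg)
  got <- predict_targets(sim$sequences$mirna, sim$sequences$mrna,
                         "mRNA_3UTR", min_score = Inf)
  expect_equal(nrow(got), 0)
  expect_warning(predict_targets(character(0), character(0), "mRNA_3UTR"),
                 "empty input")
})

test_that("circRNA scanning finds back-splice-spanning sites modulo length", {
  set.seed(61)
  mir <- random_rna(22)
  site <- paste0(revcomp_chr(substr(mir, 2, 22)), "A")
  circ <- random_rna(100)
  # place the 22-nt site wrapping the junction: starts at position 90
  part1 <- substr(site, 1, 11); part2 <- substr(site, 12, 22)
  circ <- paste0(part2, substr(circ, 12, 89), part1)
  stopifnot(nchar(circ) == 100)
  got <- predict_targets(stats::setNames(mir, "m"),
                         stats::setNames(circ, "c"), "circRNA")
  expect_gte(nrow(got), 1)
  # seed span starts at ((90 + 14 - 1) mod 100) + 1 = 4
  expect_true(4 %in% got$start)
})
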