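test_that("the neighbourhood window spans 3 kb each side, clipped at edges", {
  set.seed(2)
  rec <- gbk_record("r", random_dna(20000))
  nb <- extract_neighborhood(rec, c(5001L, 6200L))   # [5000, 6200) 0-based
  expect_identical(nb$window, c(2000L, 9200L))
  nb2 <- extract_neighborhood(rec, c(1001L, 2200L))
  expect_identical(nb2$window, c(0L, 5200L))
  # strand-independent arithmetic
  rec3 <- gbk_record("r3", random_dna(20000), list(
    list(type = "CDS", start = 5001L, end = 6200L, strand = "-",
         qualifiers = c(protein_id = "X.1"))))
  expect_identical(extract_neighborhood(rec3, "X.1")$window,
                   c(2000L, 9200L))
  expect_error(extract_neighborhood(rec3, "missing.1"), "not found")
})

test_that("planted ORFs are recovered with exact coordinates; length bounds hold", {
  set.seed(5)
  aa20 <- paste0("M", paste(sample(setdiff(AA20, "M"), 19, TRUE),
                            collapse = ""))
  nt <- atropomine:::orf_nt(aa20)               # 20 aa + stop = 63 nt
  aa9 <- paste0("M", random_protein(8))
  aa41 <- paste0("M", paste(sample(setdiff(AA20, "M"), 40, TRUE),
                            collapse = ""))
  seq <- random_dna(2000)
  seq <- atropomine:::splice(seq, 300L, nt)
  seq <- atropomine:::splice(seq, 700L, atropomine:::orf_nt(aa9))
  seq <- atropomine:::splice(seq, 1000L, atropomine:::orf_nt(aa41))
  nb <- orf_test_neighborhood(seq)
  orfs <- scan_orfs(nb)
  planted <- orfs[orfs$start == 300L, , drop = FALSE]
  expect_identical(nrow(planted), 1L)
  expect_identical(planted$end, 300L + 63L)
  expect_identical(planted$strand, "+")
  expect_identical(planted$aa_seq, aa20)
  expect_false(any(orfs$start == 700L & orfs$end == 730L))    # 9 aa
  expect_false(any(orfs$start == 1000L & orfs$end == 1126L))  # 41 aa
})

test_that("the six-frame scan matches a brute-force oracle", {
  set.seed(17)
  for (i in 1:25) {
    seq <- random_dna(sample(100:1500, 1), gc = runif(1, 0.3, 0.7))
    nb <- orf_test_neighborhood(seq)
    got <- scan_orfs(nb)[, c("start", "end", "strand", "aa_seq")]
    rownames(got) <- NULL
    want <- brute_force_orfs(seq, 0L)
    rownames(want) <- NULL
    expect_identical(got, want, info = paste("case", i))
  }
})

test_that("the aromatic-core rule inspects adjacent pairs in the last six residues", {
  expect_true(apply_core_rule("SWYQWL"))
  expect_true(apply_core_rule("TWFIWYS"))   # last six WFIWYS: W-F adjacent
  expect_false(apply_core_rule("ASGIGL"))
  expect_false(apply_core_rule("AWAWAW"))   # aromatics never adjacent
  # aromatic pair in the leader does not satisfy the core rule
  expect_false(apply_core_rule("WWAAAAASGIGL"))
})

test_that("the motif rule returns the leftmost allowed motif", {
  lead <- paste0("MAAA", "PSLK", strrep("A", 8), "KSLK", "AACLE")
  expect_identical(apply_motif_rule(lead), "PSLK")
  expect_identical(apply_motif_rule("MAAAKSLRAAA"), NA_character_)
  pre <- paste0(strrep("A", 16), "KSLK", "SWYQWL")
  expect_identical(apply_motif_rule(pre), "KSLK")
  expect_identical(apply_motif_rule("AAKPLKAA", motif_set("KPLK")), "KPLK")
})

test_that("CDS overlap removes ORFs except tryptorubin-family precursors", {
  orfs <- data.frame(start = c(100L, 300L, 900L), end = c(160L, 360L, 960L),
                     strand = "+", start_codon = "ATG",
                     aa_seq = "M", stringsAsFactors = FALSE)
  ann <- list(
    list(type = "CDS", start = 131L, end = 500L, strand = "+",
         qualifiers = c(product = "cytochrome P450")),
    list(type = "CDS", start = 901L, end = 950L, strand = "-",
         qualifiers = c(product = "tryptorubin family RiPP precursor CDS")))
  kept <- filter_cds_overlap(orfs, ann)
  expect_identical(kept$start, c(900L))
  # intergenic ORF is retained when no CDS overlaps
  expect_identical(nrow(filter_cds_overlap(orfs[1, ], ann[2])), 1L)
})

test_that("nested same-stop candidates collapse to the shortest start", {
  cand <- data.frame(start = c(100L, 82L, 200L),
                     end = c(172L, 172L, 272L),
                     strand = c("+", "+", "-"), stringsAsFactors = FALSE)
  out <- deduplicate_nested(cand)
  expect_identical(nrow(out), 2L)
  kept <- out[out$strand == "+", ]
  expect_identical(kept$start, 100L)           # 24-aa form discarded
  expect_identical(kept$alt_starts, "82")
  # same stop coordinate on opposite strands: both kept
  cand2 <- data.frame(start = c(100L, 100L), end = c(172L, 160L),
                      strand = c("+", "-"), stringsAsFactors = FALSE)
  expect_identical(nrow(deduplicate_nested(cand2)), 2L)
  # single candidate unchanged
  one <- deduplicate_nested(cand[3, ])
  expect_identical(one$start, 200L)
})

test_that("rule filters are pure and order-independent", {
  set.seed(8)
  g <- generate_neighborhood(neighborhood_spec(seed = 31))
  nb <- extract_neighborhood(g$record, g$anchor_protein_id)
  orfs <- filter_cds_overlap(scan_orfs(nb), nb$annotations)
  core_then_motif <- orfs[apply_core_rule(orfs$aa_seq), ]
  core_then_motif <-
    core_then_motif[!is.na(apply_motif_rule(core_then_motif$aa_seq)), ]
  motif_then_core <- orfs[!is.na(apply_motif_rule(orfs$aa_seq)), ]
  motif_then_core <-
    motif_then_core[apply_core_rule(motif_then_core$aa_seq), ]
  expect_identical(core_then_motif, motif_then_core)
})

test_that("GC content excludes ambiguous bases and is strand-invariant", {
  expect_equal(gc_content("GGCC"), 1.0)
  expect_equal(gc_content("ATAT"), 0.0)
  expect_equal(gc_content("GCAT"), 0.5)
  expect_equal(gc_delta(gc_content("GCAT"), 0.70), -0.20)
  expect_equal(gc_content("GCNNNAT"), 0.5)
  expect_error(gc_content("NNN"), "unambiguous")
  set.seed(3)
  for (i in 1:10) {
    s <- random_dna(sample(10:200, 1), gc = runif(1))
    expect_equal(gc_content(s), gc_content(atropomine:::revcomp(s)))
  }
})
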