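test_that("generators are byte-deterministic under a fixed seed", {
  f1 <- generate_family(family_spec(n_positive = 5, n_negative = 5, seed = 8))
  f2 <- generate_family(family_spec(n_positive = 5, n_negative = 5, seed = 8))
  expect_identical(f1, f2)
  g1 <- generate_neighborhood(neighborhood_spec(seed = 8))
  g2 <- generate_neighborhood(neighborhood_spec(seed = 8))
  expect_identical(g1, g2)
  f3 <- generate_family(family_spec(n_positive = 5, n_negative = 5, seed = 9))
  expect_false(identical(f1$positives, f3$positives))
})

test_that("planted signatures separate positives from negatives segment-wise", {
  spec <- family_spec(n_positive = 10, n_negative = 10, seed = 4)
  fam <- generate_family(spec)
  seg_start <- c(1L, spec$cut_positions + 1L)
  seg_end <- c(spec$cut_positions, spec$backbone_length)
  for (sg in spec$signatures) {
    pos_seg <- vapply(fam$positives, function(p) reduce_sequence(
      substr(p, seg_start[sg$segment], seg_end[sg$segment])), character(1))
    neg_seg <- vapply(fam$negatives, function(p) reduce_sequence(
      substr(p, seg_start[sg$segment], seg_end[sg$segment])), character(1))
    expect_true(all(grepl(sg$kmer, pos_seg, fixed = TRUE)))
    expect_false(any(grepl(sg$kmer, neg_seg, fixed = TRUE)))
  }
})

test_that("zero mutation rate yields signature-bearing near-clones", {
  spec <- family_spec(n_positive = 4, n_negative = 2, seed = 6,
                      mutation_rate = 0)
  fam <- generate_family(spec)
  expect_identical(length(unique(fam$positives)), 1L)
  expect_identical(length(unique(fam$negatives)), 1L)
  expect_false(identical(fam$positives[[1]], fam$negatives[[1]]))
})

test_that("an unplantable signature is rejected", {
  expect_error(generate_family(family_spec(
    seed = 1, signatures = list(list(segment = 5L, kmer = "FKDS")),
    backbone_length = 400L, cut_positions = c(92L, 192L, 275L, 395L))),
    "does not fit")
})

test_that("colliding planted elements are rejected", {
  expect_error(generate_neighborhood(
    neighborhood_spec(seed = 3, precursor_offset = 900L)), "collide")
})

test_that("the truth precursor satisfies both rules at the expected position", {
  g <- generate_neighborhood(neighborhood_spec(seed = 23, motif = "KSLK",
                                               core = "SWYQWL"))
  expect_true(apply_core_rule(g$truth$aa_seq))
  expect_identical(apply_motif_rule(g$truth$aa_seq), "KSLK")
  expect_identical(substr(g$truth$aa_seq, 17, 20), "KSLK")
  expect_identical(substr(g$truth$aa_seq, 21, 26), "SWYQWL")
})

test_that("the precursor search recovers exactly the planted truth", {
  g <- generate_neighborhood(neighborhood_spec(seed = 44))
  nb <- extract_neighborhood(g$record, g$anchor_protein_id)
  found <- find_precursors(nb, rule_mode = "both")
  expect_identical(nrow(found), 1L)
  expect_identical(found$start, g$truth$start)
  expect_identical(found$end, g$truth$end)
  expect_identical(found$strand, g$truth$strand)
  expect_identical(found$aa_seq, g$truth$aa_seq)
  expect_identical(found$core, g$truth$core)
  expect_identical(found$matched_motif, g$truth$motif)
  # no decoy coordinates appear in the result
  expect_false(any(found$start %in% g$decoys$start))
})

test_that("decoys violate exactly the advertised rule", {
  g <- generate_neighborhood(neighborhood_spec(seed = 51))
  d <- g$decoys
  short <- d[d$violates == "min_length", ]
  expect_lt(nchar(short$aa_seq), 10L)
  expect_true(apply_core_rule(short$aa_seq))
  expect_false(is.na(apply_motif_rule(short$aa_seq)))
  long <- d[d$violates == "max_length", ]
  expect_gt(nchar(long$aa_seq), 40L)
  nomotif <- d[d$violates == "leader_motif", ]
  expect_true(is.na(apply_motif_rule(nomotif$aa_seq)))
  expect_true(apply_core_rule(nomotif$aa_seq))
  nocore <- d[d$violates == "aromatic_core", ]
  expect_false(apply_core_rule(nocore$aa_seq))
  expect_false(is.na(apply_motif_rule(nocore$aa_seq)))
})

test_that("a minus-strand truth precursor is recovered in record coordinates", {
  g <- generate_neighborhood(neighborhood_spec(seed = 61,
                                               precursor_strand = "-"))
  nb <- extract_neighborhood(g$record, g$anchor_protein_id)
  found <- find_precursors(nb, rule_mode = "both")
  expect_identical(nrow(found), 1L)
  expect_identical(found$strand, "-")
  expect_identical(found$start, g$truth$start)
  expect_identical(found$end, g$truth$end)
  expect_identical(found$aa_seq, g$truth$aa_seq)
})
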