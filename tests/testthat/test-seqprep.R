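test_that("reference cut positions map through self- and shifted alignments", {
  set.seed(7)
  ref <- random_protein(430)
  scheme <- reference_scheme(ref)

  self <- segment_by_reference(ref, scheme)
  expect_identical(self$query_boundaries, c(92L, 192L, 275L, 395L))
  expect_identical(unname(nchar(self$segments)),
                   c(92L, 100L, 83L, 120L, 430L - 395L))

  prefixed <- paste0(random_protein(10), ref)
  expect_identical(segment_by_reference(prefixed, scheme)$query_boundaries,
                   c(102L, 202L, 285L, 405L))
})

test_that("a cut inside a query deletion anchors to the nearest left position", {
  set.seed(7)
  ref <- random_protein(430)
  scheme <- reference_scheme(ref)
  # residues 90-95 deleted: the 92 cut falls in the gap and maps to the
  # query position aligned to reference residue 89
  query <- paste0(substr(ref, 1, 89), substr(ref, 96, 430))
  b <- segment_by_reference(query, scheme)$query_boundaries
  expect_identical(b, c(89L, 186L, 269L, 389L))
})

test_that("segment concatenation reproduces any query and boundaries are monotone", {
  set.seed(42)
  ref <- random_protein(430)
  scheme <- reference_scheme(ref)
  for (i in 1:15) {
    q <- strsplit(ref, "")[[1L]]
    # random substitutions, a deletion and an insertion
    subs <- sample(length(q), 20)
    q[subs] <- sample(AA20, 20, TRUE)
    del <- sample(50:400, 1)
    q <- q[-seq(del, del + sample(3:12, 1))]
    ins_at <- sample(seq_along(q), 1)
    q <- append(q, sample(AA20, sample(2:8, 1), TRUE), after = ins_at)
    q <- paste(q, collapse = "")
    seg <- segment_by_reference(q, scheme)
    expect_identical(paste(seg$segments, collapse = ""), q)
    expect_false(is.unsorted(seg$query_boundaries))
    expect_lte(max(seg$query_boundaries), nchar(q))
  }
})

test_that("segmentation rejects degenerate queries", {
  set.seed(7)
  scheme <- reference_scheme(random_protein(430))
  expect_error(segment_by_reference(random_protein(30), scheme),
               "minimum alignable length")
  expect_error(segment_by_reference("MKT1AYI", scheme), "non-amino-acid")
})

test_that("reduced-alphabet recoding groups residues and preserves length", {
  expect_identical(reduce_sequence(""), "")
  expect_identical(reduce_sequence("WYF"), "FFF")
  expect_identical(reduce_sequence("KRH"), "KKK")
  expect_identical(reduce_sequence("X"), "X")
  expect_error(reduce_sequence("WY1"), "alphabet|amino")
  set.seed(1)
  for (i in 1:20) {
    s <- random_protein(sample(1:80, 1))
    r <- reduce_sequence(s)
    expect_identical(nchar(r), nchar(s))
    # group symbols are fixed points: reducing twice equals reducing once
    expect_identical(reduce_sequence(r), r)
  }
})

test_that("greedy dereplication honours the identity threshold", {
  s <- random_protein(100)
  expect_length(dereplicate(c(a = s, b = s)), 1L)
  ch <- strsplit(s, "")[[1L]]
  ch[seq(1, 100, by = 10)] <- vapply(ch[seq(1, 100, by = 10)], function(x)
    sample(setdiff(AA20, x), 1), character(1))
  diverged <- paste(ch, collapse = "")
  expect_length(dereplicate(c(a = s, b = diverged)), 2L)  # identity 0.90
  expect_length(dereplicate(c(only = s)), 1L)
})

test_that("dereplication is idempotent and covers all inputs (all-pairs oracle)", {
  set.seed(13)
  founders <- replicate(3, random_protein(120))
  seqs <- unlist(lapply(founders, function(f) {
    vapply(1:10, function(i) {
      ch <- strsplit(f, "")[[1L]]
      k <- sample(0:3, 1)
      if (k > 0) {
        at <- sample(length(ch), k)
        ch[at] <- vapply(ch[at], function(x)
          sample(setdiff(AA20, x), 1), character(1))
      }
      paste(ch, collapse = "")
    }, character(1))
  }))
  names(seqs) <- sprintf("s%02d", seq_along(seqs))
  reps <- dereplicate(seqs)
  expect_identical(dereplicate(reps), reps)
  # coverage: every sequence within threshold of some representative
  for (s in seqs) {
    ids <- vapply(reps, function(r) pairwise_identity(s, r), numeric(1))
    expect_gte(max(ids), 0.95)
  }
  # founders are mutually below threshold
  if (length(reps) > 1L) {
    for (i in seq_len(length(reps) - 1L)) {
      for (j in seq(i + 1L, length(reps))) {
        expect_lt(pairwise_identity(reps[[i]], reps[[j]]), 0.95)
      }
    }
  }
})

test_that("the classification length filter drops out-of-band sequences", {
  seqs <- c(short = random_protein(250), ok = random_protein(350),
            long = random_protein(500))
  out <- dereplicate(seqs, derep_params())
  expect_identical(names(out), "ok")
})

test_that("FASTA round-trip preserves ids and residues", {
  path <- withr::local_tempfile(fileext = ".fasta")
  seqs <- c("P450_A some description" = random_protein(60),
            "P450_B" = random_protein(45))
  write_protein_fasta(seqs, path)
  back <- read_protein_fasta(path)
  expect_identical(back, seqs)
})
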