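seg5 <- function(...) {
  x <- c(...)
  length(x) <- 5L
  x[is.na(x)] <- ""
  x
}

test_that("the at-least-half rule decides feature retention", {
  # 2 positives: present in 1 of 2 is retained (1 >= ceil(0.5*2))
  sp <- build_feature_space(list(seg5("AAKK"), seg5("DDDD")))
  expect_true("AAKK" %in% sp$per_segment_features[[1L]])
  # 3 positives: present in 1 of 3 is dropped (1 < ceil(1.5) = 2)
  sp3 <- build_feature_space(list(seg5("AAKK"), seg5("DDDD"), seg5("SSSS")))
  expect_false("AAKK" %in% sp3$per_segment_features[[1L]])
  # never retained when absent from all positives
  expect_false("FFFF" %in% unlist(sp$per_segment_features))
  # wildcard-containing k-mers are excluded
  spx <- build_feature_space(list(seg5("AXKK"), seg5("AXKK")))
  expect_length(spx$per_segment_features[[1L]], 0L)
  expect_error(build_feature_space(list(seg5("AAAA"))), "at least 2")
})

test_that("retained k-mers are exactly those passing the half rule (exhaustive)", {
  set.seed(21)
  reduce_rand <- function(n) paste(sample(c("A", "F", "K", "D", "S", "G"),
                                          n, TRUE), collapse = "")
  positives <- lapply(1:7, function(i)
    vapply(1:5, function(s) reduce_rand(sample(10:40, 1)), character(1)))
  sp <- build_feature_space(positives)
  min_count <- ceiling(0.5 * 7)
  for (s in 1:5) {
    segs <- vapply(positives, `[[`, character(1), s)
    all_kmers <- unique(unlist(lapply(segs, function(x) {
      n <- nchar(x)
      substring(x, 1:(n - 3L), 4:n)
    })))
    presence <- vapply(all_kmers, function(k)
      sum(grepl(k, segs, fixed = TRUE)), integer(1))
    expect_setequal(sp$per_segment_features[[s]],
                    all_kmers[presence >= min_count])
  }
})

test_that("vectorization counts overlapping occurrences", {
  sp <- build_feature_space(list(seg5("AAAA"), seg5("AAAA")))
  expect_identical(unname(vectorize(seg5("AAAAA"), sp)[1L, 1L]), 2L)
  expect_identical(unname(vectorize(seg5(""), sp)[1L, 1L]), 0L)
  expect_identical(unname(vectorize(seg5("AAA"), sp)[1L, 1L]), 0L)
  expect_error(vectorize(c("AAAA", "AAAA"), sp), "segment count")
})

test_that("vectorization matches the naive sliding-window oracle", {
  set.seed(33)
  symbols <- c("A", "F", "K", "D", "S", "G")
  for (i in 1:40) {
    segs <- lapply(1:4, function(j)
      vapply(1:5, function(s)
        paste(sample(symbols, sample(5:30, 1), TRUE), collapse = ""),
        character(1)))
    sp <- build_feature_space(segs[1:2])
    if (sum(lengths(sp$per_segment_features)) == 0L) next
    x <- vectorize(segs, sp)
    for (r in 1:4) {
      expected <- unlist(lapply(1:5, function(s)
        vapply(sp$per_segment_features[[s]], function(k)
          naive_kmer_count(segs[[r]][s], k), integer(1))),
        use.names = FALSE)
      expect_identical(unname(x[r, ]), expected)
    }
  }
})

test_that("random oversampling equalises classes and conserves samples", {
  x <- matrix(seq_len(24), ncol = 2)
  y <- rep(c("pos", "neg"), c(3, 9))
  bal <- oversample_balance(x, y, seed = 4)
  expect_identical(as.integer(table(bal$y)), c(9L, 9L))
  # original rows all retained, added rows drawn from the minority
  expect_identical(bal$x[1:12, ], x)
  expect_true(all(bal$x[13:18, 1] %in% x[1:3, 1]))
  # reproducible bit-for-bit
  expect_identical(oversample_balance(x, y, seed = 4), bal)
  # already balanced input is returned unchanged
  xb <- x[1:10, ]
  expect_identical(oversample_balance(xb, rep(c("pos", "neg"), 5),
                                      seed = 1)$x, xb)
  # single minority item is duplicated
  y14 <- rep(c("pos", "neg"), c(1, 4))
  b14 <- oversample_balance(x[1:5, ], y14, seed = 2)
  expect_identical(sum(b14$y == "pos"), 4L)
  expect_true(all(b14$x[b14$y == "pos", 1] == x[1, 1]))
  expect_error(oversample_balance(x, rep("pos", 12), 1), "two classes")
})

test_that("balanced accuracy is the mean of recall and specificity", {
  truth <- rep(c(TRUE, FALSE), each = 5)
  labels <- c(TRUE, TRUE, TRUE, TRUE, FALSE,   # recall 0.8
              FALSE, FALSE, FALSE, TRUE, TRUE) # specificity 0.6
  rep <- atropomine:::eval_report(truth, labels)
  expect_equal(rep$recall, 0.8)
  expect_equal(rep$specificity, 0.6)
  expect_equal(rep$balanced_accuracy, 0.7)
})

test_that("training rejects degenerate label sets", {
  x <- matrix(rnorm(40), ncol = 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  expect_error(train_classifier(x, rep("pos", 10)), "two classes")
})

test_that("positive calls use a strict score threshold and are monotone in it", {
  fit <- fit_small_family_model()
  res <- classify(fit$model, fit$x)
  expect_true(all(res$positive == (res$score > 0.15)))
  # an item is negative when the threshold equals its own score
  s <- res$score[which.max(res$score)]
  at_score <- classify(fit$model, fit$x, threshold = s)
  expect_false(any(at_score$score == s & at_score$positive))
  # raising the threshold never flips a label to positive, and never
  # changes the scores
  thresholds <- c(0.05, 0.15, 0.5, 0.9)
  prev <- rep(TRUE, nrow(res))
  for (th in thresholds) {
    r <- classify(fit$model, fit$x, threshold = th)
    expect_identical(r$score, res$score)
    expect_true(all(r$positive <= prev))
    prev <- r$positive
  }
})

test_that("a planted segment signature is learned perfectly at small n", {
  fit <- fit_small_family_model(seed = 9)
  expect_equal(fit$model$eval$f1_positive, 1.0)
})

test_that("refinement with no new sequences reproduces the feature space", {
  fit <- fit_small_family_model(seed = 15, n = 6)
  fam <- fit$fam
  ref1 <- iterate_training(fam$positives, character(0), fam$negatives,
                           fam$scheme, fam$alphabet)
  expect_identical(ref1$space$per_segment_features,
                   fit$space$per_segment_features)
  expect_equal(ref1$model$config$max_depth, 14L)
})

test_that("feature spaces survive JSON serialisation", {
  sp <- build_feature_space(list(seg5("AAKK", "DDDD"), seg5("AAKK", "DDDD")))
  path <- withr::local_tempfile(fileext = ".json")
  write_feature_space(sp, path)
  back <- read_feature_space(path)
  expect_identical(back$per_segment_features, sp$per_segment_features)
  expect_identical(back$k, sp$k)
})
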