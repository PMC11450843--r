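#' Build the segment-wise k-mer feature space from positive P450s
#'
#' For each of the five functional regions, every overlapping k-mer (in the
#' reduced alphabet) that occurs in at least `ceiling(min_positive_fraction
#' * n_positives)` of the positive training sequences' corresponding
#' segments is retained as a feature axis. K-mers containing the wildcard
#' symbol `X` are never retained. Retained k-mers are ordered
#' lexicographically within each segment for deterministic serialisation.
#'
#' @param positive_segments List of reduced segment vectors (one
#'   `character(5)` per positive sequence, e.g. from
#'   [segment_by_reference()] followed by [reduce_sequence()]).
#' @param k k-mer length, default 4.
#' @param min_positive_fraction Minimum fraction of positives a k-mer must
#'   occur in, default 0.5.
#' @return An object of class `kmer_feature_space`.
#' @export
build_feature_space <- function(positive_segments, k = 4L,
                                min_positive_fraction = 0.5) {
  n <- length(positive_segments)
  if (n < 2L) stop("at least 2 positive sequences are required")
  n_seg <- unique(lengths(positive_segments))
  if (length(n_seg) != 1L)
    stop("all sequences must carry the same number of segments")
  min_count <- ceiling(min_positive_fraction * n)
  feats <- lapply(seq_len(n_seg), function(s) {
    per_seq <- lapply(positive_segments, function(x) kgram_set(x[[s]], k))
    tab <- table(unlist(per_seq, use.names = FALSE))
    kept <- as.character(names(tab)[tab >= min_count])
    kept <- kept[!grepl("X", kept, fixed = TRUE)]
    sort(kept, method = "radix")
  })
  structure(list(k = as.integer(k),
                 min_positive_fraction = min_positive_fraction,
                 n_positives = n,
                 per_segment_features = feats),
            class = "kmer_feature_space")
}

#' @export
print.kmer_feature_space <- function(x, ...) {
  cat("kmer_feature_space: k =", x$k, ",",
      sum(lengths(x$per_segment_features)), "features over",
      length(x$per_segment_features), "segments (built from",
      x$n_positives, "positives)\n")
  invisible(x)
}

feature_names <- function(space) {
  unlist(lapply(seq_along(space$per_segment_features), function(s) {
    f <- space$per_segment_features[[s]]
    if (length(f)) paste0("s", s, "_", f) else character(0)
  }), use.names = FALSE)
}

count_kmers <- function(s, kmers, k) {
  out <- integer(length(kmers))
  names(out) <- kmers
  n <- nchar(s)
  if (n >= k && length(kmers)) {
    grams <- substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
    tab <- table(grams)
    hit <- intersect(names(tab), kmers)
    out[hit] <- as.integer(tab[hit])
  }
  out
}

#' Vectorize a segmented, reduced protein against a feature space
#'
#' Each entry of the result is the overlapping-substring occurrence count
#' of one retained k-mer in the corresponding segment.
#'
#' @param segments `character(5)` of reduced segment strings, or a list of
#'   such vectors (one row per sequence in the result).
#' @param space A [build_feature_space()] result.
#' @return An integer matrix with one row per input sequence and one
#'   column per (segment, k-mer) feature.
#' @export
vectorize <- function(segments, space) {
  stopifnot(inherits(space, "kmer_feature_space"))
  if (!is.list(segments)) segments <- list(segments)
  n_seg <- length(space$per_segment_features)
  bad <- lengths(segments) != n_seg
  if (any(bad)) stop("segment count mismatch with the feature space")
  rows <- lapply(segments, function(x) {
    unlist(lapply(seq_len(n_seg), function(s) {
      count_kmers(x[[s]], space$per_segment_features[[s]], space$k)
    }), use.names = FALSE)
  })
  m <- do.call(rbind, rows)
  colnames(m) <- feature_names(space)
  rownames(m) <- names(segments)
  m
}

#' Random oversampling to balance two classes
#'
#' The minority class is upsampled with replacement until both classes
#' have the majority count; every original row is retained, so the set of
#' distinct samples is conserved.
#'
#' @param x Feature matrix (rows = samples).
#' @param y Labels (two classes).
#' @param seed Integer seed; the operation is reproducible bit-for-bit.
#' @return List with balanced `x` and `y`.
#' @export
oversample_balance <- function(x, y, seed = 1L) {
  y <- as.factor(y)
  if (nlevels(droplevels(y)) != 2L) stop("exactly two classes are required")
  y <- droplevels(y)
  counts <- table(y)
  if (counts[1L] == counts[2L]) return(list(x = x, y = y))
  minority <- names(counts)[which.min(counts)]
  need <- max(counts) - min(counts)
  idx_min <- which(y == minority)
  extra <- withr::with_seed(seed,
    sample(idx_min, need, replace = TRUE))
  list(x = rbind(x, x[extra, , drop = FALSE]),
       y = factor(c(as.character(y), as.character(y)[extra]),
                  levels = levels(y)))
}

#' Random-forest classifier configuration
#'
#' @param n_trees Number of trees (default 100).
#' @param max_depth Maximum tree depth: 10 for a first training round, 14
#'   for a refinement round on an enlarged positive set.
#' @param min_samples_leaf Minimum samples per terminal leaf (default 1).
#' @param split_fraction Training share of the 60:40 train/validation
#'   split.
#' @param score_threshold Vote-fraction threshold above which (strictly) a
#'   query is called positive. Default 0.15.
#' @param seed Integer seed controlling the split and the forest.
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(n_trees = 100L, max_depth = 10L,
                              min_samples_leaf = 1L, split_fraction = 0.6,
                              score_threshold = 0.15, seed = 1L) {
  if (split_fraction <= 0 || split_fraction >= 1)
    stop("split_fraction must be in (0, 1)")
  if (score_threshold <= 0 || score_threshold >= 1)
    stop("score_threshold must be in (0, 1)")
  if (max_depth < 1L) stop("max_depth must be >= 1")
  structure(list(n_trees = as.integer(n_trees),
                 max_depth = as.integer(max_depth),
                 min_samples_leaf = as.integer(min_samples_leaf),
                 split_fraction = split_fraction,
                 score_threshold = score_threshold,
                 seed = as.integer(seed)),
            class = "classifier_config")
}

stratified_split <- function(y, fraction, seed) {
  idx <- withr::with_seed(seed, {
    unlist(lapply(levels(y), function(lv) {
      i <- which(y == lv)
      sample(i, max(1L, round(fraction * length(i))))
    }), use.names = FALSE)
  })
  sort(idx)
}

eval_report <- function(truth, labels) {
  tp <- sum(truth & labels)
  fp <- sum(!truth & labels)
  tn <- sum(!truth & !labels)
  fn <- sum(truth & !labels)
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  specificity <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_
  list(f1_positive = f1, recall = recall, specificity = specificity,
       balanced_accuracy = (recall + specificity) / 2,
       TP = tp, FP = fp, TN = tn, FN = fn)
}

#' Train the P450 random-forest classifier
#'
#' Splits the (balanced) data 60:40 stratified by class, fits a random
#' forest on the training share, and evaluates it on the held-out share.
#' The score of an item is the fraction of trees voting for the positive
#' class.
#'
#' @param x Feature matrix from [vectorize()] (balanced, e.g. via
#'   [oversample_balance()]).
#' @param y Labels; the positive class is identified by `positive`.
#' @param config A [classifier_config()].
#' @param positive Label value denoting the positive class.
#' @return An object of class `p450_classifier` with elements `forest`,
#'   `config`, `positive`, `feature_names` and `eval` (the held-out
#'   evaluation report).
#' @export
train_classifier <- function(x, y, config = classifier_config(),
                             positive = "pos") {
  stopifnot(inherits(config, "classifier_config"))
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2L) stop("exactly two classes are required for training")
  if (!positive %in% levels(y)) stop("positive label not present in y")
  if (ncol(x) == 0L) stop("empty feature space: nothing to train on")
  tr <- stratified_split(y, config$split_fraction, config$seed)
  if (nlevels(droplevels(y[tr])) != 2L || nlevels(droplevels(y[-tr])) != 2L)
    stop("degenerate split: a class is missing from train or validation")
  df <- as.data.frame(x[tr, , drop = FALSE])
  fit <- ranger::ranger(x = df, y = y[tr],
                        num.trees = config$n_trees,
                        max.depth = config$max_depth,
                        min.node.size = config$min_samples_leaf,
                        seed = config$seed,
                        num.threads = 1L)
  model <- structure(list(forest = fit, config = config,
                          positive = positive,
                          feature_names = colnames(x)),
                     class = "p450_classifier")
  scores <- classifier_scores(model, x[-tr, , drop = FALSE])
  labels <- scores > config$score_threshold
  model$eval <- eval_report(y[-tr] == positive, labels)
  model
}

#' @export
print.p450_classifier <- function(x, ...) {
  cat("p450_classifier:", x$config$n_trees, "trees, depth",
      x$config$max_depth, "\n")
  if (!is.null(x$eval))
    cat("  held-out f1 =", round(x$eval$f1_positive, 3),
        "balanced accuracy =", round(x$eval$balanced_accuracy, 3), "\n")
  invisible(x)
}

classifier_scores <- function(model, x) {
  df <- as.data.frame(x[, model$feature_names, drop = FALSE])
  pred <- stats::predict(model$forest, data = df, predict.all = TRUE,
                         num.threads = 1L)$predictions
  pos_idx <- match(model$positive, model$forest$forest$levels)
  rowMeans(pred == pos_idx)
}

#' Score and label query P450s
#'
#' @param model A trained [train_classifier()] model.
#' @param x Feature matrix for the queries.
#' @param threshold Score threshold; queries with vote fraction strictly
#'   greater than this are labelled positive. Defaults to the model's
#'   configured threshold.
#' @return Data frame with `id`, `score` and logical `positive`.
#' @export
classify <- function(model, x, threshold = model$config$score_threshold) {
  stopifnot(inherits(model, "p450_classifier"))
  scores <- classifier_scores(model, x)
  data.frame(id = if (is.null(rownames(x)))
               as.character(seq_len(nrow(x))) else rownames(x),
             score = scores, positive = scores > threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Refine the classifier with newly discovered positives
#'
#' Mining rounds feed back: new positives found by the precursor search
#' are merged into the positive training set (dereplicated against the
#' existing set), the feature space is rebuilt from the union, and the
#' forest is retrained with the refinement configuration (deeper trees).
#'
#' @param initial_positives,new_positives,negatives Named character
#'   vectors of protein sequences.
#' @param scheme A [reference_scheme()].
#' @param alphabet Reduced alphabet mapping.
#' @param config A [classifier_config()]; the refinement default uses
#'   depth 14.
#' @param derep A [derep_params()] for merging the positive sets.
#' @return List with `model`, `space` and the dereplicated `positives`.
#' @export
iterate_training <- function(initial_positives, new_positives, negatives,
                             scheme, alphabet = default_alphabet(),
                             config = classifier_config(max_depth = 14L),
                             derep = derep_params(length_filter = NULL)) {
  pool <- c(initial_positives, new_positives)
  positives <- dereplicate(pool, derep)
  seg_pos <- lapply(positives, function(s)
    reduce_segments(segment_by_reference(s, scheme), alphabet))
  seg_neg <- lapply(negatives, function(s)
    reduce_segments(segment_by_reference(s, scheme), alphabet))
  space <- build_feature_space(seg_pos)
  x <- vectorize(c(seg_pos, seg_neg), space)
  y <- factor(rep(c("pos", "neg"), c(length(seg_pos), length(seg_neg))),
              levels = c("neg", "pos"))
  bal <- oversample_balance(x, y, seed = config$seed)
  model <- train_classifier(bal$x, bal$y, config)
  list(model = model, space = space, positives = positives)
}

#' Serialise a feature space to JSON
#'
#' @param space A [build_feature_space()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_space <- function(space, path) {
  jsonlite::write_json(
    list(k = space$k,
         min_positive_fraction = space$min_positive_fraction,
         n_positives = space$n_positives,
         per_segment_features = space$per_segment_features),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a serialised feature space
#'
#' @param path Path written by [write_feature_space()].
#' @return A `kmer_feature_space` object.
#' @export
read_feature_space <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  feats <- lapply(j$per_segment_features, as.character)
  structure(list(k = as.integer(j$k),
                 min_positive_fraction = j$min_positive_fraction,
                 n_positives = as.integer(j$n_positives),
                 per_segment_features = feats),
            class = "kmer_feature_space")
}
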