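#' Assemble a pipeline run configuration
#'
#' Collects the paths and parameters shared by the pipeline commands.
#' All paths are local files; genome records are supplied as GenBank flat
#' files.
#'
#' @param reference_fasta FASTA with the single annotated reference P450.
#' @param positives_fasta,negatives_fasta Labelled training FASTAs.
#' @param query_fasta FASTA of P450s to classify.
#' @param genbank_files Character vector of GenBank flat files providing
#'   the genomic context of query P450s (matched by `protein_id`).
#' @param out_dir Output directory (created if absent).
#' @param cut_positions Reference cut positions.
#' @param alphabet Reduced alphabet mapping.
#' @param classifier A [classifier_config()].
#' @param derep A [derep_params()].
#' @param motifs A [motif_set()].
#' @param rule_mode Precursor rule mode: `"aromatic-core"`,
#'   `"leader-motif"` or `"both"`.
#' @param flank Neighbourhood flank in nt.
#' @param seed Integer seed (propagated into the classifier config).
#' @return An object of class `run_config`.
#' @export
run_config <- function(reference_fasta = NULL, positives_fasta = NULL,
                       negatives_fasta = NULL, query_fasta = NULL,
                       genbank_files = character(0), out_dir = ".",
                       cut_positions = c(92L, 192L, 275L, 395L),
                       alphabet = default_alphabet(),
                       classifier = classifier_config(),
                       derep = derep_params(length_filter = NULL),
                       motifs = motif_set(),
                       rule_mode = "both", flank = 3000L, seed = 1L) {
  classifier$seed <- as.integer(seed)
  structure(list(reference_fasta = reference_fasta,
                 positives_fasta = positives_fasta,
                 negatives_fasta = negatives_fasta,
                 query_fasta = query_fasta,
                 genbank_files = genbank_files, out_dir = out_dir,
                 cut_positions = as.integer(cut_positions),
                 alphabet = alphabet, classifier = classifier,
                 derep = derep, motifs = motifs, rule_mode = rule_mode,
                 flank = as.integer(flank), seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognised keys mirror the [run_config()] arguments; flat classifier
#' keys (`n_trees`, `max_depth`, `min_samples_leaf`, `split_fraction`,
#' `score_threshold`) and dereplication keys (`identity_threshold`,
#' `word_size`) are folded into the nested configs.
#'
#' @param path Path to a YAML file.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  cc <- classifier_config(
    n_trees = y$n_trees %||% 100L, max_depth = y$max_depth %||% 10L,
    min_samples_leaf = y$min_samples_leaf %||% 1L,
    split_fraction = y$split_fraction %||% 0.6,
    score_threshold = y$score_threshold %||% 0.15,
    seed = y$seed %||% 1L)
  dp <- derep_params(identity_threshold = y$identity_threshold %||% 0.95,
                     word_size = y$word_size %||% 5L,
                     length_filter = y$length_filter)
  run_config(reference_fasta = y$reference_fasta,
             positives_fasta = y$positives_fasta,
             negatives_fasta = y$negatives_fasta,
             query_fasta = y$query_fasta,
             genbank_files = unlist(y$genbank_files) %||% character(0),
             out_dir = y$out_dir %||% ".",
             cut_positions = unlist(y$cut_positions) %||%
               c(92L, 192L, 275L, 395L),
             classifier = cc, derep = dp,
             motifs = if (is.null(y$motifs)) motif_set() else
               motif_set(unlist(y$motifs)),
             rule_mode = y$rule_mode %||% "both",
             flank = y$flank %||% 3000L, seed = y$seed %||% 1L)
}

require_path <- function(path, what) {
  if (is.null(path)) stop("config is missing the ", what, " path")
  if (!file.exists(path)) stop(what, " file not found: ", path)
  path
}

segment_and_reduce_all <- function(seqs, scheme, alphabet) {
  lapply(seqs, function(s)
    reduce_segments(segment_by_reference(s, scheme), alphabet))
}

#' Train the classifier from configured FASTA inputs
#'
#' Reads the reference and the labelled training sets, dereplicates both,
#' segments and reduces every sequence, builds the feature space from the
#' positives, balances the classes by random oversampling, trains the
#' random forest, and writes `feature_space.json` and `eval.json` into the
#' output directory.
#'
#' @param config A [run_config()].
#' @return List with `model`, `space`, `scheme` and per-stage `counts`,
#'   invisibly.
#' @export
run_train <- function(config) {
  stopifnot(inherits(config, "run_config"))
  ref <- read_protein_fasta(require_path(config$reference_fasta,
                                         "reference FASTA"))
  pos <- read_protein_fasta(require_path(config$positives_fasta,
                                         "positive training FASTA"))
  neg <- read_protein_fasta(require_path(config$negatives_fasta,
                                         "negative training FASTA"))
  scheme <- reference_scheme(ref[[1L]], config$cut_positions)
  pos_d <- dereplicate(pos, config$derep)
  neg_d <- dereplicate(neg, config$derep)
  seg_pos <- segment_and_reduce_all(pos_d, scheme, config$alphabet)
  seg_neg <- segment_and_reduce_all(neg_d, scheme, config$alphabet)
  space <- build_feature_space(seg_pos)
  x <- vectorize(c(seg_pos, seg_neg), space)
  y <- factor(rep(c("pos", "neg"), c(length(seg_pos), length(seg_neg))),
              levels = c("neg", "pos"))
  bal <- oversample_balance(x, y, seed = config$seed)
  model <- train_classifier(bal$x, bal$y, config$classifier)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_feature_space(space, file.path(config$out_dir,
                                       "feature_space.json"))
  jsonlite::write_json(c(model$eval, seed = config$seed),
                       file.path(config$out_dir, "eval.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  counts <- list(positives_in = length(pos), negatives_in = length(neg),
                 positives_dereplicated = length(pos_d),
                 negatives_dereplicated = length(neg_d),
                 features = sum(lengths(space$per_segment_features)))
  invisible(list(model = model, space = space, scheme = scheme,
                 counts = counts))
}

#' Classify query P450s and mine neighbourhoods of the positives
#'
#' Scores every query against the trained model and, for each positive
#' call whose protein id matches an annotated CDS in the supplied GenBank
#' records, extracts the genomic neighbourhood and runs the precursor
#' search. Writes `classification.tsv`, one annotated region GenBank per
#' positive, `precursors.tsv` and `report.json`.
#'
#' @param config A [run_config()].
#' @param trained A [run_train()] result (model + space + scheme).
#' @return List with `classification`, `precursors` and the pipeline
#'   `report`, invisibly.
#' @export
run_mine <- function(config, trained) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  queries <- tryCatch(
    read_protein_fasta(require_path(config$query_fasta, "query FASTA")),
    error = function(e) {
      if (grepl("no sequences", conditionMessage(e)))
        stats::setNames(character(0), character(0)) else stop(e)
    })
  report <- list(queries = length(queries), classified_positive = 0L,
                 neighborhoods_scanned = 0L, orfs_considered = 0L,
                 precursors_found = 0L)
  cls <- data.frame(id = character(0), score = numeric(0),
                    positive = logical(0), stringsAsFactors = FALSE)
  precursors <- NULL
  if (length(queries)) {
    segs <- segment_and_reduce_all(queries, trained$scheme,
                                   config$alphabet)
    x <- vectorize(segs, trained$space)
    cls <- classify(trained$model, x)
    report$classified_positive <- sum(cls$positive)
    records <- list()
    for (f in config$genbank_files) records <- c(records, read_genbank(f))
    for (id in cls$id[cls$positive]) {
      acc <- strsplit(id, "\\s+")[[1L]][1L]
      nb <- NULL
      for (rec in records) {
        nb <- tryCatch(extract_neighborhood(rec, acc,
                                            flank = config$flank),
                       error = function(e) NULL)
        if (!is.null(nb)) break
      }
      if (is.null(nb)) {
        warning("query '", acc,
                "' not found in any GenBank record; skipped from the ",
                "precursor search")
        next
      }
      report$neighborhoods_scanned <- report$neighborhoods_scanned + 1L
      report$orfs_considered <- report$orfs_considered +
        nrow(scan_orfs(nb))
      found <- find_precursors(nb, rule_mode = config$rule_mode,
                               motifs = config$motifs)
      if (nrow(found)) {
        found$query <- acc
        found$record <- nb$record_id
        precursors <- rbind(precursors, found)
      }
      write_region_genbank(nb, found,
                           file.path(config$out_dir,
                                     paste0(gsub("[^A-Za-z0-9._-]", "_",
                                                 acc), "_region.gbk")))
    }
  }
  if (is.null(precursors)) {
    precursors <- data.frame(start = integer(0), end = integer(0),
                             strand = character(0),
                             start_codon = character(0),
                             aa_seq = character(0),
                             matched_motif = character(0),
                             alt_starts = character(0),
                             core = character(0), leader = character(0),
                             rule_mode = character(0),
                             query = character(0), record = character(0),
                             stringsAsFactors = FALSE)
  }
  report$precursors_found <- nrow(precursors)
  stopifnot(report$precursors_found <= max(report$orfs_considered,
                                           report$precursors_found))
  utils::write.table(cls, file.path(config$out_dir, "classification.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(precursors,
                     file.path(config$out_dir, "precursors.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(classification = cls, precursors = precursors,
                 report = report))
}

#' Predict ion candidates for a table of core peptides
#'
#' For each row of the cores table a [candidate_series()] is generated;
#' if observed masses are supplied each candidate within the ppm
#' tolerance is reported as a match.
#'
#' @param cores Data frame with columns `core`, and optionally
#'   `max_crosslinks` and `allow_n_truncations` per row, or the path of a
#'   TSV with those columns.
#' @param observed Optional numeric vector of observed m/z values.
#' @param tol_ppm Matching tolerance in ppm.
#' @param out Optional output TSV path.
#' @param max_crosslinks,allow_n_truncations Defaults for rows that do
#'   not carry their own values.
#' @return Data frame of candidates (plus `observed`/`ppm` columns when
#'   observed masses are supplied).
#' @export
run_masses <- function(cores, observed = NULL, tol_ppm = 5, out = NULL,
                       max_crosslinks = 3L, allow_n_truncations = 1L) {
  if (is.character(cores)) {
    cores <- utils::read.table(cores, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE)
  }
  rows <- list()
  for (i in seq_len(nrow(cores))) {
    res <- tryCatch({
      series <- candidate_series(
        cores$core[i],
        max_crosslinks = cores$max_crosslinks[i] %||na% max_crosslinks,
        allow_n_truncations =
          cores$allow_n_truncations[i] %||na% allow_n_truncations)
      series$core <- cores$core[i]
      if (!is.null(observed)) series <- match_observed(series, observed,
                                                       tol_ppm)
      series
    }, error = function(e) {
      warning("cores row ", i, " skipped: ", conditionMessage(e))
      NULL
    })
    if (!is.null(res)) rows[[length(rows) + 1L]] <- res
  }
  out_df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sequence = character(0), truncation = integer(0),
               n_crosslinks = integer(0), formula = character(0),
               mz = numeric(0), core = character(0),
               stringsAsFactors = FALSE)
  if (!is.null(out)) {
    df <- out_df
    df$mz <- sprintf("%.4f", df$mz)
    if ("ppm" %in% names(df)) df$ppm <- sprintf("%.2f", df$ppm)
    utils::write.table(df, out, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  out_df
}

`%||na%` <- function(a, b) {
  if (is.null(a) || length(a) == 0L || is.na(a)) b else a
}
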