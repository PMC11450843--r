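# Independent oracles and small fixture builders used across the suite.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_protein <- function(n) paste(sample(AA20, n, TRUE), collapse = "")

random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, TRUE, p), collapse = "")
}

# Naive sliding-window count of overlapping occurrences of `kmer` in `s`.
naive_kmer_count <- function(s, kmer) {
  k <- nchar(kmer)
  n <- nchar(s)
  if (n < k) return(0L)
  sum(vapply(seq_len(n - k + 1L), function(i)
    substr(s, i, i + k - 1L) == kmer, logical(1)))
}

# Brute-force six-frame ORF enumeration: walk codon by codon from every
# start-codon position to the first in-frame stop. Translation goes
# through Biostrings::translate (a code path the scanner does not use).
brute_force_orfs <- function(seq, win0, min_aa = 10L, max_aa = 40L) {
  starts <- c("ATG", "GTG", "TTG")
  stops <- c("TAA", "TAG", "TGA")
  one_strand <- function(s) {
    n <- nchar(s)
    hits <- list()
    for (p in seq_len(max(0L, n - 2L))) {
      if (!substr(s, p, p + 2L) %in% starts) next
      q <- p + 3L
      while (q + 2L <= n) {
        if (substr(s, q, q + 2L) %in% stops) break
        q <- q + 3L
      }
      if (q + 2L > n) next
      aa_len <- (q - p) / 3L
      if (aa_len < min_aa || aa_len > max_aa) next
      aa <- as.character(Biostrings::translate(
        Biostrings::DNAString(substr(s, p, q - 1L)),
        no.init.codon = TRUE))
      hits[[length(hits) + 1L]] <- list(p = p, q = q + 2L, aa = aa)
    }
    hits
  }
  rc <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(x)))
  L <- nchar(seq)
  rows <- list()
  for (h in one_strand(seq)) {
    rows[[length(rows) + 1L]] <- data.frame(
      start = win0 + h$p - 1L, end = win0 + h$q, strand = "+",
      aa_seq = h$aa, stringsAsFactors = FALSE)
  }
  for (h in one_strand(rc(seq))) {
    rows[[length(rows) + 1L]] <- data.frame(
      start = win0 + L - h$q, end = win0 + L - h$p + 1L, strand = "-",
      aa_seq = h$aa, stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), aa_seq = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$strand), , drop = FALSE]
}

# A bare record wrapping a sequence, for driving scan_orfs on raw DNA.
orf_test_neighborhood <- function(seq, anchor = NULL) {
  rec <- gbk_record("test", seq)
  if (is.null(anchor)) anchor <- c(1L, nchar(seq))
  extract_neighborhood(rec, anchor, flank = nchar(seq))
}

# Tiny separable family + fitted model for classifier semantics tests.
fit_small_family_model <- function(seed = 5L, n = 8L) {
  fam <- generate_family(family_spec(n_positive = n, n_negative = n,
                                     seed = seed))
  segs <- lapply(c(fam$positives, fam$negatives), function(s)
    atropomine:::reduce_segments(segment_by_reference(s, fam$scheme),
                                 fam$alphabet))
  space <- build_feature_space(segs[seq_len(n)])
  x <- vectorize(segs, space)
  y <- factor(rep(c("pos", "neg"), each = n), levels = c("neg", "pos"))
  model <- train_classifier(x, y, classifier_config(seed = seed))
  list(fam = fam, space = space, x = x, y = y, model = model)
}
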