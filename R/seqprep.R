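#' @importFrom stats setNames
NULL

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA21 <- c(AA20, "X")

#' Validate and normalise protein sequences
#'
#' Uppercases the input and checks that every residue is one of the 20
#' standard amino acids or the wildcard `X`. Used on ingestion so that all
#' downstream operations can assume a clean 21-letter alphabet.
#'
#' @param x Character vector of residue strings (optionally named by
#'   accession).
#' @return The validated, uppercased character vector.
#' @export
as_protein <- function(x) {
  if (length(x) == 0L) stop("no sequences supplied")
  nm <- names(x)
  x <- toupper(as.character(x))
  names(x) <- nm
  if (any(!nzchar(x))) stop("empty protein sequence")
  bad <- grepl(sprintf("[^%s]", paste(AA21, collapse = "")), x)
  if (any(bad)) {
    stop("non-amino-acid characters in sequence(s): ",
         paste(utils::head(names(x)[bad], 3), collapse = ", "))
  }
  x
}

#' Read a protein FASTA file
#'
#' @param path Path to a (multi-record) protein FASTA file.
#' @return Named character vector of uppercased residue strings; names are
#'   the full description lines.
#' @export
read_protein_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  as_protein(setNames(as.character(set), names(set)))
}

#' Write a protein FASTA file
#'
#' @param seqs Named character vector of residue strings.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(seqs, path) {
  set <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Reference segmentation scheme for cytochrome P450s
#'
#' Defines the annotated reference P450 and the residue positions at which
#' every query is fragmented into five functional regions (N-terminus, two
#' substrate-binding regions, core region, C-terminus). Cut positions are
#' 1-based residue indices on the reference; the default 92/192/275/395
#' follows the functional-region annotation of the reference sequence.
#'
#' @param reference Residue string of the reference P450.
#' @param cut_positions Strictly increasing integer vector of four 1-based
#'   cut positions on the reference.
#' @param region_names Labels for the five resulting regions.
#' @return An object of class `reference_scheme`.
#' @export
reference_scheme <- function(reference,
                             cut_positions = c(92L, 192L, 275L, 395L),
                             region_names = c("N-terminus",
                                              "substrate-binding-1",
                                              "substrate-binding-2",
                                              "core-region",
                                              "C-terminus")) {
  reference <- as_protein(reference)[[1L]]
  cut_positions <- as.integer(cut_positions)
  if (length(cut_positions) != 4L || any(diff(cut_positions) <= 0L))
    stop("cut_positions must be four strictly increasing indices")
  if (cut_positions[1L] < 1L || cut_positions[4L] > nchar(reference))
    stop("cut_positions must lie within the reference sequence")
  if (length(region_names) != 5L)
    stop("exactly five region names are required")
  structure(list(reference = reference,
                 cut_positions = cut_positions,
                 region_names = as.character(region_names)),
            class = "reference_scheme")
}

#' @export
print.reference_scheme <- function(x, ...) {
  cat("reference_scheme: reference of", nchar(x$reference), "aa; cuts at",
      paste(x$cut_positions, collapse = "/"), "\n")
  invisible(x)
}

blosum62 <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <<- e$BLOSUM62
    }
    m
  }
})

# Map each reference residue index to the query coordinate consumed at (or
# last before) the alignment column where the reference reaches that index.
# A cut that falls in a query gap therefore resolves to the nearest aligned
# query position to the LEFT, which keeps regions contiguous.
map_reference_cuts <- function(query, reference, cuts,
                               gap_opening = 10, gap_extension = 1) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(reference),
    type = "global", substitutionMatrix = blosum62(),
    gapOpening = gap_opening, gapExtension = gap_extension)
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  qpos <- cumsum(p != "-")
  rpos <- cumsum(s != "-")
  vapply(cuts, function(cut) {
    col <- match(cut, rpos)          # first column where reference reaches cut
    if (is.na(col)) nchar(query) else qpos[col]
  }, integer(1))
}

#' Segment a P450 by alignment to an annotated reference
#'
#' Globally aligns the query against the scheme's reference (BLOSUM62, gap
#' open 10, extension 1) and maps each reference cut position through the
#' alignment to a query coordinate, fragmenting the query into five
#' functional regions. Cuts falling inside a query gap resolve to the
#' nearest aligned query position to the left, so the concatenation of the
#' five segments always reproduces the query exactly.
#'
#' @param query Residue string (one sequence).
#' @param scheme A [reference_scheme()].
#' @param min_length Minimum alignable query length; shorter queries are
#'   rejected.
#' @param gap_opening,gap_extension Affine gap penalties for the global
#'   alignment.
#' @return An object of class `segmented_protein` with elements `source`,
#'   `segments` (five residue strings named by region) and
#'   `query_boundaries` (the four query cut coordinates, 1-based inclusive
#'   region ends).
#' @export
segment_by_reference <- function(query, scheme, min_length = 50L,
                                 gap_opening = 10, gap_extension = 1) {
  stopifnot(inherits(scheme, "reference_scheme"))
  query <- as_protein(query)[[1L]]
  if (nchar(query) < min_length)
    stop("query shorter than the minimum alignable length (", min_length, ")")
  b <- map_reference_cuts(query, scheme$reference, scheme$cut_positions,
                          gap_opening, gap_extension)
  if (is.unsorted(b)) stop("internal error: non-monotone boundary mapping")
  starts <- c(1L, b + 1L)
  ends <- c(b, nchar(query))
  segs <- substring(query, starts, pmax(ends, starts - 1L))
  names(segs) <- scheme$region_names
  structure(list(source = query, segments = segs,
                 query_boundaries = as.integer(b)),
            class = "segmented_protein")
}

#' @export
print.segmented_protein <- function(x, ...) {
  cat("segmented_protein:", nchar(x$source), "aa; boundaries",
      paste(x$query_boundaries, collapse = "/"), "\n")
  invisible(x)
}

#' Default reduced amino-acid alphabet
#'
#' A six-group physico-chemical mapping used to recode sequences before
#' k-mer feature extraction, limiting overfitting to exact residue
#' identity: aliphatic \{A,V,L,I,M\} -> "A", aromatic \{F,W,Y\} -> "F",
#' positively charged \{K,R,H\} -> "K", negatively charged \{D,E\} -> "D",
#' polar \{S,T,N,Q,C\} -> "S", conformationally special \{G,P\} -> "G".
#' The wildcard `X` maps to its own symbol `X`, which is excluded from
#' every feature k-mer so ambiguous residues never create spurious counts.
#' Any alternative grouping can be supplied wherever an `alphabet` argument
#' is accepted, as a named character vector `residue -> group symbol`.
#'
#' @return Named character vector mapping the 21-letter alphabet to group
#'   symbols.
#' @export
default_alphabet <- function() {
  c(A = "A", V = "A", L = "A", I = "A", M = "A",
    F = "F", W = "F", Y = "F",
    K = "K", R = "K", H = "K",
    D = "D", E = "D",
    S = "S", T = "S", N = "S", Q = "S", C = "S",
    G = "G", P = "G",
    X = "X")
}

check_alphabet <- function(alphabet) {
  if (is.null(names(alphabet)) || !all(AA20 %in% names(alphabet)))
    stop("alphabet must map every one of the 20 amino acids")
  if (any(nchar(alphabet) != 1L))
    stop("group symbols must be single characters")
  if (!"X" %in% names(alphabet)) alphabet <- c(alphabet, X = "X")
  alphabet
}

#' Recode a residue string into a reduced alphabet
#'
#' @param seq Residue string over the 21-letter alphabet (may be empty).
#' @param alphabet Named character vector mapping residues to group
#'   symbols; see [default_alphabet()].
#' @return The recoded string, same length as the input.
#' @export
reduce_sequence <- function(seq, alphabet = default_alphabet()) {
  alphabet <- check_alphabet(alphabet)
  seq <- toupper(seq)
  if (!nzchar(seq)) return(seq)
  if (grepl(sprintf("[^%s]", paste(names(alphabet), collapse = "")), seq))
    stop("residue absent from the alphabet mapping")
  chartr(paste(names(alphabet), collapse = ""),
         paste(alphabet, collapse = ""), seq)
}

reduce_segments <- function(seg, alphabet = default_alphabet()) {
  vapply(seg$segments, reduce_sequence, character(1), alphabet = alphabet)
}

#' Dereplication parameters
#'
#' @param identity_threshold Minimum pairwise identity (matches divided by
#'   the length of the shorter sequence under a global alignment) for two
#'   sequences to share a cluster. Default 0.95.
#' @param word_size k-mer length for the candidate-pair prefilter; two
#'   sequences are only aligned if they share at least one word of this
#'   size. Default 5.
#' @param length_filter Inclusive residue-length range retained before
#'   clustering, or `NULL` to keep all lengths. Default `c(300, 450)`, the
#'   range used when assembling P450 classification sets.
#' @return An object of class `derep_params`.
#' @export
derep_params <- function(identity_threshold = 0.95, word_size = 5L,
                         length_filter = c(300L, 450L)) {
  if (identity_threshold <= 0 || identity_threshold > 1)
    stop("identity_threshold must be in (0, 1]")
  if (word_size < 1L) stop("word_size must be >= 1")
  structure(list(identity_threshold = identity_threshold,
                 word_size = as.integer(word_size),
                 length_filter = length_filter),
            class = "derep_params")
}

kgram_set <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  unique(substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L))
}

#' Global-alignment identity between two sequences
#'
#' Identity is the number of identical aligned residues divided by the
#' length of the shorter sequence, the convention of greedy incremental
#' clustering tools.
#'
#' @param a,b Residue strings.
#' @param gap_opening,gap_extension Affine gap penalties.
#' @return Fraction in \[0, 1\].
#' @export
pairwise_identity <- function(a, b, gap_opening = 10, gap_extension = 1) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = blosum62(),
    gapOpening = gap_opening, gapExtension = gap_extension)
  Biostrings::nmatch(aln) / min(nchar(a), nchar(b))
}

#' Greedy dereplication of a protein set
#'
#' Longest-first greedy incremental clustering: each sequence joins the
#' first existing cluster whose representative (the founder) it matches at
#' or above the identity threshold, otherwise it founds a new cluster. The
#' representatives are returned in descending founder length. The word-size
#' prefilter only prunes alignment candidates; membership is always decided
#' by alignment identity.
#'
#' @param seqs Named character vector of residue strings.
#' @param params A [derep_params()] object. The default applies no length
#'   filter so that training sets are reduced as-is.
#' @return Named character vector of cluster representatives.
#' @export
dereplicate <- function(seqs, params = derep_params(length_filter = NULL)) {
  stopifnot(inherits(params, "derep_params"))
  seqs <- as_protein(seqs)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  if (!is.null(params$length_filter)) {
    keep <- nchar(seqs) >= params$length_filter[1] &
      nchar(seqs) <= params$length_filter[2]
    seqs <- seqs[keep]
    if (length(seqs) == 0L) return(seqs)
  }
  ord <- order(-nchar(seqs))          # stable: ties keep input order
  seqs <- seqs[ord]
  reps <- integer(0)
  words <- lapply(seqs, kgram_set, k = params$word_size)
  for (i in seq_along(seqs)) {
    placed <- FALSE
    for (r in reps) {
      if (length(intersect(words[[i]], words[[r]])) == 0L) next
      if (pairwise_identity(seqs[[i]], seqs[[r]]) >=
          params$identity_threshold) {
        placed <- TRUE
        break
      }
    }
    if (!placed) reps <- c(reps, i)
  }
  seqs[reps]
}
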