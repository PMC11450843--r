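START_CODONS <- c("ATG", "GTG", "TTG")
STOP_CODONS <- c("TAA", "TAG", "TGA")
AROMATIC <- c("F", "W", "Y")
EXEMPT_CDS_LABEL <- "tryptorubin family RiPP precursor"

revcomp <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1L]]), collapse = ""))
}

translate_codons <- function(codons, literal_initiator = TRUE) {
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  if (!literal_initiator && length(aa)) aa[1L] <- "M"
  paste(aa, collapse = "")
}

#' Default leader-peptide motif set
#'
#' The KSLK motif family found in atropopeptide precursor leaders
#' (typically around residues 17-20, which is informational and not
#' enforced by the search).
#'
#' @param motifs Character vector of allowed 4-residue motifs.
#' @return An object of class `motif_set`.
#' @export
motif_set <- function(motifs = c("KSLK", "RSLK", "ESLK",
                                 "KSRK", "KPLK", "PSLK")) {
  motifs <- toupper(motifs)
  if (any(nchar(motifs) != 4L)) stop("motifs must be 4 residues long")
  structure(list(motifs = motifs), class = "motif_set")
}

#' Extract the genomic neighbourhood of an anchor P450 gene
#'
#' The window spans up to `flank` nucleotides on each side of the anchor
#' gene's boundaries (strand-independent), truncated at the record edges.
#' Annotated features overlapping the window are retained with their
#' original record coordinates.
#'
#' @param record A [gbk_record()].
#' @param anchor Either a feature from `record$features`, or a character
#'   value matched against the `protein_id` and `locus_tag` qualifiers of
#'   CDS features, or a numeric `c(start, end)` pair of 1-based inclusive
#'   record coordinates.
#' @param flank Flank size in nucleotides (default 3000).
#' @return An object of class `neighborhood` with the window in 0-based
#'   half-open record coordinates.
#' @export
extract_neighborhood <- function(record, anchor, flank = 3000L) {
  stopifnot(inherits(record, "gbk_record"))
  n <- nchar(record$sequence)
  if (is.character(anchor)) {
    hit <- NULL
    for (f in record$features) {
      q <- f$qualifiers
      if (f$type == "CDS" &&
          (identical(unname(q["protein_id"]), anchor) ||
           identical(unname(q["locus_tag"]), anchor))) {
        hit <- f
        break
      }
    }
    if (is.null(hit)) stop("anchor '", anchor, "' not found in record ",
                           record$id)
    anchor <- hit
  }
  if (is.numeric(anchor))
    anchor <- list(start = anchor[1L], end = anchor[2L], strand = "+")
  a0 <- anchor$start - 1L              # to 0-based half-open
  a1 <- anchor$end
  if (a0 < 0L || a1 > n) stop("anchor coordinates outside the record")
  win <- c(max(0L, a0 - as.integer(flank)), min(n, a1 + as.integer(flank)))
  keep <- Filter(function(f) f$end > win[1L] && f$start - 1L < win[2L],
                 record$features)
  structure(list(record_id = record$id, sequence = record$sequence,
                 anchor = list(start = a0, end = a1,
                               strand = anchor$strand %||% "+"),
                 window = win, annotations = keep),
            class = "neighborhood")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.neighborhood <- function(x, ...) {
  cat("neighborhood of", x$record_id, ": window [", x$window[1L], ",",
      x$window[2L], "), anchor [", x$anchor$start, ",", x$anchor$end,
      ")\n")
  invisible(x)
}

scan_orfs_strand <- function(s, min_aa, max_aa, literal_initiator = TRUE,
                             start_codons = START_CODONS) {
  n <- nchar(s)
  if (n < 3L) return(NULL)
  pos <- seq_len(n - 2L)
  codons <- substring(s, pos, pos + 2L)
  is_start <- codons %in% start_codons
  is_stop <- codons %in% STOP_CODONS
  out <- list()
  for (f in 0:2) {
    fpos <- pos[(pos - 1L) %% 3L == f]
    starts <- fpos[is_start[fpos]]
    stops <- fpos[is_stop[fpos]]
    if (!length(starts) || !length(stops)) next
    nxt <- stops[findInterval(starts, stops) + 1L]   # first stop after start
    ok <- !is.na(nxt)
    starts <- starts[ok]
    nxt <- nxt[ok]
    aa_len <- (nxt - starts) %/% 3L                  # excludes the stop
    keep <- aa_len >= min_aa & aa_len <= max_aa
    if (!any(keep)) next
    for (i in which(keep)) {
      cd <- codons[seq(starts[i], nxt[i] - 3L, by = 3L)]
      out[[length(out) + 1L]] <- list(
        s1 = starts[i], e1 = nxt[i] + 2L,            # 1-based inclusive in s
        aa_seq = translate_codons(cd, literal_initiator),
        start_codon = codons[starts[i]])
    }
  }
  out
}

#' Scan a neighbourhood for short open reading frames
#'
#' All six reading frames of the window are scanned for ORFs (start codon
#' ATG/GTG/TTG through the first in-frame stop, translation table 11 with
#' the initiator translated literally) whose translated length falls in
#' `[min_aa, max_aa]`. Coordinates of the reported ORFs are 0-based
#' half-open record coordinates spanning the stop codon.
#'
#' @param nb A [extract_neighborhood()] result.
#' @param min_aa,max_aa Inclusive translated-length bounds (default
#'   10-40).
#' @param literal_initiator Translate GTG/TTG initiators as Val/Leu
#'   (default) rather than forcing Met.
#' @param start_codons Permitted initiation codons.
#' @return Data frame with columns `start`, `end`, `strand`,
#'   `start_codon`, `aa_seq`, sorted by (start, strand).
#' @export
scan_orfs <- function(nb, min_aa = 10L, max_aa = 40L,
                      literal_initiator = TRUE,
                      start_codons = START_CODONS) {
  stopifnot(inherits(nb, "neighborhood"))
  win <- nb$window
  w0 <- win[1L]
  s <- substr(nb$sequence, win[1L] + 1L, win[2L])
  L <- nchar(s)
  empty <- data.frame(start = integer(0), end = integer(0),
                      strand = character(0), start_codon = character(0),
                      aa_seq = character(0), stringsAsFactors = FALSE)
  if (L < 36L) return(empty)
  fwd <- scan_orfs_strand(s, min_aa, max_aa, literal_initiator, start_codons)
  rev <- scan_orfs_strand(revcomp(s), min_aa, max_aa, literal_initiator,
                          start_codons)
  rows <- list()
  for (o in fwd) {
    rows[[length(rows) + 1L]] <- data.frame(
      start = w0 + o$s1 - 1L, end = w0 + o$e1, strand = "+",
      start_codon = o$start_codon, aa_seq = o$aa_seq,
      stringsAsFactors = FALSE)
  }
  for (o in rev) {
    rows[[length(rows) + 1L]] <- data.frame(
      start = w0 + L - o$e1, end = w0 + L - o$s1 + 1L, strand = "-",
      start_codon = o$start_codon, aa_seq = o$aa_seq,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$start, out$strand), , drop = FALSE]
}

#' Aromatic-core rule (first mining round)
#'
#' A candidate precursor passes if the C-terminal six residues (the
#' presumed core peptide) contain at least one adjacent pair of aromatic
#' residues (F, W or Y).
#'
#' @param aa_seq Translated precursor sequence.
#' @return Logical.
#' @export
apply_core_rule <- function(aa_seq) {
  vapply(aa_seq, function(s) {
    core <- substr(s, max(1L, nchar(s) - 5L), nchar(s))
    ch <- strsplit(core, "")[[1L]]
    arom <- ch %in% AROMATIC
    any(arom[-length(arom)] & arom[-1L])
  }, logical(1), USE.NAMES = FALSE)
}

#' Leader-motif rule (second mining round)
#'
#' Searches the full precursor for the first (leftmost) occurrence of any
#' allowed leader motif.
#'
#' @param aa_seq Translated precursor sequence(s).
#' @param motifs A [motif_set()].
#' @return Character vector: the matched motif, or `NA` if none occurs.
#' @export
apply_motif_rule <- function(aa_seq, motifs = motif_set()) {
  stopifnot(inherits(motifs, "motif_set"))
  vapply(aa_seq, function(s) {
    pos <- vapply(motifs$motifs, function(m)
      regexpr(m, s, fixed = TRUE), integer(1))
    hit <- pos > 0
    if (!any(hit)) return(NA_character_)
    motifs$motifs[hit][which.min(pos[hit])]
  }, character(1), USE.NAMES = FALSE)
}

#' Remove ORFs overlapping annotated coding sequences
#'
#' An ORF is discarded if it shares at least one nucleotide with any
#' annotated CDS (either strand) unless that CDS is labelled as a
#' tryptorubin-family RiPP precursor (case-insensitive substring match on
#' the product and note qualifiers).
#'
#' @param orfs Data frame from [scan_orfs()].
#' @param annotations Feature list (from a [gbk_record()] /
#'   [extract_neighborhood()]).
#' @return The filtered data frame.
#' @export
filter_cds_overlap <- function(orfs, annotations) {
  if (!nrow(orfs)) return(orfs)
  cds <- Filter(function(f) f$type == "CDS", annotations)
  cds <- Filter(function(f) {
    lab <- paste(f$qualifiers["product"], f$qualifiers["note"])
    !grepl(EXEMPT_CDS_LABEL, lab, ignore.case = TRUE)
  }, cds)
  if (!length(cds)) return(orfs)
  keep <- vapply(seq_len(nrow(orfs)), function(i) {
    !any(vapply(cds, function(f)
      orfs$start[i] < f$end && f$start - 1L < orfs$end[i], logical(1)))
  }, logical(1))
  orfs[keep, , drop = FALSE]
}

#' Collapse nested ORFs sharing a stop codon
#'
#' Alternative start codons upstream of the same stop produce nested
#' candidates encoding the same core with longer leaders. Within each
#' (strand, stop coordinate) group exactly one candidate is kept - the
#' shortest - and the discarded alternative start coordinates are recorded
#' in an `alt_starts` column.
#'
#' @param cand Data frame of candidates with `start`, `end`, `strand`.
#' @return Deduplicated data frame with an added `alt_starts` column
#'   (comma-separated 0-based start coordinates of discarded longer
#'   forms).
#' @export
deduplicate_nested <- function(cand) {
  if (!nrow(cand)) {
    cand$alt_starts <- character(0)
    return(cand)
  }
  stop_coord <- ifelse(cand$strand == "+", cand$end, cand$start)
  key <- paste(cand$strand, stop_coord)
  keep <- integer(0)
  alt <- character(0)
  for (k in unique(key)) {
    idx <- which(key == k)
    len <- cand$end[idx] - cand$start[idx]
    best <- idx[which.min(len)]
    keep <- c(keep, best)
    others <- setdiff(idx, best)
    alt <- c(alt, if (length(others))
      paste(sort(cand$start[others]), collapse = ",") else "")
  }
  out <- cand[keep, , drop = FALSE]
  out$alt_starts <- alt
  out[order(out$start, out$strand), , drop = FALSE]
}

#' Find precursor-peptide candidates near an anchor P450
#'
#' Runs the full deterministic search: six-frame short-ORF scan of the
#' neighbourhood window, removal of ORFs overlapping annotated CDS
#' (tryptorubin-family precursor annotations exempt), application of the
#' active precursor rules, and collapsing of nested same-stop candidates
#' to the shortest form.
#'
#' @param nb A [extract_neighborhood()] result.
#' @param rule_mode `"aromatic-core"` (first-round rule),
#'   `"leader-motif"` (second-round rule) or `"both"`.
#' @param motifs A [motif_set()] for the leader-motif rule.
#' @param min_aa,max_aa ORF length bounds in residues.
#' @return Data frame of precursor candidates: coordinates, strand, start
#'   codon, full translation, `leader`, 6-residue `core`,
#'   `matched_motif`, `rule_mode` and `alt_starts`.
#' @export
find_precursors <- function(nb, rule_mode = c("aromatic-core",
                                              "leader-motif", "both"),
                            motifs = motif_set(),
                            min_aa = 10L, max_aa = 40L) {
  rule_mode <- match.arg(rule_mode)
  orfs <- scan_orfs(nb, min_aa = min_aa, max_aa = max_aa)
  orfs <- filter_cds_overlap(orfs, nb$annotations)
  if (nrow(orfs)) {
    motif_hit <- apply_motif_rule(orfs$aa_seq, motifs)
    core_ok <- apply_core_rule(orfs$aa_seq)
    pass <- switch(rule_mode,
                   "aromatic-core" = core_ok,
                   "leader-motif" = !is.na(motif_hit),
                   "both" = core_ok & !is.na(motif_hit))
    orfs$matched_motif <- motif_hit
    orfs <- orfs[pass, , drop = FALSE]
  } else {
    orfs$matched_motif <- character(0)
  }
  orfs <- deduplicate_nested(orfs)
  orfs$core <- substr(orfs$aa_seq, pmax(1L, nchar(orfs$aa_seq) - 5L),
                      nchar(orfs$aa_seq))
  orfs$leader <- substr(orfs$aa_seq, 1L, pmax(0L, nchar(orfs$aa_seq) - 6L))
  orfs$rule_mode <- rep(rule_mode, nrow(orfs))
  rownames(orfs) <- NULL
  orfs
}

#' Write a neighbourhood with annotated precursors as GenBank
#'
#' The window sequence is re-based to position 1; carried-over
#' annotations and precursor candidates are emitted as CDS features with
#' 1-based inclusive coordinates, the precursors carrying translation,
#' core, motif and rule-mode qualifiers.
#'
#' @param nb A [extract_neighborhood()] result.
#' @param precursors Data frame from [find_precursors()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_region_genbank <- function(nb, precursors, path) {
  stopifnot(inherits(nb, "neighborhood"))
  w0 <- nb$window[1L]
  w1 <- nb$window[2L]
  seq <- substr(nb$sequence, w0 + 1L, w1)
  feats <- lapply(nb$annotations, function(f) {
    f$start <- max(1L, f$start - w0)
    f$end <- min(w1 - w0, f$end - w0)
    f
  })
  if (nrow(precursors)) {
    for (i in seq_len(nrow(precursors))) {
      quals <- c(product = "putative atropopeptide precursor",
                 translation = precursors$aa_seq[i],
                 core_peptide = precursors$core[i],
                 rule_mode = precursors$rule_mode[i])
      if (!is.na(precursors$matched_motif[i]))
        quals <- c(quals, leader_motif = precursors$matched_motif[i])
      if (nzchar(precursors$alt_starts[i]))
        quals <- c(quals, note = paste0("alternative starts (record, 0-based): ",
                                        precursors$alt_starts[i]))
      feats[[length(feats) + 1L]] <- list(
        type = "CDS",
        start = precursors$start[i] - w0 + 1L,
        end = precursors$end[i] - w0,
        strand = precursors$strand[i],
        qualifiers = quals)
    }
  }
  rec <- gbk_record(paste0(nb$record_id, "_region"), seq, feats)
  write_genbank(rec, path)
}

#' GC content of a nucleotide sequence
#'
#' Ambiguous bases are excluded from both numerator and denominator.
#'
#' @param nt_seq Nucleotide string.
#' @return Fraction (G+C)/(A+C+G+T) in \[0, 1\].
#' @export
gc_content <- function(nt_seq) {
  ch <- strsplit(toupper(nt_seq), "")[[1L]]
  gc <- sum(ch %in% c("G", "C"))
  at <- sum(ch %in% c("A", "T"))
  if (gc + at == 0L) stop("no unambiguous bases in sequence")
  gc / (gc + at)
}

#' Signed GC-content difference of a gene versus its genome
#'
#' @param gene_gc GC fraction of the gene.
#' @param genome_mean_gc Mean GC fraction of the genome.
#' @return `gene_gc - genome_mean_gc`.
#' @export
gc_delta <- function(gene_gc, genome_mean_gc) gene_gc - genome_mean_gc
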