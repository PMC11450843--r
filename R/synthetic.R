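# Fixed codon per amino acid (first of the standard-code codons in lexical
# order) keeps reverse translation deterministic.
codon_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      gc <- Biostrings::GENETIC_CODE
      tab <<- vapply(sort(unique(gc[gc != "*"])), function(a)
        sort(names(gc)[gc == a])[1L], character(1))
    }
    tab
  }
})

reverse_translate <- function(aa) {
  paste(codon_table()[strsplit(aa, "")[[1L]]], collapse = "")
}

random_aa <- function(n, exclude = NULL) {
  pool <- setdiff(AA20, exclude)
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

# Residue strings destined for planted ORFs exclude Met: with the fixed
# reverse-translation codons only ATG (Met) forms an in-frame start codon,
# so excluding internal Met prevents unintended nested ORFs that would
# share the planted stop.
random_orf_aa <- function(n) random_aa(n, exclude = "M")

group_representative <- function(alphabet) {
  groups <- unique(unname(alphabet[names(alphabet) != "X"]))
  setNames(vapply(groups, function(g)
    sort(names(alphabet)[alphabet == g & names(alphabet) != "X"])[1L],
    character(1)), groups)
}

#' Specification of a synthetic P450 family
#'
#' Describes a labelled protein family for classifier testing, emulating
#' a target family against a background family: positives are
#' point-mutated copies of one random backbone carrying planted
#' reduced-alphabet 4-mer signatures at fixed positions inside chosen
#' functional regions, negatives are point-mutated copies of an unrelated
#' backbone of the same length. The planted sites are written after
#' mutation, so every positive carries every signature; negatives are
#' scrubbed of the signature k-mers in the corresponding regions.
#'
#' @param n_positive,n_negative Family sizes (default 40/40).
#' @param seed Integer seed; generation is byte-deterministic.
#' @param backbone_length Backbone length in residues (default 430,
#'   within the 300-450 aa band typical of bacterial P450s).
#' @param signatures List of `list(segment =, kmer =)` entries; `kmer` is
#'   a 4-mer over the reduced-alphabet group symbols.
#' @param mutation_rate Per-site substitution probability diversifying
#'   family members (default 0.05, placing typical pairwise identities
#'   near 0.90 so that generated families survive dereplication at the
#'   0.95 threshold, as a dereplicated training set does).
#' @param cut_positions Reference cut positions (default 92/192/275/395).
#' @param alphabet Reduced alphabet mapping.
#' @return An object of class `family_spec`.
#' @export
family_spec <- function(n_positive = 40L, n_negative = 40L, seed = 1L,
                        backbone_length = 430L,
                        signatures = list(list(segment = 2L, kmer = "FKDS"),
                                          list(segment = 4L, kmer = "KFGA")),
                        mutation_rate = 0.05,
                        cut_positions = c(92L, 192L, 275L, 395L),
                        alphabet = default_alphabet()) {
  stopifnot(n_positive >= 2L, n_negative >= 1L,
            mutation_rate >= 0, mutation_rate < 1)
  symbols <- unique(unname(alphabet[names(alphabet) != "X"]))
  for (sg in signatures) {
    stopifnot(sg$segment %in% 1:5, nchar(sg$kmer) == 4L)
    if (!all(strsplit(sg$kmer, "")[[1L]] %in% symbols))
      stop("signature k-mer must use reduced-alphabet group symbols")
  }
  structure(list(n_positive = as.integer(n_positive),
                 n_negative = as.integer(n_negative),
                 seed = as.integer(seed),
                 backbone_length = as.integer(backbone_length),
                 signatures = signatures,
                 mutation_rate = mutation_rate,
                 cut_positions = as.integer(cut_positions),
                 alphabet = alphabet),
            class = "family_spec")
}

mutate_protein <- function(seq, rate) {
  ch <- strsplit(seq, "")[[1L]]
  hit <- which(stats::runif(length(ch)) < rate)
  for (i in hit) {
    ch[i] <- sample(setdiff(AA20, ch[i]), 1L)
  }
  paste(ch, collapse = "")
}

scrub_kmer <- function(seg_seq, kmer, alphabet, rep_map) {
  # Replace the 2nd residue of each occurrence (in reduced space) with a
  # residue from a different physico-chemical group.
  repeat {
    red <- reduce_sequence(seg_seq, alphabet)
    pos <- regexpr(kmer, red, fixed = TRUE)
    if (pos < 0L) return(seg_seq)
    target <- substr(kmer, 2L, 2L)
    other <- rep_map[setdiff(names(rep_map), target)][1L]
    substr(seg_seq, pos + 1L, pos + 1L) <- unname(other)
  }
}

#' Generate a labelled synthetic P450 family
#'
#' @param spec A [family_spec()].
#' @return List with `positives` and `negatives` (named residue vectors),
#'   the backbone `reference`, the matching [reference_scheme()], the
#'   `alphabet` and the planted `signatures`.
#' @export
generate_family <- function(spec) {
  stopifnot(inherits(spec, "family_spec"))
  withr::with_seed(spec$seed, {
    backbone <- random_aa(spec$backbone_length)
    neg_backbone <- random_aa(spec$backbone_length)
    scheme <- reference_scheme(backbone, spec$cut_positions)
    seg_start <- c(1L, spec$cut_positions + 1L)
    seg_end <- c(spec$cut_positions, spec$backbone_length)
    rep_map <- group_representative(spec$alphabet)
    # absolute planting windows, staggered within each segment
    slots <- list()
    used <- stats::setNames(integer(5), 1:5)
    for (sg in spec$signatures) {
      s <- sg$segment
      at <- seg_start[s] + 10L + 6L * used[[as.character(s)]]
      used[[as.character(s)]] <- used[[as.character(s)]] + 1L
      if (at + 3L > seg_end[s]) stop("signature does not fit in segment ", s)
      aa4 <- paste(rep_map[strsplit(sg$kmer, "")[[1L]]], collapse = "")
      slots[[length(slots) + 1L]] <- list(at = at, aa = aa4, segment = s,
                                          kmer = sg$kmer)
    }
    make_positive <- function() {
      s <- mutate_protein(backbone, spec$mutation_rate)
      for (sl in slots) substr(s, sl$at, sl$at + 3L) <- sl$aa
      s
    }
    make_negative <- function() {
      s <- mutate_protein(neg_backbone, spec$mutation_rate)
      for (sl in slots) {
        seg <- substr(s, seg_start[sl$segment], seg_end[sl$segment])
        seg <- scrub_kmer(seg, sl$kmer, spec$alphabet, rep_map)
        substr(s, seg_start[sl$segment], seg_end[sl$segment]) <- seg
      }
      s
    }
    positives <- stats::setNames(
      vapply(seq_len(spec$n_positive), function(i) make_positive(),
             character(1)),
      sprintf("pos_%02d", seq_len(spec$n_positive)))
    negatives <- stats::setNames(
      vapply(seq_len(spec$n_negative), function(i) make_negative(),
             character(1)),
      sprintf("neg_%02d", seq_len(spec$n_negative)))
    # planted-signature presence is guaranteed by construction; verify
    for (sl in slots) {
      red <- vapply(positives, function(p) reduce_sequence(
        substr(p, seg_start[sl$segment], seg_end[sl$segment]),
        spec$alphabet), character(1))
      stopifnot(all(grepl(sl$kmer, red, fixed = TRUE)))
    }
    list(positives = positives, negatives = negatives,
         reference = backbone, scheme = scheme, alphabet = spec$alphabet,
         signatures = spec$signatures)
  })
}

random_core_with_aromatics <- function() {
  core <- strsplit(random_orf_aa(6L), "")[[1L]]
  at <- sample(1:5, 1L)
  core[at] <- sample(AROMATIC, 1L)
  core[at + 1L] <- sample(AROMATIC, 1L)
  paste(core, collapse = "")
}

scrub_motifs <- function(aa, motifs) {
  repeat {
    pos <- vapply(motifs$motifs, function(m)
      regexpr(m, aa, fixed = TRUE), integer(1))
    if (all(pos < 0L)) return(aa)
    p <- min(pos[pos > 0L])
    substr(aa, p + 1L, p + 1L) <- "A"
  }
}

#' Specification of a synthetic GenBank neighbourhood
#'
#' Describes a nucleotide record embedding an annotated anchor P450 gene,
#' one unannotated truth precursor ORF (leader with a KSLK-family motif
#' plus a 6-residue core with consecutive aromatics), and a panel of decoy
#' ORFs each violating exactly one precursor rule: below the minimum
#' length, above the maximum length, overlapping the anchor CDS, lacking
#' every leader motif, or lacking the aromatic core pair.
#'
#' @param seed Integer seed.
#' @param record_length Record length in nt (default 9000).
#' @param gc Background GC fraction (default 0.6, actinobacteria-like).
#' @param anchor_start 0-based start of the anchor P450 gene.
#' @param anchor_aa Anchor protein length in residues.
#' @param anchor_strand Anchor strand.
#' @param precursor_offset Truth ORF start, in nt downstream of the
#'   anchor gene end (must leave the ORF inside the 3 kb flank).
#' @param precursor_strand Truth ORF strand.
#' @param motif Leader motif planted at `motif_pos`; drawn from
#'   [motif_set()] when `NULL`.
#' @param motif_pos 1-based residue position of the motif in the
#'   precursor (default 17, the typical leader position).
#' @param leader_length Leader length in residues (default 20).
#' @param core 6-residue core; random with a planted consecutive aromatic
#'   pair when `NULL`.
#' @param decoys Include the decoy panel (default TRUE).
#' @return An object of class `neighborhood_spec`.
#' @export
neighborhood_spec <- function(seed = 1L, record_length = 9000L, gc = 0.6,
                              anchor_start = 3600L, anchor_aa = 380L,
                              anchor_strand = "+",
                              precursor_offset = 500L,
                              precursor_strand = "+",
                              motif = NULL, motif_pos = 17L,
                              leader_length = 20L, core = NULL,
                              decoys = TRUE) {
  stopifnot(motif_pos + 3L <= leader_length, leader_length >= 5L,
            gc > 0, gc < 1)
  structure(list(seed = as.integer(seed),
                 record_length = as.integer(record_length), gc = gc,
                 anchor_start = as.integer(anchor_start),
                 anchor_aa = as.integer(anchor_aa),
                 anchor_strand = anchor_strand,
                 precursor_offset = as.integer(precursor_offset),
                 precursor_strand = precursor_strand,
                 motif = motif, motif_pos = as.integer(motif_pos),
                 leader_length = as.integer(leader_length),
                 core = core, decoys = decoys),
            class = "neighborhood_spec")
}

orf_nt <- function(aa) paste0(reverse_translate(aa), "TAA")

splice <- function(seq, at0, insert) {
  # replace bases [at0, at0 + nchar(insert)) (0-based) with `insert`
  paste0(substr(seq, 1L, at0), insert,
         substr(seq, at0 + nchar(insert) + 1L, nchar(seq)))
}

#' Generate a synthetic GenBank neighbourhood with known truth
#'
#' Assembles the record described by `spec`, then sanitises the
#' background: any ORF that would pass both precursor rules but is not
#' the planted truth is destroyed by point mutations outside the planted
#' elements, so that the precursor search recovers exactly the truth.
#' The truth precursor itself is embedded as plain sequence (no
#' annotation), mirroring the unannotated precursor genes the search is
#' designed to discover.
#'
#' @param spec A [neighborhood_spec()].
#' @return List with `record` (a [gbk_record()]), `truth` (one-row data
#'   frame with the expected search result) and `decoys` (data frame of
#'   planted rule-violating ORFs and the rule each violates).
#' @export
generate_neighborhood <- function(spec) {
  stopifnot(inherits(spec, "neighborhood_spec"))
  withr::with_seed(spec$seed, {
    motifs <- motif_set()
    motif <- spec$motif %||% sample(motifs$motifs, 1L)
    core <- spec$core %||% random_core_with_aromatics()
    stopifnot(nchar(core) == 6L)
    p <- c(A = (1 - spec$gc) / 2, C = spec$gc / 2, G = spec$gc / 2,
           T = (1 - spec$gc) / 2)
    seq <- paste(sample(names(p), spec$record_length, TRUE, p),
                 collapse = "")
    planted <- list()
    plant <- function(seq, at0, nt) {
      stopifnot(at0 >= 0L, at0 + nchar(nt) <= nchar(seq))
      for (sp in planted) {
        if (at0 < sp[2L] && sp[1L] < at0 + nchar(nt))
          stop("planted elements collide")
      }
      planted[[length(planted) + 1L]] <<- c(at0, at0 + nchar(nt))
      splice(seq, at0, nt)
    }
    plant_overlapping <- function(seq, at0, nt) {
      planted[[length(planted) + 1L]] <<- c(at0, at0 + nchar(nt))
      splice(seq, at0, nt)
    }
    # anchor P450 gene
    anchor_nt <- orf_nt(paste0("M", random_aa(spec$anchor_aa - 1L)))
    a0 <- spec$anchor_start
    a1 <- a0 + nchar(anchor_nt)
    seq <- plant(seq, a0, if (spec$anchor_strand == "+") anchor_nt else
      revcomp(anchor_nt))
    # truth precursor: motif planted at motif_pos, rest of the leader
    # scrubbed so the planted motif is the leftmost (and only) match
    leader <- scrub_motifs(paste0("M", random_orf_aa(spec$leader_length - 1L)),
                           motifs)
    leader <- paste0(substr(leader, 1L, spec$motif_pos - 1L), motif,
                     substr(leader, spec$motif_pos + 4L, nchar(leader)))
    truth_aa <- paste0(leader, core)
    truth_nt <- orf_nt(truth_aa)
    t0 <- a1 + spec$precursor_offset
    seq <- plant(seq, t0, if (spec$precursor_strand == "+") truth_nt else
      revcomp(truth_nt))
    truth <- data.frame(start = t0, end = t0 + nchar(truth_nt),
                        strand = spec$precursor_strand, aa_seq = truth_aa,
                        core = core, motif = motif,
                        stringsAsFactors = FALSE)
    decoys <- data.frame(start = integer(0), end = integer(0),
                         strand = character(0), aa_seq = character(0),
                         violates = character(0), stringsAsFactors = FALSE)
    if (isTRUE(spec$decoys)) {
      arom2 <- function() paste(sample(AROMATIC, 2L, TRUE), collapse = "")
      short_aa <- paste0("M", motif, "A", arom2(), "A")          # 9 aa
      long_aa <- paste0(scrub_motifs(paste0("M", random_orf_aa(15L)), motifs),
                        motif,
                        scrub_motifs(random_orf_aa(15L), motifs),
                        random_core_with_aromatics())             # 41 aa
      nomotif_aa <- paste0(scrub_motifs(paste0("M", random_orf_aa(19L)), motifs),
                           random_core_with_aromatics())          # 26 aa
      nonarom <- setdiff(AA20, AROMATIC)
      nocore_lead <- paste0("M", random_orf_aa(19L))
      nocore_lead <- paste0(substr(nocore_lead, 1L, 16L), motif)
      nocore_aa <- paste0(nocore_lead,
                          paste(sample(nonarom, 6L, TRUE), collapse = ""))
      overlap_aa <- paste0(scrub_motifs(paste0("M", random_orf_aa(13L)), motifs),
                           motif, "A", random_core_with_aromatics()) # 25 aa
      panel <- list(
        list(aa = short_aa, at = a1 + 900L, violates = "min_length"),
        list(aa = long_aa, at = a1 + 1200L, violates = "max_length"),
        list(aa = nomotif_aa, at = a0 - 900L, violates = "leader_motif"),
        list(aa = nocore_aa, at = a0 - 1300L, violates = "aromatic_core"),
        list(aa = overlap_aa, at = a0 - 40L, violates = "cds_overlap"))
      for (d in panel) {
        nt <- orf_nt(d$aa)
        seq <- if (d$violates == "cds_overlap")
          plant_overlapping(seq, d$at, nt) else plant(seq, d$at, nt)
        decoys <- rbind(decoys, data.frame(
          start = d$at, end = d$at + nchar(nt), strand = "+",
          aa_seq = d$aa, violates = d$violates, stringsAsFactors = FALSE))
      }
    }
    anchor_feat <- list(type = "CDS", start = a0 + 1L, end = a1,
                        strand = spec$anchor_strand,
                        qualifiers = c(product = "cytochrome P450",
                                       protein_id = sprintf("SYNP450_%d.1",
                                                            spec$seed)))
    # decorative annotation exercising carry-over; dropped if it would
    # cover a planted element (the overlap filter must not see truth ORFs
    # under an annotated CDS)
    extra_feat <- list(type = "CDS", start = a1 + 1801L, end = a1 + 2400L,
                       strand = "+",
                       qualifiers = c(product = "hypothetical protein"))
    extra_clear <- !any(vapply(planted, function(x)
      x[1L] < extra_feat$end && extra_feat$start - 1L < x[2L], logical(1)))
    feats <- if (extra_clear && extra_feat$end <= nchar(seq))
      list(anchor_feat, extra_feat) else list(anchor_feat)
    rec <- gbk_record(sprintf("SYNNB%04d", spec$seed), seq, feats)
    rec <- sanitize_neighborhood(rec, anchor_feat, truth, planted)
    list(record = rec, truth = truth, decoys = decoys,
         anchor_protein_id = unname(anchor_feat$qualifiers["protein_id"]))
  })
}

# Destroy background ORFs that would pass both precursor rules but are not
# the planted truth, by point mutations outside every planted element.
sanitize_neighborhood <- function(rec, anchor_feat, truth, planted) {
  flip <- c(A = "C", C = "A", G = "T", T = "G")
  for (iter in 1:40) {
    nb <- extract_neighborhood(rec, anchor_feat)
    found <- find_precursors(nb, rule_mode = "both")
    spurious <- found[!(found$start == truth$start &
                          found$end == truth$end &
                          found$strand == truth$strand), , drop = FALSE]
    if (!nrow(spurious)) return(rec)
    sp <- spurious[1L, ]
    fixed <- FALSE
    for (p0 in seq(sp$start, sp$end - 1L)) {
      inside <- any(vapply(planted, function(x)
        p0 >= x[1L] && p0 < x[2L], logical(1)))
      if (inside) next
      old <- substr(rec$sequence, p0 + 1L, p0 + 1L)
      substr(rec$sequence, p0 + 1L, p0 + 1L) <- unname(flip[old])
      nb <- extract_neighborhood(rec, anchor_feat)
      found <- find_precursors(nb, rule_mode = "both")
      still <- any(found$start == sp$start & found$end == sp$end &
                     found$strand == sp$strand)
      if (!still) {
        fixed <- TRUE
        break
      }
      substr(rec$sequence, p0 + 1L, p0 + 1L) <- old
    }
    if (!fixed) stop("could not sanitise spurious ORF at ", sp$start)
  }
  stop("sanitisation did not converge")
}
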