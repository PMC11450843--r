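# Monoisotopic masses (most abundant isotope) and particle masses.
MONO_MASS <- c(C = 12.0, H = 1.00782503207, N = 14.0030740048,
               O = 15.9949146196, S = 31.97207100)
PROTON_MASS <- 1.007276466812
ELECTRON_MASS <- 0.00054857990907

# Residue (amino acid minus water) elemental compositions, C/H/N/O/S.
AA_RESIDUE_FORMULA <- list(
  A = c(3, 5, 1, 1, 0),  R = c(6, 12, 4, 1, 0), N = c(4, 6, 2, 2, 0),
  D = c(4, 5, 1, 3, 0),  C = c(3, 5, 1, 1, 1),  E = c(5, 7, 1, 3, 0),
  Q = c(5, 8, 2, 2, 0),  G = c(2, 3, 1, 1, 0),  H = c(6, 7, 3, 1, 0),
  I = c(6, 11, 1, 1, 0), L = c(6, 11, 1, 1, 0), K = c(6, 12, 2, 1, 0),
  M = c(5, 9, 1, 1, 1),  F = c(9, 9, 1, 1, 0),  P = c(5, 7, 1, 1, 0),
  S = c(3, 5, 1, 2, 0),  T = c(4, 7, 1, 2, 0),  W = c(11, 10, 2, 1, 0),
  Y = c(9, 9, 1, 2, 0),  V = c(5, 9, 1, 1, 0))

#' Elemental formula over C, H, N, O, S
#'
#' Integer atom counts with component-wise addition/subtraction;
#' subtraction producing a negative count is rejected.
#'
#' @param C,H,N,O,S Non-negative integer atom counts.
#' @return An object of class `elemental_formula`.
#' @export
elemental_formula <- function(C = 0L, H = 0L, N = 0L, O = 0L, S = 0L) {
  v <- c(C = as.integer(C), H = as.integer(H), N = as.integer(N),
         O = as.integer(O), S = as.integer(S))
  if (any(v < 0L)) stop("atom counts must be non-negative")
  structure(v, class = "elemental_formula")
}

#' @export
`+.elemental_formula` <- function(e1, e2) {
  elemental_formula(e1["C"] + e2["C"], e1["H"] + e2["H"], e1["N"] + e2["N"],
                    e1["O"] + e2["O"], e1["S"] + e2["S"])
}

#' @export
`-.elemental_formula` <- function(e1, e2) {
  v <- unclass(e1) - unclass(e2)
  if (any(v < 0L)) stop("formula subtraction would give a negative count")
  do.call(elemental_formula, as.list(v))
}

#' @exportS3Method base::format
format.elemental_formula <- function(x, ...) {
  parts <- vapply(c("C", "H", "N", "O", "S"), function(el) {
    n <- x[[el]]
    if (n == 0L) "" else if (n == 1L) el else paste0(el, n)
  }, character(1))
  paste(parts, collapse = "")
}

#' @export
print.elemental_formula <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Elemental formula of a linear peptide
#'
#' Sum of the residue compositions plus one water (the termini).
#'
#' @param seq Residue string over the 20 standard amino acids.
#' @return An `elemental_formula` of the neutral peptide.
#' @export
peptide_formula <- function(seq) {
  seq <- toupper(seq)
  ch <- strsplit(seq, "")[[1L]]
  bad <- setdiff(ch, names(AA_RESIDUE_FORMULA))
  if (length(bad)) stop("unknown residue(s): ", paste(bad, collapse = ", "))
  tot <- Reduce(`+`, AA_RESIDUE_FORMULA[ch], c(0, 0, 0, 0, 0))
  elemental_formula(tot[1], tot[2] + 2L, tot[3], tot[4] + 1L, tot[5])
}

#' Apply oxidative crosslinks to a peptide formula
#'
#' Each crosslink (biaryl, carbon-nitrogen or aryl-ether bridge) removes
#' two hydrogens from the elemental formula; other atoms are unchanged.
#'
#' @param formula An `elemental_formula` (neutral peptide).
#' @param n Number of crosslinks (>= 0).
#' @param delta_h Hydrogens removed per crosslink (default 2).
#' @return The modified `elemental_formula`.
#' @export
apply_crosslinks <- function(formula, n, delta_h = 2L) {
  stopifnot(inherits(formula, "elemental_formula"), n >= 0L)
  if (n == 0L) return(formula)
  formula - elemental_formula(H = as.integer(n) * as.integer(delta_h))
}

#' Monoisotopic mass of a neutral formula
#'
#' @param formula An `elemental_formula`.
#' @return Mass in Da.
#' @export
monoisotopic_mass <- function(formula) {
  stopifnot(inherits(formula, "elemental_formula"))
  sum(unclass(formula) * MONO_MASS[names(unclass(formula))])
}

#' Protonated monoisotopic m/z of a neutral species
#'
#' m/z of the \[M+H\]+ cation: neutral mass plus one proton, with the
#' electron-mass correction applied (the cation carries one electron
#' fewer than neutral-plus-hydrogen).
#'
#' @param formula An `elemental_formula` of the neutral species.
#' @param electron_correction Apply the electron-mass correction
#'   (default TRUE).
#' @return m/z of the singly protonated cation.
#' @export
mz_protonated <- function(formula, electron_correction = TRUE) {
  m <- monoisotopic_mass(formula) + MONO_MASS[["H"]]
  if (electron_correction) m <- m - ELECTRON_MASS
  m
}

#' Signed parts-per-million mass error
#'
#' @param observed Observed m/z.
#' @param calculated Calculated m/z.
#' @return `(observed - calculated) / calculated * 1e6`.
#' @export
ppm_error <- function(observed, calculated) {
  stopifnot(all(observed > 0), all(calculated > 0))
  (observed - calculated) / calculated * 1e6
}

#' Enumerate ion candidates for a (possibly truncated, crosslinked) core
#'
#' Builds the Cartesian product of N-terminal truncations
#' `0..allow_n_truncations` and crosslink counts `0..max_crosslinks` of a
#' core peptide, with the elemental formula and protonated monoisotopic
#' m/z of each variant. Used to screen culture extracts for modified core
#' peptides: proteolytic trimming of the core N-terminus is a common
#' maturation event, and each oxidative crosslink subtracts 2 H.
#'
#' @param core Core peptide residue string (length >= 2).
#' @param max_crosslinks Maximum number of crosslinks to consider.
#' @param allow_n_truncations Maximum number of N-terminal residues
#'   removed (must be < core length).
#' @return Data frame sorted by m/z: `sequence`, `truncation`,
#'   `n_crosslinks`, `formula` (Hill-style string), `mz` (4-decimal
#'   convention when printed).
#' @export
candidate_series <- function(core, max_crosslinks = 2L,
                             allow_n_truncations = 0L) {
  core <- toupper(core)
  if (nchar(core) < 2L) stop("core must have at least 2 residues")
  if (allow_n_truncations >= nchar(core))
    stop("truncation must leave at least one residue")
  grid <- expand.grid(truncation = 0:allow_n_truncations,
                      n_crosslinks = 0:max_crosslinks)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    tr <- grid$truncation[i]
    nx <- grid$n_crosslinks[i]
    pep <- substr(core, tr + 1L, nchar(core))
    f <- apply_crosslinks(peptide_formula(pep), nx)
    data.frame(sequence = pep, truncation = tr, n_crosslinks = nx,
               formula = format(f), mz = mz_protonated(f),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$mz), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Match observed masses against a candidate series
#'
#' @param series Data frame from [candidate_series()].
#' @param observed Numeric vector of observed m/z values.
#' @param tol_ppm Matching tolerance in ppm (default 5).
#' @return Data frame of matches: candidate columns plus `observed` and
#'   `ppm`.
#' @export
match_observed <- function(series, observed, tol_ppm = 5) {
  rows <- list()
  for (obs in observed) {
    ppm <- ppm_error(obs, series$mz)
    hit <- which(abs(ppm) <= tol_ppm)
    for (i in hit) {
      r <- series[i, , drop = FALSE]
      r$observed <- obs
      r$ppm <- ppm[i]
      rows[[length(rows) + 1L]] <- r
    }
  }
  if (!length(rows)) {
    out <- series[0, , drop = FALSE]
    out$observed <- numeric(0)
    out$ppm <- numeric(0)
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
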