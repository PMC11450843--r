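#' Construct a GenBank-style record object
#'
#' Lightweight in-memory representation of a nucleotide record: a sequence
#' plus a feature table. Coordinates in the feature table are 1-based
#' inclusive (GenBank convention); all internal neighbourhood arithmetic
#' uses 0-based half-open coordinates and converts at the boundary.
#'
#' @param id Record identifier (LOCUS name).
#' @param sequence Nucleotide string (A/C/G/T/N, uppercased on input).
#' @param features List of features, each a list with `type`, `start`,
#'   `end` (1-based inclusive), `strand` (`"+"` or `"-"`) and `qualifiers`
#'   (named character vector, e.g. `product`, `protein_id`, `note`,
#'   `translation`).
#' @return An object of class `gbk_record`.
#' @export
gbk_record <- function(id, sequence, features = list()) {
  sequence <- toupper(sequence)
  for (f in features) {
    stopifnot(f$start >= 1L, f$end <= nchar(sequence), f$start <= f$end,
              f$strand %in% c("+", "-"))
  }
  structure(list(id = as.character(id), sequence = sequence,
                 features = features),
            class = "gbk_record")
}

#' @export
print.gbk_record <- function(x, ...) {
  cat("gbk_record", x$id, ":", nchar(x$sequence), "bp,",
      length(x$features), "features\n")
  invisible(x)
}

wrap_qualifier <- function(key, value, width = 58L) {
  text <- sprintf("/%s=\"%s\"", key, value)
  out <- character(0)
  while (nchar(text) > width) {
    out <- c(out, substr(text, 1L, width))
    text <- substr(text, width + 1L, nchar(text))
  }
  c(out, text)
}

#' Write records to a GenBank flat file
#'
#' @param records A `gbk_record` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(records, path) {
  if (inherits(records, "gbk_record")) records <- list(records)
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error"))
    stop("cannot open GenBank output path: ", path)
  on.exit(close(con))
  for (rec in records) {
    n <- nchar(rec$sequence)
    writeLines(sprintf("LOCUS       %-16s %d bp    DNA     linear   BCT",
                       rec$id, n), con)
    writeLines(sprintf("DEFINITION  %s.", rec$id), con)
    writeLines("FEATURES             Location/Qualifiers", con)
    writeLines(sprintf("     %-16s%s", "source", sprintf("1..%d", n)), con)
    for (f in rec$features) {
      loc <- sprintf("%d..%d", f$start, f$end)
      if (f$strand == "-") loc <- sprintf("complement(%s)", loc)
      writeLines(sprintf("     %-16s%s", f$type, loc), con)
      quals <- f$qualifiers
      for (k in names(quals)) {
        for (line in wrap_qualifier(k, quals[[k]]))
          writeLines(paste0(strrep(" ", 21L), line), con)
      }
    }
    writeLines("ORIGIN", con)
    pos <- seq(1L, n, by = 60L)
    for (p in pos) {
      chunk <- substr(rec$sequence, p, min(p + 59L, n))
      tens <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(1L, nchar(chunk), 10L) + 9L, nchar(chunk)))
      writeLines(sprintf("%9d %s", p, paste(tolower(tens), collapse = " ")),
                 con)
    }
    writeLines("//", con)
  }
  invisible(path)
}

parse_location <- function(loc) {
  strand <- "+"
  loc <- gsub("[<>]", "", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  parts <- as.integer(strsplit(loc, "\\.\\.")[[1L]])
  if (length(parts) == 1L) parts <- c(parts, parts)
  list(start = parts[1L], end = parts[2L], strand = strand)
}

parse_one_record <- function(lines) {
  locus <- grep("^LOCUS", lines, value = TRUE)[1L]
  id <- strsplit(trimws(sub("^LOCUS", "", locus)), "\\s+")[[1L]][1L]
  fstart <- grep("^FEATURES", lines)[1L]
  ostart <- grep("^ORIGIN", lines)[1L]
  features <- list()
  if (!is.na(fstart) && !is.na(ostart) && ostart > fstart + 1L) {
    block <- lines[(fstart + 1L):(ostart - 1L)]
    cur <- NULL
    pending <- ""
    flush_qual <- function(f, q) {
      if (!nzchar(q)) return(f)
      q <- sub("^/", "", q)
      eq <- regexpr("=", q, fixed = TRUE)
      if (eq > 0) {
        key <- substr(q, 1L, eq - 1L)
        val <- gsub("^\"|\"$", "", substr(q, eq + 1L, nchar(q)))
      } else {
        key <- q
        val <- ""
      }
      f$qualifiers[[key]] <- val
      f
    }
    for (line in block) {
      if (grepl("^ {5}\\S", line)) {          # new feature line
        bits <- strsplit(trimws(line), "\\s+")[[1L]]
        if (!is.null(cur)) {
          cur <- flush_qual(cur, pending)
          pending <- ""
          if (cur$type != "source") features[[length(features) + 1L]] <- cur
        }
        loc <- parse_location(bits[2L])
        cur <- list(type = bits[1L], start = loc$start, end = loc$end,
                    strand = loc$strand, qualifiers = character(0))
      } else if (grepl("^ {21}/", line)) {    # new qualifier
        cur <- flush_qual(cur, pending)
        pending <- trimws(line)
      } else {                                # continuation
        pending <- paste0(pending, trimws(line))
      }
    }
    if (!is.null(cur)) {
      cur <- flush_qual(cur, pending)
      if (cur$type != "source") features[[length(features) + 1L]] <- cur
    }
  }
  seq_lines <- lines[(ostart + 1L):length(lines)]
  seq <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  gbk_record(id, seq, features)
}

#' Read a GenBank flat file
#'
#' Parses LOCUS, the feature table (simple and `complement()` locations,
#' multi-line qualifiers) and ORIGIN. Multi-record files are supported.
#'
#' @param path Path to a GenBank flat file.
#' @return List of `gbk_record` objects.
#' @export
read_genbank <- function(path) {
  if (!file.exists(path)) stop("GenBank file not found: ", path)
  lines <- readLines(path)
  ends <- grep("^//\\s*$", lines)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  recs <- lapply(seq_along(ends), function(i) {
    chunk <- lines[starts[i]:(ends[i] - 1L)]
    chunk <- chunk[nzchar(trimws(chunk)) | seq_along(chunk) > 0]
    parse_one_record(chunk)
  })
  recs
}
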