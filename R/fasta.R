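# FASTA input with an optional trailing dot-bracket structure line per record.

.structure_alphabet <- "^[.()\\[\\]{}<>A-Za-z]+$"  # needs perl = TRUE
.bracket_chars <- "[.()\\[\\]{}<>]"

#' Normalize an RNA sequence
#'
#' Uppercases, maps T to U and replaces characters outside `A C G U N`
#' by `N` (with a warning).
#'
#' @param seq character scalar.
#' @return Normalized sequence string.
#' @export
normalize_rna <- function(seq) {
  s <- toupper(seq)
  s <- gsub("T", "U", s, fixed = TRUE)
  bad <- gsub("[ACGUN]", "", s)
  if (nchar(bad) > 0L) {
    warning("replacing ", nchar(bad), " non-ACGUN character(s) by N")
    s <- gsub("[^ACGUN]", "N", s)
  }
  s
}

#' Read FASTA records with optional structure lines
#'
#' Each record is a `>` header, one or more sequence lines, and optionally a
#' dot-bracket structure line (possibly wrapped over several lines).  A line
#' is treated as structure when it contains at least one bracket-alphabet
#' symbol (`.()[]{}<>`); lines of letters only are sequence.  Sequences are
#' normalized via [normalize_rna()] and the structure, if present, is parsed
#' with [parse_dotbracket()] and length-checked.
#'
#' @param path file path, or a character vector of lines via `text`.
#' @param text optional character vector of lines (overrides `path`).
#' @return A list of records: `id`, `sequence`, `structure` (or `NULL`).
#' @export
#' @examples
#' read_fasta(text = c(">s", "GGGAAACCC", "(((...)))"))[[1]]$structure$pairs
read_fasta <- function(path = NULL, text = NULL) {
  lines <- if (!is.null(text)) text else readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty FASTA input")
  if (!startsWith(lines[1], ">")) stop("FASTA input must start with '>'")
  records <- list()
  id <- NULL; seq_parts <- character(); struct_parts <- character()
  flush <- function() {
    if (is.null(id)) return()
    seq <- normalize_rna(paste(seq_parts, collapse = ""))
    if (nchar(seq) == 0L) stop("record '", id, "' has an empty sequence")
    struct <- NULL
    if (length(struct_parts) > 0L) {
      db <- paste(struct_parts, collapse = "")
      if (nchar(db) != nchar(seq)) {
        stop("structure length ", nchar(db), " != sequence length ",
             nchar(seq), " in record '", id, "'")
      }
      struct <- parse_dotbracket(db)
    }
    records[[length(records) + 1L]] <<- list(id = id, sequence = seq,
                                             structure = struct)
  }
  for (ln in lines) {
    if (startsWith(ln, ">")) {
      flush()
      id <- sub("^>\\s*", "", ln)
      id <- strsplit(id, "\\s+")[[1]][1]
      seq_parts <- character(); struct_parts <- character()
    } else {
      # A structure line contains at least one true bracket symbol; lines of
      # letters only (ambiguous with Aa..Zz pseudoknot pages) count as
      # sequence unless a structure line has already started in this record.
      is_struct <- grepl(.structure_alphabet, ln, perl = TRUE) &&
        (grepl(.bracket_chars, ln, perl = TRUE) || length(struct_parts) > 0L)
      if (is_struct && length(seq_parts) == 0L) {
        stop("structure line before any sequence in record '", id, "'")
      }
      if (is_struct) struct_parts <- c(struct_parts, ln)
      else seq_parts <- c(seq_parts, ln)
    }
  }
  flush()
  records
}

#' Write FASTA records
#'
#' @param records list of records as returned by [read_fasta()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  out <- character()
  for (r in records) {
    out <- c(out, paste0(">", r$id), r$sequence)
    if (!is.null(r$structure)) out <- c(out, to_dotbracket(r$structure))
  }
  writeLines(out, path)
  invisible(path)
}
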