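# Secondary structure container and dot-bracket notation.
#
# Pairs are stored 1-based with i < j.  Each pair carries a "page": page 0 is
# the nested skeleton used for geometry, pages >= 1 hold pseudoknotted pairs
# that cross the skeleton.  Bracket families are fixed in the order
# ( ), [ ], { }, < >, Aa, Bb ... Zz, so up to 30 pages can be written out.

.bracket_open  <- c("(", "[", "{", "<", LETTERS)
.bracket_close <- c(")", "]", "}", ">", letters)

#' Secondary structure of an RNA sequence
#'
#' Constructs a validated secondary structure: a set of base pairs over a
#' sequence of given length, each pair assigned to a non-crossing "page"
#' (page 0 is the nested skeleton; pages >= 1 are pseudoknots).
#'
#' @param length number of nucleotides.
#' @param pairs data frame with integer columns `i`, `j` (1-based, `i < j`),
#'   optional `page` (default 0) and logical `predicted` (default `FALSE`).
#' @return An object of class `rna_structure` with elements `length`,
#'   `pairs` (sorted by `i`) and `partner` (integer vector, `NA` = unpaired).
#' @export
#' @examples
#' s <- rna_structure(7, data.frame(i = c(1, 2), j = c(7, 6)))
#' s$partner
rna_structure <- function(length, pairs = NULL) {
  length <- as.integer(length)
  if (is.na(length) || length < 0L) stop("invalid structure length")
  if (is.null(pairs) || nrow(pairs) == 0L) {
    pairs <- data.frame(i = integer(), j = integer(), page = integer(),
                        predicted = logical())
  } else {
    pairs <- as.data.frame(pairs)
    if (is.null(pairs$page)) pairs$page <- 0L
    if (is.null(pairs$predicted)) pairs$predicted <- FALSE
    pairs <- pairs[c("i", "j", "page", "predicted")]
    pairs$i <- as.integer(pairs$i)
    pairs$j <- as.integer(pairs$j)
    pairs$page <- as.integer(pairs$page)
    pairs$predicted <- as.logical(pairs$predicted)
  }
  if (any(pairs$i >= pairs$j)) stop("pair indices must satisfy i < j")
  if (any(pairs$i < 1L) || any(pairs$j > length)) {
    stop("pair index out of range 1..", length)
  }
  if (any(pairs$page < 0L)) stop("pages must be non-negative")
  idx <- c(pairs$i, pairs$j)
  if (anyDuplicated(idx)) {
    stop("position ", idx[duplicated(idx)][1], " participates in more than one pair")
  }
  pairs <- pairs[order(pairs$i, -pairs$j), , drop = FALSE]
  rownames(pairs) <- NULL
  # no two pairs on the same page may cross
  for (pg in unique(pairs$page)) {
    p <- pairs[pairs$page == pg, , drop = FALSE]
    if (nrow(p) > 1L && .any_crossing(p$i, p$j)) {
      stop("crossing pairs within page ", pg)
    }
  }
  partner <- rep(NA_integer_, length)
  partner[pairs$i] <- pairs$j
  partner[pairs$j] <- pairs$i
  structure(list(length = length, pairs = pairs, partner = partner),
            class = "rna_structure")
}

# TRUE if any two of the pairs (i, j) cross (i < k < j < l).
.any_crossing <- function(i, j) {
  n <- length(i)
  if (n < 2L) return(FALSE)
  for (a in seq_len(n - 1L)) {
    b <- (a + 1L):n
    if (any((i[a] < i[b] & i[b] < j[a] & j[a] < j[b]) |
            (i[b] < i[a] & i[a] < j[b] & j[b] < j[a]))) return(TRUE)
  }
  FALSE
}

#' @export
print.rna_structure <- function(x, ...) {
  cat("rna_structure: ", x$length, " nt, ", nrow(x$pairs), " pairs, ",
      length(unique(x$pairs$page)), " page(s)\n", sep = "")
  invisible(x)
}

#' @export
format.rna_structure <- function(x, ...) to_dotbracket(x)

#' Parse dot-bracket notation (pseudoknots allowed)
#'
#' Matches brackets with one stack per family; the page of a pair is the
#' rank of its bracket family in the fixed order `( ) [ ] { } < > Aa Bb ...`.
#' Dots are unpaired positions.
#'
#' @param text a single dot-bracket string.
#' @return An [rna_structure()].
#' @export
#' @examples
#' parse_dotbracket("((..[[..))..]]")$pairs
parse_dotbracket <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  nfam <- length(.bracket_open)
  stacks <- vector("list", nfam)
  res_i <- integer(); res_j <- integer(); res_p <- integer()
  for (pos in seq_len(n)) {
    ch <- chars[pos]
    if (ch == ".") next
    fo <- match(ch, .bracket_open)
    fc <- match(ch, .bracket_close)
    if (!is.na(fo)) {
      stacks[[fo]] <- c(stacks[[fo]], pos)
    } else if (!is.na(fc)) {
      st <- stacks[[fc]]
      if (length(st) == 0L) {
        stop("unbalanced '", .bracket_close[fc], "' at position ", pos)
      }
      op <- st[length(st)]
      stacks[[fc]] <- st[-length(st)]
      res_i <- c(res_i, op); res_j <- c(res_j, pos); res_p <- c(res_p, fc - 1L)
    } else {
      stop("illegal character '", ch, "' at position ", pos)
    }
  }
  for (f in seq_len(nfam)) {
    if (length(stacks[[f]]) > 0L) {
      stop("unbalanced '", .bracket_open[f], "' at position ", stacks[[f]][1])
    }
  }
  rna_structure(n, data.frame(i = res_i, j = res_j, page = res_p))
}

#' Serialize a secondary structure to dot-bracket notation
#'
#' Inverse of [parse_dotbracket()]: page `k` is written with the `k`-th
#' bracket family.
#'
#' @param structure an [rna_structure()].
#' @return A dot-bracket string.
#' @export
to_dotbracket <- function(structure) {
  stopifnot(inherits(structure, "rna_structure"))
  p <- structure$pairs
  if (nrow(p) > 0L && max(p$page) >= length(.bracket_open)) {
    stop("structure uses more pages (", max(p$page) + 1L,
         ") than available bracket families (", length(.bracket_open), ")")
  }
  out <- rep(".", structure$length)
  out[p$i] <- .bracket_open[p$page + 1L]
  out[p$j] <- .bracket_close[p$page + 1L]
  paste(out, collapse = "")
}

#' Assign pseudoknot pages to a set of base pairs
#'
#' Greedy first-fit page assignment: pairs are processed in order of
#' increasing `i` (ties: decreasing `j`) and each is placed on the lowest
#' page on which it crosses no previously placed pair.
#'
#' @param pairs data frame (or list coercible to one) with columns `i`, `j`.
#' @param length sequence length; defaults to `max(j)`.
#' @return An [rna_structure()] with pages assigned.
#' @export
#' @examples
#' assign_pages(data.frame(i = c(2, 5), j = c(9, 14)))$pairs$page
assign_pages <- function(pairs, length = NULL) {
  pairs <- as.data.frame(pairs)
  if (nrow(pairs) == 0L) {
    return(rna_structure(if (is.null(length)) 0L else length))
  }
  if (anyDuplicated(c(pairs$i, pairs$j))) stop("duplicate index use in pairs")
  ord <- order(pairs$i, -pairs$j)
  pairs <- pairs[ord, , drop = FALSE]
  page <- integer(nrow(pairs))
  for (a in seq_len(nrow(pairs))) {
    pg <- 0L
    repeat {
      on_page <- which(page[seq_len(a - 1L)] == pg)
      if (length(on_page) == 0L ||
          !.crosses_any(pairs$i[a], pairs$j[a],
                        pairs$i[on_page], pairs$j[on_page])) {
        break
      }
      pg <- pg + 1L
    }
    page[a] <- pg
  }
  if (is.null(length)) length <- max(pairs$j)
  rna_structure(length, data.frame(i = pairs$i, j = pairs$j, page = page))
}

.crosses_any <- function(i, j, is, js) {
  any((is < i & i < js & js < j) | (i < is & is < j & j < js))
}

#' Parse a Leontis-Westhof base-pair code
#'
#' Decodes codes like `"cWW"` or `"tHS"` (case-insensitive): glycosidic
#' orientation (cis/trans) followed by the interacting edge of each
#' nucleotide (Watson-Crick, Hoogsteen or Sugar).
#'
#' @param code a 3-character LW code.
#' @return A list with `orientation`, `edge5`, `edge3` and `code` (the
#'   canonical lowercase-orientation/uppercase-edge form).
#' @export
#' @examples
#' parse_lw("tHS")
parse_lw <- function(code) {
  stopifnot(is.character(code), length(code) == 1L)
  if (!grepl("^[ctCT][whsWHS][whsWHS]$", code)) {
    stop("unknown Leontis-Westhof code: '", code, "'")
  }
  edges <- c(W = "WatsonCrick", H = "Hoogsteen", S = "Sugar")
  ch <- strsplit(toupper(code), "")[[1]]
  canonical <- paste0(tolower(ch[1]), ch[2], ch[3])
  list(orientation = if (ch[1] == "C") "cis" else "trans",
       edge5 = unname(edges[ch[2]]),
       edge3 = unname(edges[ch[3]]),
       code = canonical)
}

#' Format Leontis-Westhof fields back to the canonical code
#'
#' @param orientation `"cis"` or `"trans"`.
#' @param edge5,edge3 `"WatsonCrick"`, `"Hoogsteen"` or `"Sugar"`.
#' @return The canonical code, e.g. `"cWW"`.
#' @export
format_lw <- function(orientation, edge5, edge3) {
  ab <- c(WatsonCrick = "W", Hoogsteen = "H", Sugar = "S")
  if (!orientation %in% c("cis", "trans") ||
      !edge5 %in% names(ab) || !edge3 %in% names(ab)) {
    stop("invalid Leontis-Westhof fields")
  }
  paste0(substr(orientation, 1, 1), ab[[edge5]], ab[[edge3]])
}
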