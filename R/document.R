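# RNA 2D JSON interchange documents.
#
# The dialect is frozen in this package (and mirrored by the machine-readable
# description in inst/schema/rna2d-dialect.json):
#   top level: "rnaComplexes" -> list of { "name", "rnaMolecules" }, plus a
#   "classes" style table.
#   molecule:  { "name",
#                "sequence":  [ { "residueName", "residueIndex" (1-based),
#                                 "x", "y", "styleClass" (optional) } ],
#                "basePairs": [ { "residueIndex1", "residueIndex2" (1-based),
#                                 "lw" ("canonical" or an LW code),
#                                 "predicted" } ],
#                "labels":    [ { "residueIndex", "label" } ] }
#   class:     { "name", "colour", "fontSize", "visibility" }

#' Construct an RNA 2D document
#'
#' @param molecules list of molecules; each a list with `name`, `residues`
#'   (data frame: `char`, `index`, `x`, `y`, optional `styleClass`),
#'   `labels` (data frame: `index`, `text`; may be empty) and `basePairs`
#'   (data frame: `i`, `j` 1-based, `lw`, `predicted`).
#' @param classes data frame of style classes (`name`, `colour`,
#'   `fontSize`, `visibility`); may be empty.
#' @return An object of class `rna2d_document`.
#' @export
rna2d_document <- function(molecules, classes = NULL) {
  if (is.null(classes)) {
    classes <- data.frame(name = character(), colour = character(),
                          fontSize = numeric(), visibility = character())
  }
  doc <- structure(list(molecules = molecules, classes = classes),
                   class = "rna2d_document")
  validate_document(doc)
  doc
}

#' Validate an RNA 2D document
#'
#' Checks required fields, that every base pair references existing
#' residues and that no coordinate is NaN; failures name the offending
#' path.
#'
#' @param doc an `rna2d_document`.
#' @return `doc`, invisibly.
#' @export
validate_document <- function(doc) {
  if (length(doc$molecules) == 0L) stop("document has no molecules")
  for (mi in seq_along(doc$molecules)) {
    mol <- doc$molecules[[mi]]
    path <- paste0("rnaComplexes[1].rnaMolecules[", mi, "]")
    if (is.null(mol$name)) stop("missing field: ", path, ".name")
    res <- mol$residues
    if (is.null(res) || nrow(res) == 0L) {
      stop("missing or empty field: ", path, ".sequence")
    }
    for (f in c("char", "index", "x", "y")) {
      if (is.null(res[[f]])) stop("missing field: ", path, ".sequence.", f)
    }
    if (any(!is.finite(res$x)) || any(!is.finite(res$y))) {
      bad <- which(!is.finite(res$x) | !is.finite(res$y))[1]
      stop("NaN coordinate at ", path, ".sequence[", bad, "]")
    }
    bp <- mol$basePairs
    if (!is.null(bp) && nrow(bp) > 0L) {
      n <- nrow(res)
      bad <- which(bp$i < 1L | bp$i > n | bp$j < 1L | bp$j > n)
      if (length(bad) > 0L) {
        stop("base pair ", path, ".basePairs[", bad[1], "] (",
             bp$i[bad[1]], ",", bp$j[bad[1]],
             ") references a nonexistent residue (n = ", n, ")")
      }
      for (code in unique(bp$lw)) {
        if (code != "canonical") parse_lw(code)
      }
    }
    lab <- mol$labels
    if (!is.null(lab) && nrow(lab) > 0L) {
      bad <- which(lab$index < 1L | lab$index > nrow(res))
      if (length(bad) > 0L) {
        stop("label ", path, ".labels[", bad[1], "] references a nonexistent residue")
      }
    }
  }
  invisible(doc)
}

#' Serialize a document to canonical JSON text
#'
#' The writer is canonical: serializing the result of [read_document()]
#' reproduces the input byte for byte.
#'
#' @param doc an `rna2d_document`.
#' @param path optional file to write to.
#' @return The JSON text (invisibly when `path` is given).
#' @export
write_document <- function(doc, path = NULL) {
  validate_document(doc)
  mols <- lapply(doc$molecules, function(mol) {
    res <- mol$residues
    seq_list <- lapply(seq_len(nrow(res)), function(k) {
      r <- list(residueName = res$char[k],
                residueIndex = as.integer(res$index[k]),
                x = as.numeric(res$x[k]), y = as.numeric(res$y[k]))
      if (!is.null(res$styleClass) && !is.na(res$styleClass[k]) &&
          nzchar(res$styleClass[k])) {
        r$styleClass <- res$styleClass[k]
      }
      r
    })
    bp <- mol$basePairs
    bp_list <- if (is.null(bp)) list() else lapply(seq_len(nrow(bp)), function(k) {
      list(residueIndex1 = as.integer(bp$i[k]),
           residueIndex2 = as.integer(bp$j[k]),
           lw = bp$lw[k], predicted = as.logical(bp$predicted[k]))
    })
    lab <- mol$labels
    lab_list <- if (is.null(lab)) list() else lapply(seq_len(nrow(lab)), function(k) {
      list(residueIndex = as.integer(lab$index[k]), label = lab$text[k])
    })
    list(name = mol$name, sequence = seq_list, basePairs = bp_list,
         labels = lab_list)
  })
  cls <- doc$classes
  cls_list <- lapply(seq_len(nrow(cls)), function(k) {
    list(name = cls$name[k], colour = cls$colour[k],
         fontSize = as.numeric(cls$fontSize[k]),
         visibility = cls$visibility[k])
  })
  top <- list(rnaComplexes = list(list(name = "complex", rnaMolecules = mols)),
              classes = cls_list)
  txt <- jsonlite::toJSON(top, auto_unbox = TRUE, digits = NA, null = "list",
                          pretty = TRUE)
  txt <- paste0(as.character(txt), "\n")
  if (!is.null(path)) {
    writeLines(txt, path, sep = "")
    return(invisible(txt))
  }
  txt
}

#' Parse an RNA 2D document from JSON text
#'
#' @param text JSON text, or a file path via `path`.
#' @param path optional file to read.
#' @return An `rna2d_document`.
#' @export
read_document <- function(text = NULL, path = NULL) {
  if (is.null(text)) text <- paste(readLines(path, warn = FALSE), collapse = "\n")
  top <- jsonlite::fromJSON(text, simplifyVector = FALSE)
  if (is.null(top$rnaComplexes)) stop("missing field: rnaComplexes")
  mols <- list()
  for (cx in top$rnaComplexes) {
    if (is.null(cx$rnaMolecules)) stop("missing field: rnaComplexes[].rnaMolecules")
    for (m in cx$rnaMolecules) {
      res <- m$sequence
      if (is.null(res)) stop("missing field: rnaMolecules[].sequence")
      residues <- data.frame(
        char = vapply(res, function(r) as.character(r$residueName), ""),
        index = vapply(res, function(r) as.integer(r$residueIndex), 0L),
        x = vapply(res, function(r) as.numeric(r$x), 0),
        y = vapply(res, function(r) as.numeric(r$y), 0),
        styleClass = vapply(res, function(r) {
          if (is.null(r$styleClass)) NA_character_ else as.character(r$styleClass)
        }, ""))
      bp <- m$basePairs
      basePairs <- if (is.null(bp) || length(bp) == 0L) {
        data.frame(i = integer(), j = integer(), lw = character(),
                   predicted = logical())
      } else {
        data.frame(
          i = vapply(bp, function(b) as.integer(b$residueIndex1), 0L),
          j = vapply(bp, function(b) as.integer(b$residueIndex2), 0L),
          lw = vapply(bp, function(b) as.character(b$lw), ""),
          predicted = vapply(bp, function(b) isTRUE(b$predicted), NA))
      }
      lb <- m$labels
      labels <- if (is.null(lb) || length(lb) == 0L) {
        data.frame(index = integer(), text = character())
      } else {
        data.frame(index = vapply(lb, function(l) as.integer(l$residueIndex), 0L),
                   text = vapply(lb, function(l) as.character(l$label), ""))
      }
      mols[[length(mols) + 1L]] <- list(name = m$name, residues = residues,
                                        labels = labels, basePairs = basePairs)
    }
  }
  cls <- top$classes
  classes <- if (is.null(cls) || length(cls) == 0L) NULL else data.frame(
    name = vapply(cls, function(c) as.character(c$name), ""),
    colour = vapply(cls, function(c) as.character(c$colour), ""),
    fontSize = vapply(cls, function(c) as.numeric(c$fontSize), 0),
    visibility = vapply(cls, function(c) as.character(c$visibility), ""))
  rna2d_document(mols, classes)
}

#' Build a document from a drawn molecule
#'
#' @param id molecule name.
#' @param seq RNA sequence.
#' @param structure an [rna_structure()]; page-0 pairs get `lw`
#'   `"canonical"`, with `predicted` carried over.
#' @param layout an [rna_layout()].
#' @param labels optional per-position numbering labels (`NA` = none).
#' @param lw_pairs optional data frame (`i`, `j`, `lw`) of Leontis-Westhof
#'   annotated pairs replacing the plain `"canonical"` tag on those pairs.
#' @return An `rna2d_document` with one molecule.
#' @export
as_rna2d_document <- function(id, seq, structure, layout, labels = NULL,
                              lw_pairs = NULL) {
  n <- nchar(seq)
  residues <- data.frame(char = strsplit(seq, "")[[1]],
                         index = seq_len(n),
                         x = layout$coords[, 1], y = layout$coords[, 2],
                         styleClass = NA_character_)
  p <- structure$pairs
  lw <- rep("canonical", nrow(p))
  if (!is.null(lw_pairs) && nrow(lw_pairs) > 0L) {
    for (k in seq_len(nrow(lw_pairs))) {
      hit <- which(p$i == lw_pairs$i[k] & p$j == lw_pairs$j[k])
      if (length(hit) > 0L) lw[hit] <- lw_pairs$lw[k]
    }
  }
  basePairs <- data.frame(i = p$i, j = p$j, lw = lw, predicted = p$predicted)
  lab <- if (is.null(labels)) {
    data.frame(index = integer(), text = character())
  } else {
    keep <- which(!is.na(labels))
    data.frame(index = keep, text = labels[keep])
  }
  rna2d_document(list(list(name = id, residues = residues, labels = lab,
                           basePairs = basePairs)))
}

#' Extract sequence, structure and layout from a document molecule
#'
#' @param doc an `rna2d_document`.
#' @param molecule molecule number (default 1).
#' @return A list with `id`, `seq`, `structure` (pages re-assigned via
#'   [assign_pages()]), `layout` and `labels`.
#' @export
document_to_drawing <- function(doc, molecule = 1L) {
  mol <- doc$molecules[[molecule]]
  seq <- paste(mol$residues$char, collapse = "")
  bp <- mol$basePairs
  struct <- if (nrow(bp) == 0L) {
    rna_structure(nrow(mol$residues))
  } else {
    s <- assign_pages(bp[c("i", "j")], length = nrow(mol$residues))
    s$pairs$predicted <- bp$predicted[match(paste(s$pairs$i, s$pairs$j),
                                            paste(bp$i, bp$j))]
    s
  }
  labels <- rep(NA_character_, nrow(mol$residues))
  if (nrow(mol$labels) > 0L) labels[mol$labels$index] <- mol$labels$text
  list(id = mol$name, seq = seq, structure = struct,
       layout = rna_layout(cbind(mol$residues$x, mol$residues$y)),
       labels = labels)
}
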