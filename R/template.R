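# Template records and the on-disk template library.
#
# A library is a directory with one sub-directory per template holding
#   template.fasta  sequence + dot-bracket structure line
#   coords.tsv      columns: index, x, y, label
#   meta.yaml       id, name, category
# plus an index.yaml at the top level listing the stage order.

#' Construct a layout template
#'
#' A template is a named record of sequence, secondary structure,
#' per-nucleotide drawing coordinates (y growing downward) and optional
#' numbering labels, tagged with a category used for staged selection.
#'
#' @param id unique identifier (used for deterministic tie-breaking).
#' @param sequence RNA sequence (normalized via [normalize_rna()]).
#' @param structure an [rna_structure()] of the same length.
#' @param coords numeric matrix `n x 2` (columns x, y), no NaN.
#' @param name human-readable name; defaults to `id`.
#' @param labels optional per-position character labels (`NA` = none).
#' @param category one of `"long"`, `"family"`, `"trna"`.
#' @return An object of class `rna_template`.
#' @export
rna_template <- function(id, sequence, structure, coords, name = id,
                         labels = NULL, category = "family") {
  sequence <- normalize_rna(sequence)
  n <- nchar(sequence)
  stopifnot(inherits(structure, "rna_structure"))
  if (structure$length != n) stop("structure length != sequence length")
  coords <- as.matrix(coords)
  if (nrow(coords) != n || ncol(coords) != 2L) {
    stop("coords must be an n x 2 matrix")
  }
  if (any(!is.finite(coords))) stop("coords contain NaN or infinite values")
  colnames(coords) <- c("x", "y")
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != n) stop("labels length != sequence length")
  }
  if (!category %in% c("long", "family", "trna")) {
    stop("unknown template category '", category, "'")
  }
  structure(list(id = id, name = name, sequence = sequence,
                 structure = structure, coords = coords,
                 labels = labels, category = category),
            class = "rna_template")
}

#' @export
print.rna_template <- function(x, ...) {
  cat("rna_template '", x$id, "' (", x$category, "): ",
      nchar(x$sequence), " nt, ", nrow(x$structure$pairs), " pairs\n",
      sep = "")
  invisible(x)
}

#' Write a template into a library directory
#'
#' @param template an [rna_template()].
#' @param library_dir library root (created if missing).
#' @param overwrite replace an existing template with the same id?
#' @return The template directory path, invisibly.
#' @export
write_template <- function(template, library_dir, overwrite = FALSE) {
  stopifnot(inherits(template, "rna_template"))
  dir.create(library_dir, recursive = TRUE, showWarnings = FALSE)
  tdir <- file.path(library_dir, template$id)
  if (dir.exists(tdir) && !overwrite) {
    stop("template id '", template$id, "' already exists in ", library_dir)
  }
  dir.create(tdir, showWarnings = FALSE)
  writeLines(c(paste0(">", template$id), template$sequence,
               to_dotbracket(template$structure)),
             file.path(tdir, "template.fasta"))
  lab <- if (is.null(template$labels)) rep("", nchar(template$sequence))
         else ifelse(is.na(template$labels), "", template$labels)
  tsv <- data.frame(index = seq_len(nchar(template$sequence)),
                    x = sprintf("%.6f", template$coords[, 1]),
                    y = sprintf("%.6f", template$coords[, 2]),
                    label = lab)
  utils::write.table(tsv, file.path(tdir, "coords.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  yaml::write_yaml(list(id = template$id, name = template$name,
                        category = template$category),
                   file.path(tdir, "meta.yaml"))
  invisible(tdir)
}

#' Read one template directory
#'
#' @param tdir path to a template directory.
#' @return An [rna_template()].
#' @export
read_template <- function(tdir) {
  meta <- yaml::read_yaml(file.path(tdir, "meta.yaml"))
  rec <- read_fasta(file.path(tdir, "template.fasta"))[[1]]
  if (is.null(rec$structure)) stop("template.fasta lacks a structure line")
  tsv <- utils::read.table(file.path(tdir, "coords.tsv"), sep = "\t",
                           header = TRUE, colClasses = c("integer", "numeric",
                                                         "numeric", "character"),
                           na.strings = NULL, quote = "")
  labels <- tsv$label
  if (all(!nzchar(labels))) labels <- NULL
  else labels[!nzchar(labels)] <- NA_character_
  rna_template(id = meta$id, name = meta$name, sequence = rec$sequence,
               structure = rec$structure,
               coords = cbind(tsv$x, tsv$y),
               labels = labels, category = meta$category)
}

#' Read a template library
#'
#' @param library_dir library root directory.
#' @return A list with `templates` (named list of [rna_template()]) and
#'   `stages` (category order from `index.yaml`, or the default order).
#' @export
read_library <- function(library_dir) {
  if (!dir.exists(library_dir)) stop("no such library: ", library_dir)
  dirs <- list.dirs(library_dir, recursive = FALSE)
  dirs <- dirs[file.exists(file.path(dirs, "meta.yaml"))]
  templates <- lapply(dirs, read_template)
  names(templates) <- vapply(templates, `[[`, "", "id")
  templates <- templates[order(names(templates))]
  idx <- file.path(library_dir, "index.yaml")
  stages <- if (file.exists(idx)) unlist(yaml::read_yaml(idx)$stages)
            else c("long", "family", "trna")
  list(templates = templates, stages = stages)
}

#' Write the library index (stage order)
#'
#' @param library_dir library root.
#' @param stages category order for staged selection.
#' @export
write_library_index <- function(library_dir,
                                stages = c("long", "family", "trna")) {
  dir.create(library_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(list(stages = as.list(stages)),
                   file.path(library_dir, "index.yaml"))
  invisible(file.path(library_dir, "index.yaml"))
}
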