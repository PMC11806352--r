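# Layout container: per-nucleotide 2D coordinates plus provenance flags.

#' Construct a layout
#'
#' @param coords numeric `n x 2` matrix of drawing coordinates (y down).
#' @param provenance per-position flag in `inherited`, `rearranged`,
#'   `inserted`; defaults to all `inherited`.
#' @return An object of class `rna_layout`.
#' @export
rna_layout <- function(coords, provenance = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 2L) stop("coords must have two columns")
  if (any(!is.finite(coords))) stop("layout contains NaN or infinite coordinates")
  colnames(coords) <- c("x", "y")
  n <- nrow(coords)
  if (is.null(provenance)) provenance <- rep("inherited", n)
  if (length(provenance) != n ||
      !all(provenance %in% c("inherited", "rearranged", "inserted"))) {
    stop("invalid provenance flags")
  }
  structure(list(coords = coords, provenance = provenance),
            class = "rna_layout")
}

#' @export
print.rna_layout <- function(x, ...) {
  tab <- table(factor(x$provenance,
                      c("inherited", "rearranged", "inserted")))
  cat("rna_layout: ", nrow(x$coords), " nt (",
      paste(names(tab), tab, sep = "=", collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Diagnostics on layout invariants
#'
#' Reports backbone-neighbour distances relative to the base spacing and
#' the minimum distance between non-neighbouring nucleotides (clash guard).
#'
#' @param layout an [rna_layout()].
#' @param structure optional [rna_structure()] so that base-pair partners
#'   are excluded from the clash check.
#' @return A list with `backbone_range` (min/max neighbour distance) and
#'   `min_clash_distance`.
#' @export
check_layout <- function(layout, structure = NULL) {
  xy <- layout$coords
  n <- nrow(xy)
  if (n < 2L) return(list(backbone_range = c(NA, NA), min_clash_distance = NA))
  dd <- sqrt(rowSums((xy[-1, , drop = FALSE] - xy[-n, , drop = FALSE])^2))
  partner <- if (is.null(structure)) rep(NA_integer_, n) else structure$partner
  mind <- Inf
  for (a in seq_len(n - 1L)) {
    b <- (a + 2L):n
    b <- b[b <= n]
    if (length(b) == 0L) next
    if (!is.na(partner[a])) b <- setdiff(b, partner[a])
    if (length(b) == 0L) next
    d2 <- (xy[b, 1] - xy[a, 1])^2 + (xy[b, 2] - xy[a, 2])^2
    mind <- min(mind, sqrt(min(d2)))
  }
  list(backbone_range = range(dd), min_clash_distance = mind)
}
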