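# Template-free radial layout, overlap scoring, layout choice and
# conversion of a layout into a reusable template.

#' Template-free radial layout
#'
#' Draws a sequence with its secondary structure from scratch: the exterior
#' loop runs left to right along a horizontal line at `BASE_SPACING`
#' intervals (5' at the origin), helices are straight ladders branching
#' towards -y (up on screen) or radially off their parent loop circle, and
#' each loop's positions sit uniformly on a circle whose circumference is
#' one `BASE_SPACING` slot per nucleotide on the loop cycle.  Base-pair
#' partners are exactly `PAIR_DISTANCE` apart.  Pseudoknot pages never
#' influence geometry.  Deterministic: identical inputs give bit-identical
#' outputs.
#'
#' @param seq RNA sequence (only its length is used).
#' @param structure an [rna_structure()] of the same length.
#' @return An [rna_layout()] (all positions flagged `inherited`).
#' @export
#' @examples
#' s <- parse_dotbracket("((((....))))")
#' layout_radial("GGGGAAAACCCC", s)
layout_radial <- function(seq, structure) {
  n <- nchar(seq)
  if (structure$length != n) stop("structure length != sequence length")
  tree <- build_tree(structure)
  coords <- matrix(NA_real_, n, 2)

  draw_helix <- function(hid, A, B, u) {
    h <- tree$elements[[hid]]
    np <- nrow(h$pairs)
    for (k in seq_len(np)) {
      coords[h$pairs$i[k], ] <<- A + (k - 1) * HELIX_RISE * u
      coords[h$pairs$j[k], ] <<- B + (k - 1) * HELIX_RISE * u
    }
    P5 <- A + (np - 1) * HELIX_RISE * u
    P3 <- B + (np - 1) * HELIX_RISE * u
    draw_loop(h$children[1], P5, P3, u)
  }

  draw_loop <- function(lid, P5, P3, u) {
    lp <- tree$elements[[lid]]
    entries <- lp$cycle[!(seq_along(lp$cycle) %in%
                          c(1L, length(lp$cycle)))]  # drop closing bases
    K <- length(entries)
    if (K == 0L) return(invisible())
    circ <- .loop_circle(P5, P3, K + 2L, side = u)
    slots <- .arc_slots(circ, P5, P3, K)
    # first pass: record slot coordinates
    for (t in seq_len(K)) coords[entries[t], ] <<- slots[t, ]
    # second pass: child helices leave radially, partners exactly
    # PAIR_DISTANCE apart about the midpoint of their two anchor slots
    t <- 1L
    while (t <= K) {
      p <- entries[t]
      if (!is.na(structure$partner[p]) && t < K &&
          entries[t + 1L] == structure$partner[p]) {
        M <- (slots[t, ] + slots[t + 1L, ]) / 2
        uc <- .unit(M - circ$centre)
        w <- .rot90(uc)
        if (sum(w * (slots[t + 1L, ] - slots[t, ])) < 0) w <- -w
        hid <- tree$elem_of[p]
        draw_helix(hid, M - (PAIR_DISTANCE / 2) * w,
                   M + (PAIR_DISTANCE / 2) * w, uc)
        t <- t + 2L
      } else {
        t <- t + 1L
      }
    }
    invisible()
  }

  # exterior loop: horizontal line, helices branch to -y
  ext <- tree$elements[[tree$root]]
  x <- 0
  t <- 1L
  cyc <- ext$cycle
  while (t <= length(cyc)) {
    p <- cyc[t]
    if (!is.na(structure$partner[p]) && structure$partner[p] > p &&
        tree$elements[[tree$elem_of[p]]]$type == "helix") {
      A <- c(x, 0); B <- c(x + PAIR_DISTANCE, 0)
      draw_helix(tree$elem_of[p], A, B, c(0, -1))
      x <- x + PAIR_DISTANCE + BASE_SPACING
      t <- t + 2L  # skip the partner anchor entry
    } else {
      coords[p, ] <- c(x, 0)
      x <- x + BASE_SPACING
      t <- t + 1L
    }
  }
  rna_layout(coords)
}

#' Count drawing overlaps in a layout
#'
#' The overlap score is the number of intersecting pairs among drawn
#' segments (backbone edges plus page-0 base-pair edges), excluding pairs of
#' segments that share a nucleotide endpoint, plus the number of nucleotide
#' pairs closer than `0.5 * BASE_SPACING` that are neither backbone
#' neighbours nor base-pair partners.
#'
#' @param layout an [rna_layout()].
#' @param structure an [rna_structure()].
#' @return Non-negative integer count.
#' @export
count_overlaps <- function(layout, structure) {
  xy <- layout$coords
  n <- nrow(xy)
  segs <- NULL
  if (n >= 2L) segs <- cbind(seq_len(n - 1L), 2:n)
  p0 <- structure$pairs[structure$pairs$page == 0L, , drop = FALSE]
  if (nrow(p0) > 0L) segs <- rbind(segs, cbind(p0$i, p0$j))
  count <- 0L
  ns <- if (is.null(segs)) 0L else nrow(segs)
  if (ns >= 2L) {
    for (a in seq_len(ns - 1L)) {
      for (b in (a + 1L):ns) {
        if (length(intersect(segs[a, ], segs[b, ])) > 0L) next
        if (.segments_intersect(xy[segs[a, 1], ], xy[segs[a, 2], ],
                                xy[segs[b, 1], ], xy[segs[b, 2], ])) {
          count <- count + 1L
        }
      }
    }
  }
  # proximity clashes
  partner <- structure$partner
  lim2 <- (0.5 * BASE_SPACING)^2
  for (a in seq_len(max(n - 1L, 0L))) {
    for (b in (a + 1L):n) {
      if (b == a + 1L) next
      if (!is.na(partner[a]) && partner[a] == b) next
      d2 <- sum((xy[b, ] - xy[a, ])^2)
      if (d2 < lim2) count <- count + 1L
    }
  }
  count
}

# Robust segment intersection (shared coordinates count as intersecting;
# collinear overlap counts as intersecting).
.segments_intersect <- function(p1, p2, p3, p4) {
  d1 <- .cross_sign(p3, p4, p1)
  d2 <- .cross_sign(p3, p4, p2)
  d3 <- .cross_sign(p1, p2, p3)
  d4 <- .cross_sign(p1, p2, p4)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  (d1 == 0 && .on_segment(p3, p4, p1)) ||
  (d2 == 0 && .on_segment(p3, p4, p2)) ||
  (d3 == 0 && .on_segment(p1, p2, p3)) ||
  (d4 == 0 && .on_segment(p1, p2, p4))
}

.cross_sign <- function(a, b, c) {
  v <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  if (abs(v) < 1e-9) 0 else sign(v)
}

.on_segment <- function(a, b, p) {
  min(a[1], b[1]) - 1e-9 <= p[1] && p[1] <= max(a[1], b[1]) + 1e-9 &&
  min(a[2], b[2]) - 1e-9 <= p[2] && p[2] <= max(a[2], b[2]) + 1e-9
}

#' Choose among candidate layouts by overlap count
#'
#' Returns the candidate with the fewest overlaps (ties: first in input
#' order).  A `forced` name short-circuits the choice.
#'
#' @param candidates named list of [rna_layout()] objects.
#' @param structure the [rna_structure()] shared by all candidates.
#' @param forced optional candidate name to force.
#' @return A list with `name`, `layout` and `overlaps`.
#' @export
choose_layout <- function(candidates, structure, forced = NULL) {
  if (length(candidates) == 0L) stop("no candidate layouts")
  if (!is.null(forced)) {
    if (!forced %in% names(candidates)) {
      stop("forced layout '", forced, "' not among candidates")
    }
    lay <- candidates[[forced]]
    return(list(name = forced, layout = lay,
                overlaps = count_overlaps(lay, structure)))
  }
  counts <- vapply(candidates, count_overlaps, 0L, structure = structure)
  best <- which.min(counts)  # first minimum wins ties
  list(name = names(candidates)[best], layout = candidates[[best]],
       overlaps = counts[[best]])
}

#' Turn a layout into a reusable template
#'
#' Freezes a sequence, structure and layout as a `"family"`-category
#' template, optionally writing it into a library directory.  Laying out
#' the same sequence on the resulting template (identity alignment)
#' reproduces the coordinates exactly.
#'
#' @param id template id.
#' @param seq RNA sequence.
#' @param structure an [rna_structure()].
#' @param layout an [rna_layout()].
#' @param library_dir optional library to write into.
#' @param overwrite replace an existing template of the same id?
#' @return The new [rna_template()].
#' @export
make_template <- function(id, seq, structure, layout,
                          library_dir = NULL, overwrite = FALSE) {
  tp <- rna_template(id = id, sequence = seq, structure = structure,
                     coords = layout$coords, category = "family")
  if (!is.null(library_dir)) write_template(tp, library_dir, overwrite)
  tp
}
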