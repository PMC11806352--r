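# Template-based layout: inherit template coordinates for matched
# positions and locally rearrange the elements touched by insertions or
# deletions, keeping everything else bit-identical to the template.

#' Lay out a query on a template
#'
#' Matched positions inherit the template's coordinates exactly.  Elements
#' touched by an edit are rearranged locally:
#' \itemize{
#'   \item a helix that gained or lost pairs is re-laddered along the
#'     template helix axis, anchored at its outermost transferred pair;
#'   \item a hairpin loop containing an indel is redistributed uniformly on
#'     the circle through its closing-pair anchors, with circumference one
#'     `BASE_SPACING` slot per loop position (plus the two closing bases),
#'     centred on the side of the original loop centroid;
#'   \item in internal, multibranch and exterior loops the child-helix
#'     anchors stay fixed and only the unpaired run containing the edit is
#'     re-placed on an arc between its flanking anchors
#'     (see [place_unfolded_insertion()]).
#' }
#' All positions outside affected elements keep coordinates bit-identical
#' to the template.  Pseudoknot pairs (pages >= 1) never influence
#' geometry.
#'
#' @param query query sequence.
#' @param qstruct the query's [rna_structure()] (typically from
#'   [transfer_structure()], plus any folded additions).
#' @param template the chosen [rna_template()].
#' @param aln the `rna_alignment` of query onto template.
#' @return An [rna_layout()] with provenance flags `inherited`,
#'   `rearranged` or `inserted`.
#' @export
layout_from_template <- function(query, qstruct, template, aln) {
  n <- nchar(query)
  if (qstruct$length != n || length(aln$posmap) != n) {
    stop("alignment/structure length mismatch with query")
  }
  if (length(aln$revmap) != nchar(template$sequence)) {
    stop("alignment length mismatch with template")
  }
  tcoords <- template$coords
  posmap <- aln$posmap
  coords <- matrix(NA_real_, n, 2)
  matched <- !is.na(posmap)
  coords[matched, ] <- tcoords[posmap[matched], , drop = FALSE]

  tree <- build_tree(qstruct)
  tpartner0 <- local({
    p0 <- template$structure$pairs[template$structure$pairs$page == 0L, ,
                                   drop = FALSE]
    v <- rep(NA_integer_, nchar(template$sequence))
    v[p0$i] <- p0$j; v[p0$j] <- p0$i
    v
  })

  # --- edit events -------------------------------------------------------
  ins_pos <- which(!matched)
  del_edge <- rep(FALSE, max(n - 1L, 0L))   # template gap inside edge p..p+1
  if (n >= 2L) {
    a <- posmap[-n]; b <- posmap[-1L]
    del_edge <- !is.na(a) & !is.na(b) & (b - a > 1L)
  }
  ins_edge <- rep(FALSE, max(n - 1L, 0L))   # an inserted endpoint
  if (n >= 2L) ins_edge <- !matched[-n] | !matched[-1L]

  affected <- rep(FALSE, length(tree$elements))
  mark <- function(eid) if (!is.na(eid)) affected[eid] <<- TRUE
  for (p in ins_pos) mark(tree$elem_of[p])
  for (p in which(del_edge | ins_edge)) mark(tree$edge_of[p])

  # a pair is "transferred" when both partners match template positions
  # that pair with each other in the template
  pair_transferred <- function(i, j) {
    !is.na(posmap[i]) && !is.na(posmap[j]) &&
      !is.na(tpartner0[posmap[i]]) && tpartner0[posmap[i]] == posmap[j]
  }

  # helices mixing transferred and novel pairs must be re-laddered too
  for (el in tree$elements) {
    if (el$type != "helix") next
    tr <- mapply(pair_transferred, el$pairs$i, el$pairs$j)
    if (any(tr) && !all(tr)) affected[el$id] <- TRUE
  }

  # --- re-ladder affected helices ---------------------------------------
  for (el in tree$elements) {
    if (el$type != "helix" || !affected[el$id]) next
    tr <- which(mapply(pair_transferred, el$pairs$i, el$pairs$j))
    if (length(tr) == 0L) next  # fully novel helix: left to arc fallback
    k0 <- tr[1]                  # outermost transferred pair = anchor
    ti <- posmap[el$pairs$i[k0]]; tj <- posmap[el$pairs$j[k0]]
    a5 <- tcoords[ti, ]; a3 <- tcoords[tj, ]
    u <- .template_helix_axis(tpartner0, tcoords, ti, tj)
    for (k in seq_len(nrow(el$pairs))) {
      off <- (k - k0) * HELIX_RISE
      coords[el$pairs$i[k], ] <- a5 + off * u
      coords[el$pairs$j[k], ] <- a3 + off * u
    }
  }

  # --- rearrange affected loops (anchors use current coordinates) -------
  for (el in tree$elements) {
    if (!el$type %in% c("hairpin", "internal", "multibranch", "exterior") ||
        !affected[el$id]) next
    if (el$type == "hairpin") {
      coords <- .rearrange_hairpin(el, coords, matched)
    } else {
      coords <- .rearrange_open_loop(el, coords, matched, del_edge, n)
    }
  }

  # --- fallback for any still-unplaced positions ------------------------
  coords <- .fill_gaps(coords)

  prov <- ifelse(!matched, "inserted",
          ifelse(abs(coords[, 1] - tcoords[ifelse(matched, posmap, 1L), 1]) == 0 &
                 abs(coords[, 2] - tcoords[ifelse(matched, posmap, 1L), 2]) == 0,
                 "inherited", "rearranged"))
  rna_layout(coords, prov)
}

# Axis of the template helix containing pair (ti, tj): unit vector from the
# outermost towards the innermost stacked pair; single-pair helices use the
# perpendicular of the pair chord pointing into the enclosed region.
.template_helix_axis <- function(tpartner0, tcoords, ti, tj) {
  lo <- ti; hi <- tj
  while (lo - 1L >= 1L && !is.na(tpartner0[lo - 1L]) &&
         tpartner0[lo - 1L] == hi + 1L) { lo <- lo - 1L; hi <- hi + 1L }
  li <- ti; lj <- tj
  while (!is.na(tpartner0[li + 1L]) && tpartner0[li + 1L] == lj - 1L) {
    li <- li + 1L; lj <- lj - 1L
  }
  outer_mid <- (tcoords[lo, ] + tcoords[hi, ]) / 2
  inner_mid <- (tcoords[li, ] + tcoords[lj, ]) / 2
  u <- .unit(inner_mid - outer_mid)
  if (all(u == 0)) {
    # single pair: perpendicular to the chord, towards the enclosed region
    u <- .rot90(.unit(tcoords[tj, ] - tcoords[ti, ]))
    if (tj - ti > 1L) {
      inside <- colMeans(tcoords[(ti + 1L):(tj - 1L), , drop = FALSE])
      if (sum(u * (inside - outer_mid)) < 0) u <- -u
    }
  }
  u
}

# Hairpin rearrangement: all members on the circle through the (already
# placed) closing anchors, centred on the side of the original centroid.
.rearrange_hairpin <- function(el, coords, matched) {
  c5 <- el$closing[1]; c3 <- el$closing[2]
  P5 <- coords[c5, ]; P3 <- coords[c3, ]
  # a fully novel closing pair has no coordinates yet; leave the loop to
  # the arc fallback
  if (anyNA(P5) || anyNA(P3)) return(coords)
  members <- el$positions
  K <- length(members)
  if (K == 0L) return(coords)
  mid <- (P5 + P3) / 2
  placed <- members[matched[members] & !is.na(coords[members, 1])]
  side <- if (length(placed) > 0L) {
    colMeans(coords[placed, , drop = FALSE]) - mid
  } else {
    .rot90(.unit(P3 - P5))
  }
  circ <- .loop_circle(P5, P3, K + 2L, side = side)
  slots <- .arc_slots(circ, P5, P3, K)
  coords[members, ] <- slots
  coords
}

# Internal / multibranch / exterior loops: anchors stay fixed; each
# unpaired run containing an edit is re-placed on an arc between its
# flanking anchors, bulging away from the loop centroid.
.rearrange_open_loop <- function(el, coords, matched, del_edge, n) {
  cyc <- el$cycle
  # anchors without coordinates (outer bases of fully novel helices inside
  # an inserted run) are treated as ordinary gap members
  anc <- el$anchor & !is.na(coords[el$cycle, 1])
  anchors <- cyc[anc]
  centroid <- if (length(anchors) > 0L) {
    colMeans(coords[anchors, , drop = FALSE])
  } else NULL
  runs <- .cycle_runs(cyc, anc)
  for (run in runs) {
    mem <- run$members
    has_edit <- any(!matched[mem]) || anyNA(coords[mem, 1])
    span <- c(run$left, mem, run$right)
    span <- span[!is.na(span)]
    if (length(span) >= 2L) {
      edges <- span[-length(span)]
      has_edit <- has_edit ||
        any(del_edge[edges[edges >= 1L & edges < n]])
    }
    if (!has_edit || length(mem) == 0L) next
    if (!is.na(run$left) && !is.na(run$right)) {
      coords[mem, ] <- place_unfolded_insertion(coords[run$left, ],
                                                coords[run$right, ],
                                                length(mem),
                                                away_from = centroid)
    } else {
      coords <- .place_terminal_run(coords, mem, run$left, run$right)
    }
  }
  coords
}

# Decompose a loop cycle into unpaired runs with their flanking anchors
# (NA flank = sequence end on the exterior loop).
.cycle_runs <- function(cyc, anc) {
  runs <- list()
  i <- 1L
  while (i <= length(cyc)) {
    if (anc[i]) { i <- i + 1L; next }
    j <- i
    while (j + 1L <= length(cyc) && !anc[j + 1L]) j <- j + 1L
    runs[[length(runs) + 1L]] <- list(
      members = cyc[i:j],
      left = if (i > 1L) cyc[i - 1L] else NA_integer_,
      right = if (j < length(cyc)) cyc[j + 1L] else NA_integer_)
    i <- j + 1L
  }
  runs
}

# Terminal unpaired run on the exterior loop: extend collinearly from the
# nearest placed backbone direction at BASE_SPACING steps.
.place_terminal_run <- function(coords, mem, left, right) {
  if (!is.na(left)) {
    ref <- left
    dirref <- if (ref - 1L >= 1L && !anyNA(coords[ref - 1L, ])) {
      .unit(coords[ref, ] - coords[ref - 1L, ])
    } else c(1, 0)
    for (t in seq_along(mem)) {
      coords[mem[t], ] <- coords[ref, ] + t * BASE_SPACING * dirref
    }
  } else if (!is.na(right)) {
    ref <- right
    dirref <- if (ref + 1L <= nrow(coords) && !anyNA(coords[ref + 1L, ])) {
      .unit(coords[ref, ] - coords[ref + 1L, ])
    } else c(-1, 0)
    for (t in seq_along(mem)) {
      coords[mem[rev(seq_along(mem))[t]], ] <-
        coords[ref, ] + t * BASE_SPACING * dirref
    }
  } else {
    # nothing placed at all: straight line
    for (t in seq_along(mem)) {
      coords[mem[t], ] <- c((t - 1) * BASE_SPACING, 0)
    }
  }
  coords
}

# Last resort: any position still NA is placed between its nearest placed
# neighbours (arc rule) or collinearly off the ends.
.fill_gaps <- function(coords) {
  n <- nrow(coords)
  if (!anyNA(coords)) return(coords)
  placed <- which(!is.na(coords[, 1]))
  if (length(placed) == 0L) {
    coords[] <- cbind((seq_len(n) - 1) * BASE_SPACING, 0)
    return(coords)
  }
  na_runs <- rle(is.na(coords[, 1]))
  pos <- 1L
  for (r in seq_along(na_runs$lengths)) {
    len <- na_runs$lengths[r]
    if (na_runs$values[r]) {
      mem <- pos:(pos + len - 1L)
      left <- if (pos > 1L) pos - 1L else NA_integer_
      right <- if (pos + len <= n) pos + len else NA_integer_
      if (!is.na(left) && !is.na(right)) {
        coords[mem, ] <- place_unfolded_insertion(coords[left, ],
                                                  coords[right, ], len)
      } else {
        coords <- .place_terminal_run(coords, mem, left, right)
      }
    }
    pos <- pos + len
  }
  coords
}

#' Transfer numbering labels from a template to the query
#'
#' Matched positions inherit the template's numbering label; inserted
#' positions get none; labels whose value is listed in `suppress` are
#' omitted (used e.g. for Sprinzl positions that do not exist in every
#' tRNA isotype).
#'
#' @param template an [rna_template()] with `labels`.
#' @param aln the `rna_alignment` of the query onto the template.
#' @param suppress character vector of label values to drop.
#' @return Character vector of per-query-position labels (`NA` = none).
#' @export
transfer_labels <- function(template, aln, suppress = character()) {
  if (is.null(template$labels)) {
    stop("template '", template$id, "' has no numbering labels")
  }
  out <- rep(NA_character_, length(aln$posmap))
  m <- !is.na(aln$posmap)
  out[m] <- template$labels[aln$posmap[m]]
  out[out %in% suppress] <- NA_character_
  out
}
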