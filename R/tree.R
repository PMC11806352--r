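# Decomposition of the page-0 (nested) skeleton into a tree of helices and
# loops.  Helices own their paired positions; loops own their unpaired
# members.  Each loop records its "cycle": the positions walked around the
# loop in backbone order (closing bases and child-helix outer bases flagged
# as anchors), which is what the layout engines consume.

#' Build the helix/loop tree of a secondary structure
#'
#' Uses page-0 pairs only; pseudoknot pages never influence geometry.
#' Maximal helices are runs of directly stacked pairs; loops are classified
#' by branching degree (hairpin, internal, multibranch) with the exterior
#' loop at the root.
#'
#' @param structure an [rna_structure()].
#' @return An object of class `rna_tree`: a list with `elements` (each
#'   having `id`, `type`, `positions`, `parent`, `children`, plus
#'   helix pairs or loop cycle/anchors), `elem_of` (position -> element id)
#'   and `edge_of` (backbone edge `p`..`p+1` -> element id).
#' @export
build_tree <- function(structure) {
  stopifnot(inherits(structure, "rna_structure"))
  n <- structure$length
  p0 <- structure$pairs[structure$pairs$page == 0L, , drop = FALSE]
  partner <- rep(NA_integer_, n)
  partner[p0$i] <- p0$j
  partner[p0$j] <- p0$i

  elements <- list()
  elem_of <- rep(NA_integer_, n)
  edge_of <- rep(NA_integer_, max(n - 1L, 0L))
  new_id <- function() length(elements) + 1L

  # walk positions lo..hi at one nesting level, attached to loop `loop_id`
  walk_level <- function(lo, hi, loop_id) {
    cycle <- integer(); anchor <- logical(); children <- integer()
    members <- integer()
    p <- lo
    while (p <= hi) {
      q <- partner[p]
      if (is.na(q)) {
        cycle <- c(cycle, p); anchor <- c(anchor, FALSE)
        members <- c(members, p)
        p <- p + 1L
      } else {
        # child helix (p, q): extend stacked run
        h <- 1L
        while (p + h < q - h && !is.na(partner[p + h]) &&
               partner[p + h] == q - h) h <- h + 1L
        hid <- new_id()
        hpos <- c(p:(p + h - 1L), (q - h + 1L):q)
        elements[[hid]] <<- list(id = hid, type = "helix",
                                 positions = sort(hpos),
                                 pairs = data.frame(i = p:(p + h - 1L),
                                                    j = q:(q - h + 1L)),
                                 parent = loop_id, children = integer())
        elem_of[hpos] <<- hid
        if (h > 1L) {
          edge_of[p:(p + h - 2L)] <<- hid
          edge_of[(q - h + 1L):(q - 1L)] <<- hid
        }
        children <- c(children, hid)
        cycle <- c(cycle, p, q); anchor <- c(anchor, TRUE, TRUE)
        # recurse into the loop closed by the innermost pair
        inner <- make_loop(p + h, q - h, closing = c(p + h - 1L, q - h + 1L),
                           parent = hid)
        elements[[hid]]$children <<- inner
        p <- q + 1L
      }
    }
    list(cycle = cycle, anchor = anchor, children = children,
         members = members)
  }

  make_loop <- function(lo, hi, closing, parent) {
    lid <- new_id()
    elements[[lid]] <<- list()  # reserve slot before recursion
    w <- walk_level(lo, hi, lid)
    cyc <- w$cycle; anc <- w$anchor
    if (!is.null(closing)) {
      cyc <- c(closing[1], cyc, closing[2])
      anc <- c(TRUE, anc, TRUE)
    }
    type <- if (is.null(closing)) "exterior"
            else if (length(w$children) == 0L) "hairpin"
            else if (length(w$children) == 1L) "internal"
            else "multibranch"
    elements[[lid]] <<- list(id = lid, type = type,
                             positions = w$members,
                             cycle = cyc, anchor = anc,
                             closing = closing,
                             parent = parent, children = w$children)
    if (length(w$members) > 0L) elem_of[w$members] <<- lid
    # backbone edges between numerically adjacent cycle entries
    if (length(cyc) > 1L) {
      a <- cyc[-length(cyc)]; b <- cyc[-1L]
      own <- which(b == a + 1L)
      if (length(own) > 0L) edge_of[a[own]] <<- lid
    }
    lid
  }

  root <- make_loop(1L, n, closing = NULL, parent = NA_integer_)
  structure(list(elements = elements, root = root,
                 elem_of = elem_of, edge_of = edge_of, length = n),
            class = "rna_tree")
}

#' @export
print.rna_tree <- function(x, ...) {
  types <- vapply(x$elements, `[[`, "", "type")
  cat("rna_tree: ", x$length, " nt; ", sum(types == "helix"), " helices, ",
      sum(types %in% c("hairpin", "internal", "multibranch")), " loops\n",
      sep = "")
  invisible(x)
}
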