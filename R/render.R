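# SVG rendering: full diagrams with data layers, Leontis-Westhof glyphs,
# pseudoknot connectors and dashed predicted pairs; simplified thumbnails;
# animated morphs.  Output is deterministic text (stable element order and
# number formatting), so byte-level regression diffs are meaningful.

.fmt <- function(x) sprintf("%.2f", x)

.svg_header <- function(xy, pad = 20) {
  x0 <- min(xy[, 1]) - pad; y0 <- min(xy[, 2]) - pad
  w <- diff(range(xy[, 1])) + 2 * pad
  h <- diff(range(xy[, 2])) + 2 * pad
  sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" ',
                 'viewBox="%s %s %s %s">'),
          .fmt(x0), .fmt(y0), .fmt(w), .fmt(h))
}

# Okabe-Ito derived colour-blind safe palette for the posterior bins,
# lowest confidence first.
.posterior_palette <- c("#D55E00", "#E69F00", "#56B4E9", "#0072B2")
.posterior_edges <- c(0, 0.8, 0.85, 0.9, 0.95)

#' Data layer mapping per-position values to colours
#'
#' @param name layer name (used as SVG class prefix and legend title).
#' @param values per-position values (numeric or character; `NA` = absent).
#' @param colormap for numeric values, a list with `edges` (ascending bin
#'   edges) and `colours` (one per bin, `NA` = no highlight); for
#'   categorical values, a named character vector value -> colour.
#' @return An object of class `rna_data_layer` with resolved per-position
#'   colours (`NA` = no highlight) and a `legend` data frame.
#' @export
data_layer <- function(name, values, colormap) {
  if (is.numeric(values)) {
    edges <- colormap$edges; cols <- colormap$colours
    if (length(cols) != length(edges)) {
      stop("need one colour per bin (edges define left-closed bins; the ",
           "last edge opens the final bin)")
    }
    bin <- findInterval(values, edges, rightmost.closed = FALSE)
    bin[is.na(values)] <- NA
    if (any(!is.na(bin) & bin == 0L)) stop("value below the first bin edge")
    colour <- ifelse(is.na(bin), NA_character_, cols[bin])
    legend <- data.frame(
      from = edges,
      to = c(edges[-1], Inf),
      colour = cols)
  } else {
    values <- as.character(values)
    colour <- unname(colormap[values])
    unknown <- !is.na(values) & !(values %in% names(colormap))
    if (any(unknown)) {
      stop("no colour mapped for value '", values[unknown][1], "'")
    }
    legend <- data.frame(from = names(colormap), to = names(colormap),
                         colour = unname(colormap))
  }
  structure(list(name = name, values = values, colour = colour,
                 legend = legend), class = "rna_data_layer")
}

#' Posterior-probability data layer
#'
#' Encodes alignment confidence: values in `[0.95, 1]` are not highlighted
#' (high-probability positions stay plain); the rest are binned into four
#' intervals with edges `0, 0.8, 0.85, 0.9, 0.95` and coloured with a
#' colour-blind safe palette, lowest confidence darkest orange.
#'
#' @param values per-position probabilities in `[0, 1]` (`NA` = absent).
#' @return An `rna_data_layer`.
#' @export
#' @examples
#' posterior_layer(c(0.97, 0.5, NA))$colour
posterior_layer <- function(values) {
  if (any(!is.na(values) & (values < 0 | values > 1))) {
    stop("posterior probabilities must lie in [0, 1]")
  }
  data_layer("posterior", values,
             list(edges = c(.posterior_edges),
                  colours = c(.posterior_palette, NA_character_)))
}

#' Render a full diagram as SVG text
#'
#' One glyph per nucleotide at its coordinates, a backbone polyline,
#' page-0 pairs as solid connectors (dashed when `predicted`), pages >= 1
#' as a distinct `pseudoknot` connector class, numbering labels every
#' `label_interval` positions plus any transferred labels, and data layers
#' as filled circles behind the nucleotides.
#'
#' @param seq RNA sequence.
#' @param structure an [rna_structure()].
#' @param layout an [rna_layout()].
#' @param layers list of `rna_data_layer` objects.
#' @param labels optional per-position label text (`NA` = none).
#' @param label_interval interval for automatic position numbers
#'   (`0` disables them).
#' @param font_size nucleotide glyph size in drawing units.
#' @return SVG text (single string).
#' @export
render_svg <- function(seq, structure, layout, layers = list(),
                       labels = NULL, label_interval = 10L,
                       font_size = 6) {
  n <- nchar(seq)
  if (structure$length != n || nrow(layout$coords) != n) {
    stop("sequence/structure/layout length mismatch")
  }
  xy <- layout$coords
  chars <- strsplit(seq, "")[[1]]
  out <- c(.svg_header(xy))
  # data layers behind everything else
  for (ly in layers) {
    for (p in seq_len(n)) {
      col <- ly$colour[p]
      if (is.na(col)) next
      out <- c(out, sprintf(
        '<circle class="layer-%s" id="layer-%s-%d" cx="%s" cy="%s" r="%s" fill="%s"/>',
        ly$name, ly$name, p, .fmt(xy[p, 1]), .fmt(xy[p, 2]),
        .fmt(0.45 * BASE_SPACING), col))
    }
  }
  # backbone
  pts <- paste(paste(.fmt(xy[, 1]), .fmt(xy[, 2]), sep = ","), collapse = " ")
  out <- c(out, sprintf(
    '<polyline class="backbone" points="%s" fill="none" stroke="#B0B0B0" stroke-width="1"/>',
    pts))
  # pair connectors
  p <- structure$pairs
  for (k in seq_len(nrow(p))) {
    i <- p$i[k]; j <- p$j[k]
    cls <- if (p$page[k] > 0L) "pair pseudoknot"
           else if (p$predicted[k]) "pair predicted"
           else "pair canonical"
    dash <- if (p$predicted[k] && p$page[k] == 0L) ' stroke-dasharray="3,2"' else ""
    stroke <- if (p$page[k] > 0L) "#C04000" else "#404040"
    out <- c(out, sprintf(
      '<line class="%s" id="pair-%d-%d" x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="1"%s/>',
      cls, i, j, .fmt(xy[i, 1]), .fmt(xy[i, 2]),
      .fmt(xy[j, 1]), .fmt(xy[j, 2]), stroke, dash))
  }
  # nucleotide glyphs
  for (q in seq_len(n)) {
    out <- c(out, sprintf(
      '<text class="nt" id="nt-%d" x="%s" y="%s" text-anchor="middle" dominant-baseline="central" font-size="%s">%s</text>',
      q, .fmt(xy[q, 1]), .fmt(xy[q, 2]), format(font_size), chars[q]))
  }
  # labels: periodic numbering plus transferred labels
  lab <- if (is.null(labels)) rep(NA_character_, n) else labels
  if (label_interval > 0L) {
    auto <- seq_len(n) %% label_interval == 0L
    lab[auto & is.na(lab)] <- as.character(which(auto)[is.na(lab[auto])])
  }
  for (q in which(!is.na(lab))) {
    off <- .label_offset(xy, q)
    out <- c(out, sprintf(
      '<text class="label" id="label-%d" x="%s" y="%s" text-anchor="middle" font-size="4" fill="#808080">%s</text>',
      q, .fmt(xy[q, 1] + off[1]), .fmt(xy[q, 2] + off[2]), lab[q]))
  }
  paste(c(out, "</svg>"), collapse = "\n")
}

# place labels outward: away from the mean of the backbone neighbours
.label_offset <- function(xy, q) {
  n <- nrow(xy)
  nb <- c(if (q > 1L) q - 1L, if (q < n) q + 1L)
  u <- .unit(xy[q, ] - colMeans(xy[nb, , drop = FALSE]))
  if (all(u == 0)) u <- c(0, -1)
  u * BASE_SPACING
}

#' Render a simplified thumbnail
#'
#' A single continuous polyline through all nucleotide positions in
#' sequence order; no letters, base pairs or labels.
#'
#' @param layout an [rna_layout()].
#' @return SVG text.
#' @export
render_thumbnail <- function(layout) {
  xy <- layout$coords
  if (nrow(xy) == 0L) stop("empty layout")
  pts <- paste(paste(.fmt(xy[, 1]), .fmt(xy[, 2]), sep = ","), collapse = " ")
  paste(c(.svg_header(xy),
          sprintf('<polyline class="thumbnail" points="%s" fill="none" stroke="#404040" stroke-width="2"/>',
                  pts),
          "</svg>"), collapse = "\n")
}

#' Render Leontis-Westhof annotated base pairs as an SVG fragment
#'
#' Canonical cWW pairs are plain lines; every other geometry gets a
#' connector with an edge glyph at each end: circle = Watson-Crick,
#' square = Hoogsteen, triangle = Sugar; cis glyphs are filled, trans open.
#'
#' @param pairs data frame with columns `i`, `j` and `lw` (LW codes).
#' @param layout an [rna_layout()].
#' @return Character vector of SVG elements (no enclosing `<svg>`).
#' @export
render_lw <- function(pairs, layout) {
  xy <- layout$coords
  out <- character()
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$i[k]; j <- pairs$j[k]
    ann <- parse_lw(pairs$lw[k])
    if (ann$code == "cWW") {
      out <- c(out, sprintf(
        '<line class="lw cWW" id="lw-%d-%d" x1="%s" y1="%s" x2="%s" y2="%s" stroke="#404040" stroke-width="1"/>',
        i, j, .fmt(xy[i, 1]), .fmt(xy[i, 2]), .fmt(xy[j, 1]), .fmt(xy[j, 2])))
      next
    }
    out <- c(out, sprintf(
      '<line class="lw %s" id="lw-%d-%d" x1="%s" y1="%s" x2="%s" y2="%s" stroke="#404040" stroke-width="1"/>',
      ann$code, i, j, .fmt(xy[i, 1]), .fmt(xy[i, 2]),
      .fmt(xy[j, 1]), .fmt(xy[j, 2])))
    filled <- ann$orientation == "cis"
    out <- c(out,
             .lw_glyph(xy[i, ], xy[j, ], ann$edge5, filled, i, j, "5"),
             .lw_glyph(xy[j, ], xy[i, ], ann$edge3, filled, i, j, "3"))
  }
  out
}

.lw_glyph <- function(at, towards, edge, filled, i, j, end) {
  u <- .unit(as.numeric(towards) - as.numeric(at))
  c0 <- as.numeric(at) + u * (0.35 * BASE_SPACING)
  fill <- if (filled) "#404040" else "none"
  s <- 1.6  # glyph half-size
  id <- sprintf('id="lwg-%d-%d-%s"', i, j, end)
  if (edge == "WatsonCrick") {
    sprintf('<circle class="lw-glyph watson-crick" %s cx="%s" cy="%s" r="%s" fill="%s" stroke="#404040" stroke-width="0.6"/>',
            id, .fmt(c0[1]), .fmt(c0[2]), .fmt(s), fill)
  } else if (edge == "Hoogsteen") {
    sprintf('<rect class="lw-glyph hoogsteen" %s x="%s" y="%s" width="%s" height="%s" fill="%s" stroke="#404040" stroke-width="0.6"/>',
            id, .fmt(c0[1] - s), .fmt(c0[2] - s), .fmt(2 * s), .fmt(2 * s), fill)
  } else if (edge == "Sugar") {
    p <- sprintf("%s,%s %s,%s %s,%s",
                 .fmt(c0[1]), .fmt(c0[2] - s),
                 .fmt(c0[1] - s), .fmt(c0[2] + s),
                 .fmt(c0[1] + s), .fmt(c0[2] + s))
    sprintf('<polygon class="lw-glyph sugar" %s points="%s" fill="%s" stroke="#404040" stroke-width="0.6"/>',
            id, p, fill)
  } else {
    stop("unknown edge '", edge, "'")
  }
}

#' Animated morph between two layouts of the same molecule
#'
#' Emits an SVG in which every nucleotide linearly interpolates from its
#' position in `layoutA` (t = 0) to `layoutB` (t = `duration`), looping
#' indefinitely, using declarative SVG animation (no scripting).  With
#' `animate = FALSE` the static first frame is returned.
#'
#' @param layoutA,layoutB [rna_layout()] objects of equal length.
#' @param duration seconds for one morph (> 0).
#' @param animate emit animation elements?
#' @return SVG text.
#' @export
animate_layouts <- function(layoutA, layoutB, duration = 3, animate = TRUE) {
  A <- layoutA$coords; B <- layoutB$coords
  if (nrow(A) != nrow(B)) stop("structures must be the same size")
  if (!is.numeric(duration) || duration <= 0) stop("duration must be > 0")
  both <- rbind(A, B)
  out <- c(.svg_header(both))
  for (q in seq_len(nrow(A))) {
    el <- sprintf('<circle class="nt" id="nt-%d" cx="%s" cy="%s" r="2" fill="#404040">',
                  q, .fmt(A[q, 1]), .fmt(A[q, 2]))
    if (animate) {
      el <- paste0(el, sprintf(
        '<animate attributeName="cx" values="%s;%s" keyTimes="0;1" dur="%ss" repeatCount="indefinite"/>',
        .fmt(A[q, 1]), .fmt(B[q, 1]), format(duration)), sprintf(
        '<animate attributeName="cy" values="%s;%s" keyTimes="0;1" dur="%ss" repeatCount="indefinite"/>',
        .fmt(A[q, 2]), .fmt(B[q, 2]), format(duration)))
    }
    out <- c(out, paste0(el, "</circle>"))
  }
  paste(c(out, "</svg>"), collapse = "\n")
}
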