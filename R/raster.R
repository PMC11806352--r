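# Regression harness: a small painter that rasterizes the SVG primitives
# this package emits (lines, polylines, circles, rects, polygons, text as
# filled boxes) onto a fixed square canvas, and a global SSIM comparison.
# Full SVG-standard fidelity is a non-goal; the painter only needs to be
# deterministic and sensitive to layout changes.

.hex2rgb <- function(col) {
  if (is.na(col) || col == "none") return(NULL)
  v <- grDevices::col2rgb(col)
  as.numeric(v[, 1])
}

#' Rasterize SVG text onto a fixed canvas
#'
#' Parses the SVG elements produced by this package's renderers and paints
#' them onto a white `size x size` RGB canvas (values 0..255), mapping the
#' viewBox to the canvas with preserved aspect ratio.
#'
#' @param svg SVG text.
#' @param size canvas edge in pixels (default 512).
#' @param viewbox optional numeric `c(x, y, w, h)` overriding the SVG's own
#'   viewBox, so two diagrams can be painted in a common reference frame.
#' @return A `size x size x 3` numeric array.
#' @export
rasterize_svg <- function(svg, size = 512L, viewbox = NULL) {
  doc <- xml2::read_xml(svg)
  vb <- if (!is.null(viewbox)) as.numeric(viewbox) else
    as.numeric(strsplit(xml2::xml_attr(doc, "viewBox"), " ")[[1]])
  img <- array(255, c(size, size, 3))
  scale <- (size - 1) / max(vb[3], vb[4], 1e-9)
  tx <- function(x) (x - vb[1]) * scale + 1
  ty <- function(y) (y - vb[2]) * scale + 1

  span <- function(lo, hi) {
    lo <- max(1L, as.integer(round(lo))); hi <- min(size, as.integer(round(hi)))
    if (lo > hi) integer(0) else lo:hi
  }
  put_disc <- function(img, cx, cy, r, col) {
    xs <- span(floor(cx - r), ceiling(cx + r))
    ys <- span(floor(cy - r), ceiling(cy + r))
    if (length(xs) == 0L || length(ys) == 0L) return(img)
    for (yy in ys) {
      hit <- xs[(xs - cx)^2 + (yy - cy)^2 <= r^2]
      if (length(hit) > 0L) for (c in 1:3) img[yy, hit, c] <- col[c]
    }
    img
  }
  put_line <- function(img, x1, y1, x2, y2, col, w = 1) {
    len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
    steps <- max(2L, ceiling(len * 2))
    t <- seq(0, 1, length.out = steps)
    xs <- round(x1 + t * (x2 - x1)); ys <- round(y1 + t * (y2 - y1))
    keep <- xs >= 1 & xs <= size & ys >= 1 & ys <= size
    for (k in which(keep)) for (c in 1:3) img[ys[k], xs[k], c] <- col[c]
    img
  }
  put_box <- function(img, x1, y1, x2, y2, col) {
    xs <- span(x1, x2)
    ys <- span(y1, y2)
    if (length(xs) == 0L || length(ys) == 0L) return(img)
    for (c in 1:3) img[ys, xs, c] <- col[c]
    img
  }

  for (el in xml2::xml_children(doc)) {
    nm <- xml2::xml_name(el)
    a <- function(x) xml2::xml_attr(el, x)
    num <- function(x) suppressWarnings(as.numeric(a(x)))
    stroke <- .hex2rgb(a("stroke"))
    fill <- .hex2rgb(a("fill"))
    if (nm == "line") {
      img <- put_line(img, tx(num("x1")), ty(num("y1")),
                      tx(num("x2")), ty(num("y2")),
                      if (is.null(stroke)) c(0, 0, 0) else stroke)
    } else if (nm == "polyline" || nm == "polygon") {
      pts <- do.call(rbind, lapply(strsplit(a("points"), " ")[[1]],
                                   function(p) as.numeric(strsplit(p, ",")[[1]])))
      col <- if (!is.null(stroke)) stroke else c(0, 0, 0)
      for (k in seq_len(nrow(pts) - 1L)) {
        img <- put_line(img, tx(pts[k, 1]), ty(pts[k, 2]),
                        tx(pts[k + 1, 1]), ty(pts[k + 1, 2]), col)
      }
      if (nm == "polygon" && nrow(pts) > 2L) {
        img <- put_line(img, tx(pts[nrow(pts), 1]), ty(pts[nrow(pts), 2]),
                        tx(pts[1, 1]), ty(pts[1, 2]), col)
      }
    } else if (nm == "circle") {
      col <- if (!is.null(fill)) fill else stroke
      if (!is.null(col)) {
        img <- put_disc(img, tx(num("cx")), ty(num("cy")),
                        max(num("r") * scale, 1), col)
      }
    } else if (nm == "rect") {
      col <- if (!is.null(fill)) fill else stroke
      if (!is.null(col)) {
        img <- put_box(img, tx(num("x")), ty(num("y")),
                       tx(num("x") + num("width")), ty(num("y") + num("height")),
                       col)
      }
    } else if (nm == "text") {
      fs <- num("font-size"); if (is.na(fs)) fs <- 6
      half <- max(fs * scale / 2, 1)
      cx <- tx(num("x")); cy <- ty(num("y"))
      img <- put_box(img, cx - half, cy - half, cx + half, cy + half,
                     c(64, 64, 64))
    }
  }
  img
}

#' Global structural similarity between two rasters
#'
#' Converts both images to greyscale (`0.299 R + 0.587 G + 0.114 B`),
#' computes the global (single-window) SSIM with the standard constants
#' `C1 = (0.01 * 255)^2`, `C2 = (0.03 * 255)^2`, and reports the mean
#' absolute per-channel difference on the 0..1 scale.
#'
#' @param rasterA,rasterB arrays `h x w x 3` with values 0..255.
#' @return A list with `ssim` and `channel_diff` (length-3, R/G/B).
#' @export
image_similarity <- function(rasterA, rasterB) {
  if (!all(dim(rasterA) == dim(rasterB))) stop("raster dimension mismatch")
  greyA <- 0.299 * rasterA[, , 1] + 0.587 * rasterA[, , 2] + 0.114 * rasterA[, , 3]
  greyB <- 0.299 * rasterB[, , 1] + 0.587 * rasterB[, , 2] + 0.114 * rasterB[, , 3]
  C1 <- (0.01 * 255)^2
  C2 <- (0.03 * 255)^2
  muA <- mean(greyA); muB <- mean(greyB)
  vA <- mean((greyA - muA)^2); vB <- mean((greyB - muB)^2)
  cov <- mean((greyA - muA) * (greyB - muB))
  ssim <- ((2 * muA * muB + C1) * (2 * cov + C2)) /
          ((muA^2 + muB^2 + C1) * (vA + vB + C2))
  channel_diff <- vapply(1:3, function(c) {
    mean(abs(rasterA[, , c] - rasterB[, , c])) / 255
  }, 0)
  list(ssim = ssim, channel_diff = channel_diff)
}

#' Compare two diagrams for the regression suite
#'
#' Rasterizes both SVG texts, computes [image_similarity()] and applies
#' the acceptance thresholds: minor differences (a font-size tweak, a
#' sub-pixel shift) pass; a significantly different diagram fails.
#'
#' @param svgA,svgB SVG texts.
#' @param ssim_threshold minimum SSIM to pass (default 0.99).
#' @param diff_threshold maximum mean per-channel difference on the 0..1
#'   scale (default `2/255`).
#' @param size rasterization canvas edge.
#' @return A list with `pass`, `ssim`, `channel_diff`.
#' @export
compare_images <- function(svgA, svgB, ssim_threshold = 0.99,
                           diff_threshold = 2 / 255, size = 512L) {
  # paint both in A's reference frame so translations are visible
  vb <- as.numeric(strsplit(xml2::xml_attr(xml2::read_xml(svgA), "viewBox"),
                            " ")[[1]])
  sim <- image_similarity(rasterize_svg(svgA, size, viewbox = vb),
                          rasterize_svg(svgB, size, viewbox = vb))
  pass <- sim$ssim >= ssim_threshold && max(sim$channel_diff) <= diff_threshold
  c(list(pass = pass), sim)
}
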