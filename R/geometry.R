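# 2D geometry helpers for the layout engines.  All coordinates are in
# abstract drawing units with y growing downward (screen convention).

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) return(c(0, 0))
  v / n
}

.rot90 <- function(v) c(v[2], -v[1])  # rotate -90 deg (toward -y for +x input)

# Circle used to lay out a loop: circumference = n_slots * BASE_SPACING,
# passing through the closing-pair anchors P5 and P3, centre on the
# perpendicular bisector on the side pointed to by `side`.  When the
# circumference rule would give a radius smaller than half the chord the
# radius is clamped (the circle then degenerates towards the chord).
.loop_circle <- function(P5, P3, n_slots, side) {
  mid <- (P5 + P3) / 2
  half <- sqrt(sum((P3 - P5)^2)) / 2
  r <- max(n_slots * BASE_SPACING / (2 * pi), half)
  d <- sqrt(max(r^2 - half^2, 0))
  # the centre must sit on the perpendicular bisector of the chord; `side`
  # only picks which of the two half-planes it falls into
  n0 <- .rot90(.unit(P3 - P5))
  s <- sum(n0 * side)
  if (is.na(s) || s < 0) n0 <- -n0
  list(centre = mid + d * n0, r = r)
}

# m points uniformly spaced on the arc of `circle` from P5 to P3, taking the
# long way around (the side away from the closing helix).  Ties between the
# two directions resolve counter-clockwise.
.arc_slots <- function(circle, P5, P3, m) {
  if (m == 0L) return(matrix(numeric(0), 0, 2))
  a5 <- atan2(P5[2] - circle$centre[2], P5[1] - circle$centre[1])
  a3 <- atan2(P3[2] - circle$centre[2], P3[1] - circle$centre[1])
  ccw <- (a3 - a5) %% (2 * pi)
  sweep <- if (ccw >= pi) ccw else ccw - 2 * pi  # pick the long way
  t <- seq_len(m) / (m + 1)
  ang <- a5 + sweep * t
  cbind(circle$centre[1] + circle$r * cos(ang),
        circle$centre[2] + circle$r * sin(ang))
}

# Subtended angle theta (0, 2*pi) of a circular arc of length L over a
# chord d < L: solves 2 * (L / theta) * sin(theta / 2) = d.
.arc_theta <- function(L, d) {
  f <- function(th) 2 * (L / th) * sin(th / 2) - d
  stats::uniroot(f, c(1e-9, 2 * pi - 1e-9), tol = 1e-12)$root
}

#' Place unpaired nucleotides on an arc between two flanks
#'
#' Puts `m` points on a circular arc from `flank5` to `flank3` with arc
#' length `(m + 1) * BASE_SPACING`, bulging perpendicular to the flank
#' segment (away from `away_from` when given, otherwise to the -y side of
#' the 5'->3' direction).  Endpoints are spaced uniformly along the arc.
#' Coincident flanks fall back to a semicircle of radius
#' `BASE_SPACING * (m + 1) / pi` (logged via `message()`).
#'
#' @param flank5,flank3 numeric length-2 coordinates of the flanking,
#'   already-placed nucleotides.
#' @param m number of points to place (>= 1).
#' @param away_from optional point the bulge should avoid (e.g. the
#'   enclosing loop centroid).
#' @return An `m x 2` coordinate matrix.
#' @export
place_unfolded_insertion <- function(flank5, flank3, m, away_from = NULL) {
  m <- as.integer(m)
  if (m < 1L) stop("m must be >= 1")
  flank5 <- as.numeric(flank5); flank3 <- as.numeric(flank3)
  d <- sqrt(sum((flank3 - flank5)^2))
  L <- (m + 1) * BASE_SPACING
  if (d < 1e-9) {
    message("coincident flanks: falling back to a semicircle")
    r <- L / pi
    centre <- flank5 + c(0, -r)
    ang <- pi / 2 + pi * seq_len(m) / (m + 1)
    return(cbind(centre[1] + r * cos(ang), centre[2] + r * sin(ang)))
  }
  mid <- (flank5 + flank3) / 2
  dir <- .unit(flank3 - flank5)
  bulge <- .rot90(dir)
  if (!is.null(away_from)) {
    aw <- .unit(as.numeric(away_from) - mid)
    if (sum(bulge * aw) > 0) bulge <- -bulge
  }
  if (L <= d + 1e-9) {
    # arc cannot be longer than the chord: straight-line spacing
    t <- seq_len(m) / (m + 1)
    return(cbind(flank5[1] + t * (flank3[1] - flank5[1]),
                 flank5[2] + t * (flank3[2] - flank5[2])))
  }
  theta <- .arc_theta(L, d)
  r <- L / theta
  e <- r * cos(theta / 2)              # signed centre offset from the chord
  centre <- mid - e * bulge
  a5 <- atan2(flank5[2] - centre[2], flank5[1] - centre[1])
  a3 <- atan2(flank3[2] - centre[2], flank3[1] - centre[1])
  ccw <- (a3 - a5) %% (2 * pi)
  # choose the rotation whose arc midpoint lies on the bulge side
  mid_ccw <- a5 + ccw / 2
  probe <- c(cos(mid_ccw), sin(mid_ccw))
  sweep <- if (sum(probe * bulge) >= 0) ccw else ccw - 2 * pi
  ang <- a5 + sweep * seq_len(m) / (m + 1)
  cbind(centre[1] + r * cos(ang), centre[2] + r * sin(ang))
}
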