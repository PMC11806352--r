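# Independent brute-force oracles and small generators used across the
# suite.  Each oracle is a deliberately naive implementation kept separate
# from the package's algorithms.

pairs_cross <- function(i1, j1, i2, j2) {
  (i1 < i2 & i2 < j1 & j1 < j2) | (i2 < i1 & i1 < j2 & j2 < j1)
}

# --- minimal page count by exhaustive colouring of the crossing graph ----
oracle_min_pages <- function(pairs) {
  np <- nrow(pairs)
  if (np == 0L) return(0L)
  cross <- outer(seq_len(np), seq_len(np), function(a, b) {
    pairs_cross(pairs$i[a], pairs$j[a], pairs$i[b], pairs$j[b])
  })
  for (k in 1:np) {
    grid <- as.matrix(expand.grid(rep(list(seq_len(k)), np)))
    for (r in seq_len(nrow(grid))) {
      ok <- TRUE
      for (a in seq_len(np - 1L)) {
        for (b in (a + 1L):np) {
          if (cross[a, b] && grid[r, a] == grid[r, b]) { ok <- FALSE; break }
        }
        if (!ok) break
      }
      if (ok) return(k)
    }
  }
  np
}

# --- exhaustive alignment score for short sequences ----------------------
# Enumerates every monotone matching between query and template positions;
# unmatched runs are scored as affine gaps (open + (len-1) * ext), with
# template overhangs before the first / after the last matched position
# free.  Interleaving insertions and deletions can never merge gap runs,
# so this covers all alignments.
oracle_align_score <- function(q, t, match = 2, mismatch = -1,
                               open = -5, ext = -1) {
  qc <- strsplit(q, "")[[1]]; tc <- strsplit(t, "")[[1]]
  n <- length(qc); m <- length(tc)
  gap <- function(len) if (len <= 0L) 0 else open + (len - 1L) * ext
  best <- gap(n)  # empty matching: whole query inserted, template free
  for (k in seq_len(min(n, m))) {
    qs_all <- utils::combn(n, k)
    ts_all <- utils::combn(m, k)
    for (a in seq_len(ncol(qs_all))) {
      qs <- qs_all[, a]
      qgap <- gap(qs[1] - 1L) + gap(n - qs[k])
      if (k > 1L) for (z in 2:k) qgap <- qgap + gap(qs[z] - qs[z - 1L] - 1L)
      for (b in seq_len(ncol(ts_all))) {
        ts <- ts_all[, b]
        sc <- qgap
        for (z in seq_len(k)) {
          sc <- sc + if (qc[qs[z]] == tc[ts[z]] && qc[qs[z]] != "N") match
                     else mismatch
          if (z > 1L) sc <- sc + gap(ts[z] - ts[z - 1L] - 1L)
        }
        if (sc > best) best <- sc
      }
    }
  }
  best
}

# --- exhaustive maximum pairing ------------------------------------------
# Recursion over all non-crossing pairings (no memoization) with the
# complement alphabet and the hairpin rule; honours fixed and forbidden
# constraints.  Returns -1 when the constraints are unsatisfiable.
oracle_max_pairs <- function(seq, fixed = NULL, forbidden = integer()) {
  s <- strsplit(seq, "")[[1]]
  n <- length(s)
  comp <- function(a, b) paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
  fixed_partner <- integer(n)
  if (!is.null(fixed) && nrow(fixed) > 0L) {
    fixed_partner[fixed$i] <- fixed$j
    fixed_partner[fixed$j] <- fixed$i
  }
  rec <- function(lo, hi) {
    if (lo >= hi) return(0L)
    out <- if (fixed_partner[lo] == 0L) rec(lo + 1L, hi) else -1L
    ks <- if (fixed_partner[lo] > lo) {
      fixed_partner[lo]
    } else if (fixed_partner[lo] == 0L && hi >= lo + 4L) {
      (lo + 4L):hi
    } else integer(0)
    for (k in ks) {
      if (k > hi) next
      allowed <- if (fixed_partner[lo] == k) TRUE else {
        fixed_partner[k] == 0L &&
          !(lo %in% forbidden) && !(k %in% forbidden) &&
          comp(s[lo], s[k]) &&
          !any(fixed_partner > 0L &
               pairs_cross(lo, k, seq_len(n), fixed_partner))
      }
      if (!allowed) next
      left <- rec(lo + 1L, k - 1L)
      right <- rec(k + 1L, hi)
      if (left >= 0L && right >= 0L) out <- max(out, 1L + left + right)
    }
    out
  }
  rec(1L, n)
}

# --- independent segment-pair overlap count ------------------------------
# Parametric (linear solve) intersection test, unlike the package's
# orientation-sign method.
oracle_overlaps <- function(layout, structure) {
  xy <- layout$coords
  n <- nrow(xy)
  segs <- if (n >= 2L) cbind(seq_len(n - 1L), 2:n) else NULL
  p0 <- structure$pairs[structure$pairs$page == 0L, , drop = FALSE]
  if (nrow(p0) > 0L) segs <- rbind(segs, cbind(p0$i, p0$j))
  hit <- function(a1, a2, b1, b2) {
    d1 <- a2 - a1; d2 <- b2 - b1
    A <- cbind(d1, -d2)
    if (abs(det(A)) < 1e-9) {
      if (abs(d1[1] * (b1[2] - a1[2]) - d1[2] * (b1[1] - a1[1])) > 1e-9) {
        return(FALSE)
      }
      L <- sum(d1^2)
      if (L < 1e-18) return(sum((a1 - b1)^2) < 1e-18)
      t1 <- sum((b1 - a1) * d1) / L
      t2 <- sum((b2 - a1) * d1) / L
      return(max(min(t1, t2), 0) <= min(max(t1, t2), 1) + 1e-9)
    }
    tt <- solve(A, b1 - a1)
    all(tt >= -1e-9) && all(tt <= 1 + 1e-9)
  }
  count <- 0L
  ns <- if (is.null(segs)) 0L else nrow(segs)
  if (ns >= 2L) {
    for (a in seq_len(ns - 1L)) for (b in (a + 1L):ns) {
      if (length(intersect(segs[a, ], segs[b, ])) > 0L) next
      if (hit(xy[segs[a, 1], ], xy[segs[a, 2], ],
              xy[segs[b, 1], ], xy[segs[b, 2], ])) count <- count + 1L
    }
  }
  partner <- structure$partner
  if (n >= 3L) for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
    if (b == a + 1L) next
    if (!is.na(partner[a]) && partner[a] == b) next
    if (sum((xy[b, ] - xy[a, ])^2) < (0.5 * 8)^2) count <- count + 1L
  }
  count
}

# --- generators ----------------------------------------------------------
rand_seq <- function(n) paste(sample(c("A", "C", "G", "U"), n, TRUE),
                              collapse = "")

# random dot-bracket string over `families` bracket sets, repaired to be
# balanced per family (unmatched brackets become dots)
rand_dotbracket <- function(n, families = 1L) {
  opens <- c("(", "[", "{", "<")[seq_len(families)]
  closes <- c(")", "]", "}", ">")[seq_len(families)]
  pool <- c(".", ".", opens, closes)
  out <- sample(pool, n, replace = TRUE)
  for (f in seq_len(families)) {
    stack <- integer(0)
    for (p in seq_len(n)) {
      if (out[p] == opens[f]) stack <- c(stack, p)
      else if (out[p] == closes[f]) {
        if (length(stack) == 0L) out[p] <- "." else stack <- stack[-length(stack)]
      }
    }
    out[stack] <- "."
  }
  paste(out, collapse = "")
}

# random valid interchange document
rand_document <- function(seed) {
  set.seed(seed)
  n <- sample(4:15, 1L)
  residues <- data.frame(
    char = sample(c("A", "C", "G", "U"), n, TRUE),
    index = seq_len(n),
    x = round(runif(n, -50, 50), 3),
    y = round(runif(n, -50, 50), 3),
    styleClass = ifelse(runif(n) < 0.3, "hl", NA_character_))
  npair <- sample(0:(n %/% 3), 1L)
  bp <- data.frame(i = integer(), j = integer(), lw = character(),
                   predicted = logical())
  if (npair > 0L) {
    idx <- sample(n, 2L * npair)
    bp <- data.frame(i = pmin(idx[1:npair], idx[(npair + 1):(2 * npair)]),
                     j = pmax(idx[1:npair], idx[(npair + 1):(2 * npair)]),
                     lw = sample(c("canonical", "cWW", "tHS", "cSH"),
                                 npair, TRUE),
                     predicted = runif(npair) < 0.5)
  }
  lab <- data.frame(index = which(runif(n) < 0.2))
  lab$text <- as.character(lab$index)
  classes <- data.frame(name = "hl", colour = "#FF0000", fontSize = 8,
                        visibility = "visible")
  rna2d_document(list(list(name = paste0("mol", seed), residues = residues,
                           labels = lab, basePairs = bp)),
                 classes = classes)
}

# shared toy library, built once per test run
toy_templates <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_toy_templates(seed = 1)
    cache
  }
})
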