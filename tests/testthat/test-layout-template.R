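# helper: exact alignment with a known single edit against a template
.single_del_aln <- function(n, at) {
  posmap <- setdiff(seq_len(n), at)
  structure(list(ops = data.frame(op = c("M", "D", "M"),
                                  len = c(at - 1L, 1L, n - at)),
                 score = NA_real_,
                 posmap = posmap,
                 revmap = match(seq_len(n), posmap)),
            class = "rna_alignment")
}

.single_ins_aln <- function(n, after, m = 1L) {
  posmap <- append(seq_len(n), rep(NA_integer_, m), after = after)
  structure(list(ops = data.frame(op = c("M", "I", "M"),
                                  len = c(after, m, n - after)),
                 score = NA_real_,
                 posmap = posmap,
                 revmap = match(seq_len(n), posmap)),
            class = "rna_alignment")
}

test_that("laying a template's own sequence on itself reproduces it exactly", {
  tps <- toy_templates()
  for (tp in tps) {
    aln <- identity_alignment(nchar(tp$sequence))
    qs <- transfer_structure(tp, aln)
    lay <- layout_from_template(tp$sequence, qs, tp, aln)
    expect_equal(max(abs(lay$coords - tp$coords)), 0)
    expect_true(all(lay$provenance == "inherited"))
  }
})

test_that("deleting a hairpin-loop nucleotide rearranges only that loop", {
  tps <- toy_templates()
  tp <- tps$tmpl_trna
  n <- nchar(tp$sequence)
  # D-loop of the cloverleaf spans template positions 14..21
  at <- 16L
  q <- paste0(substr(tp$sequence, 1, at - 1L), substr(tp$sequence, at + 1L, n))
  aln <- .single_del_aln(n, at)
  qs <- transfer_structure(tp, aln)
  lay <- layout_from_template(q, qs, tp, aln)
  loop_q <- 14:20                         # remaining D-loop on the query
  outside <- setdiff(seq_len(n - 1L), loop_q)
  expect_equal(max(abs(lay$coords[outside, ] -
                       tp$coords[aln$posmap[outside], ])), 0)
  # remaining members on the recomputed closed-form circle: radius from the
  # circumference rule, centre on the perpendicular bisector of the anchors
  P5 <- tp$coords[13, ]; P3 <- tp$coords[22, ]
  K <- length(loop_q)
  r <- max((K + 2) * 8 / (2 * pi), sqrt(sum((P3 - P5)^2)) / 2)
  e <- sqrt(r^2 - sum((P3 - P5)^2) / 4)
  mid <- (P5 + P3) / 2
  normal <- c(P3[2] - P5[2], -(P3[1] - P5[1]))
  normal <- normal / sqrt(sum(normal^2))
  on_circle <- function(centre) {
    max(abs(apply(lay$coords[loop_q, ], 1, function(v) {
      sqrt(sum((v - centre)^2))
    }) - r))
  }
  expect_lt(min(on_circle(mid + e * normal), on_circle(mid - e * normal)),
            1e-9)
  expect_equal(table(lay$provenance)[["rearranged"]], K)
})

test_that("inserting into a hairpin loop grows its circle, helix untouched", {
  tps <- toy_templates()
  tp <- tps$tmpl_trna
  n <- nchar(tp$sequence)
  # anticodon hairpin: closing pair (31, 39), members 32..38
  aln <- .single_ins_aln(n, after = 35L, m = 4L)
  q <- paste0(substr(tp$sequence, 1, 35), "ACGU", substr(tp$sequence, 36, n))
  qs <- transfer_structure(tp, aln)
  lay <- layout_from_template(q, qs, tp, aln)
  expect_equal(sum(lay$provenance == "inserted"), 4L)
  loop_q <- 32:42                          # 7 original + 4 inserted members
  outside <- setdiff(which(!is.na(aln$posmap)), loop_q)
  expect_equal(max(abs(lay$coords[outside, ] -
                       tp$coords[aln$posmap[outside], ])), 0)
  # circle radius follows the circumference rule for the grown loop
  P5 <- tp$coords[31, ]; P3 <- tp$coords[39, ]
  r_expect <- max((11 + 2) * 8 / (2 * pi), 4)
  centre <- local({
    mid <- (P5 + P3) / 2
    n0 <- c(P3[2] - P5[2], -(P3[1] - P5[1]))
    n0 <- n0 / sqrt(sum(n0^2))
    side <- colMeans(tp$coords[32:38, ]) - mid
    if (sum(n0 * side) < 0) n0 <- -n0
    mid + sqrt(r_expect^2 - sum((P3 - P5)^2) / 4) * n0
  })
  for (p in loop_q) {
    expect_equal(sqrt(sum((lay$coords[p, ] - centre)^2)), r_expect,
                 tolerance = 1e-9)
  }
})

test_that("single-edit locality holds across fixtures and edit positions", {
  tps <- toy_templates()
  set.seed(17)
  for (rep in 1:30) {
    tp <- tps[[sample(c("tmpl_trna", "tmpl_5s", "tmpl_long"), 1L)]]
    n <- nchar(tp$sequence)
    del <- runif(1) < 0.5
    at <- sample(n - 2L, 1L) + 1L
    if (del) {
      aln <- .single_del_aln(n, at)
      q <- paste0(substr(tp$sequence, 1, at - 1L),
                  substr(tp$sequence, at + 1L, n))
    } else {
      aln <- .single_ins_aln(n, after = at)
      q <- paste0(substr(tp$sequence, 1, at), "A",
                  substr(tp$sequence, at + 1L, n))
    }
    qs <- transfer_structure(tp, aln)
    lay <- layout_from_template(q, qs, tp, aln)
    tree <- build_tree(qs)
    # elements containing the edit
    touched <- unique(c(tree$elem_of[is.na(aln$posmap)],
                        tree$edge_of[which(diff(aln$posmap) > 1L)],
                        if (!del) tree$edge_of[c(at, at + 1L)]))
    touched <- touched[!is.na(touched)]
    free <- which(!seq_len(qs$length) %in%
                  unlist(lapply(tree$elements[touched], `[[`, "positions")))
    free <- free[!is.na(aln$posmap[free])]
    dev <- abs(lay$coords[free, , drop = FALSE] -
               tp$coords[aln$posmap[free], , drop = FALSE])
    expect_equal(max(dev), 0, info = paste(tp$id, at, del))
    expect_true(all(is.finite(lay$coords)))
  }
})

test_that("deleting pairs from a helix re-ladders it along the template axis", {
  tps <- toy_templates()
  tp <- tps$tmpl_5s
  n <- nchar(tp$sequence)
  # remove both strands of one stacked pair in the first inner helix
  # (template helix 20..31 paired with 42..53); drop 25 and its partner
  p25 <- tp$structure$partner[25]
  dels <- sort(c(25L, p25))
  posmap <- setdiff(seq_len(n), dels)
  aln <- structure(list(ops = data.frame(op = "M", len = length(posmap)),
                        score = NA_real_, posmap = posmap,
                        revmap = match(seq_len(n), posmap)),
                   class = "rna_alignment")
  q <- paste(strsplit(tp$sequence, "")[[1]][posmap], collapse = "")
  qs <- transfer_structure(tp, aln)
  lay <- layout_from_template(q, qs, tp, aln)
  # shortened helix: consecutive pairs still 8 apart along one line
  tr <- build_tree(qs)
  hx <- Filter(function(e) e$type == "helix" &&
                           24 %in% aln$posmap[e$positions], tr$elements)[[1]]
  mids <- t(vapply(seq_len(nrow(hx$pairs)), function(k) {
    (lay$coords[hx$pairs$i[k], ] + lay$coords[hx$pairs$j[k], ]) / 2
  }, c(0, 0)))
  rises <- sqrt(rowSums((mids[-1, , drop = FALSE] -
                         mids[-nrow(mids), , drop = FALSE])^2))
  expect_true(all(abs(rises - 8) < 1e-9))
})

test_that("arc placement of unpaired runs follows the closed-form geometry", {
  # single point: on the perpendicular bisector at the computed sagitta
  pt <- place_unfolded_insertion(c(0, 0), c(8, 0), 1)
  expect_equal(pt[1, 1], 4, tolerance = 1e-9)
  # independent sagitta computation by bisection on the chord equation
  L <- 2 * 8; d <- 8
  f <- function(th) 2 * (L / th) * sin(th / 2) - d
  lo <- 1e-6; hi <- 2 * pi - 1e-6
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  r <- L / lo
  sagitta <- r * (1 - cos(lo / 2))
  expect_equal(abs(pt[1, 2]), sagitta, tolerance = 1e-6)
  expect_lt(pt[1, 2], 0)  # default bulge towards -y

  # symmetry about the flank midline
  pts <- place_unfolded_insertion(c(0, 0), c(8, 0), 3)
  expect_equal(pts[1, 1], 8 - pts[3, 1], tolerance = 1e-9)
  expect_equal(pts[2, 1], 4, tolerance = 1e-9)
  expect_equal(pts[1, 2], pts[3, 2], tolerance = 1e-9)

  expect_error(place_unfolded_insertion(c(0, 0), c(8, 0), 0), "m must be >= 1")
  expect_message(sc <- place_unfolded_insertion(c(1, 1), c(1, 1), 2),
                 "semicircle")
  expect_equal(nrow(sc), 2L)
})

test_that("numbering labels transfer with suppression", {
  tps <- toy_templates()
  tp <- tps$tmpl_trna
  n <- nchar(tp$sequence)
  aln <- identity_alignment(n)
  lab <- transfer_labels(tp, aln, suppress = c("13", "26"))
  expect_true(is.na(lab[13]) && is.na(lab[26]))
  expect_equal(lab[-c(13, 26)], tp$labels[-c(13, 26)])

  # deletions drop their label, insertions carry none
  aln <- .single_del_aln(n, 20L)
  lab <- transfer_labels(tp, aln)
  expect_false("20" %in% lab)
  aln <- .single_ins_aln(n, after = 30L, m = 2L)
  lab <- transfer_labels(tp, aln)
  expect_true(all(is.na(lab[31:32])))

  # all-inserted alignment has no labels at all
  allins <- structure(list(ops = data.frame(op = c("I", "D"),
                                            len = c(4L, n)),
                           score = NA_real_,
                           posmap = rep(NA_integer_, 4),
                           revmap = rep(NA_integer_, n)),
                      class = "rna_alignment")
  expect_true(all(is.na(transfer_labels(tp, allins))))
  expect_error(transfer_labels(tps$tmpl_5s, identity_alignment(120)),
               "no numbering labels")
})
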