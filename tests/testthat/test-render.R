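count_matches <- function(pattern, text) {
  m <- gregexpr(pattern, text, fixed = TRUE)[[1]]
  if (m[1] == -1L) 0L else length(m)
}

test_that("full diagrams conserve element counts", {
  st <- parse_dotbracket("(((...)))")
  lay <- layout_radial("GGGAAACCC", st)
  svg <- render_svg("GGGAAACCC", st, lay)
  expect_equal(count_matches('class="nt"', svg), 9L)
  expect_equal(count_matches('pair canonical', svg), 3L)
  expect_equal(count_matches('pseudoknot', svg), 0L)
  expect_equal(count_matches('<polyline class="backbone"', svg), 1L)

  # one pseudoknot pair renders exactly one pseudoknot-class connector
  tps <- toy_templates()
  tp <- tps$tmpl_pk
  lay <- layout_radial(tp$sequence, tp$structure)
  svg <- render_svg(tp$sequence, tp$structure, lay)
  expect_equal(count_matches('pair pseudoknot', svg), 1L)
  expect_equal(count_matches('pair canonical', svg), 3L)

  # predicted pairs come out dashed
  st2 <- fold_max_pairs("GGGAAACCC")
  svg2 <- render_svg("GGGAAACCC", st2, lay <- layout_radial("GGGAAACCC", st2))
  expect_equal(count_matches('pair predicted', svg2), 3L)
  expect_equal(count_matches('stroke-dasharray', svg2), 3L)

  expect_error(render_svg("ACGU", st, lay), "length mismatch")
})

test_that("rendering is deterministic", {
  tps <- toy_templates()
  tp <- tps$tmpl_trna
  lay <- layout_radial(tp$sequence, tp$structure)
  a <- render_svg(tp$sequence, tp$structure, lay,
                  layers = list(posterior_layer(rep(0.5, 76))),
                  labels = transfer_labels(tp, identity_alignment(76)))
  b <- render_svg(tp$sequence, tp$structure, lay,
                  layers = list(posterior_layer(rep(0.5, 76))),
                  labels = transfer_labels(tp, identity_alignment(76)))
  expect_identical(a, b)
})

test_that("posterior palette: high-confidence positions are not highlighted", {
  ly <- posterior_layer(c(0.97, 0.95, 0.10, 0.80, 0.9499, NA))
  expect_true(is.na(ly$colour[1]))          # 95%-100% band
  expect_true(is.na(ly$colour[2]))          # inclusive lower edge
  expect_equal(ly$colour[3], "#D55E00")     # lowest bin
  expect_equal(ly$colour[4], "#E69F00")     # 0.80 opens the second bin
  expect_equal(ly$colour[5], "#0072B2")     # just below the no-highlight band
  expect_true(is.na(ly$colour[6]))          # absent value
  expect_error(posterior_layer(c(0.5, 1.2)), "\\[0, 1\\]")

  # exhaustive grid: every value maps to exactly one bin or no highlight
  grid <- seq(0, 1, by = 0.001)
  cols <- posterior_layer(grid)$colour
  expect_true(all(is.na(cols[grid >= 0.95])))
  expect_true(all(!is.na(cols[grid < 0.95])))
  expect_equal(length(unique(cols[!is.na(cols)])), 4L)
})

test_that("thumbnails are a single polyline through all positions", {
  tps <- toy_templates()
  lay <- layout_radial(tps$tmpl_5s$sequence, tps$tmpl_5s$structure)
  th <- render_thumbnail(lay)
  expect_equal(count_matches("<polyline", th), 1L)
  pts <- regmatches(th, regexpr('points="[^"]*"', th))
  expect_equal(length(strsplit(sub('points="', "", pts), " ")[[1]]), 120L)
  expect_equal(count_matches("<text", th), 0L)
  expect_error(render_thumbnail(rna_layout(matrix(0, 0, 2))), "empty layout")

  # identity re-layout gives a byte-identical thumbnail
  tp <- tps$tmpl_5s
  aln <- identity_alignment(120)
  relay <- layout_from_template(tp$sequence, transfer_structure(tp, aln),
                                tp, aln)
  expect_identical(render_thumbnail(rna_layout(tp$coords)),
                   render_thumbnail(relay))
})

test_that("Leontis-Westhof glyphs follow the edge and orientation code", {
  lay <- rna_layout(rbind(c(0, 0), c(30, 0), c(0, 30), c(30, 30)))
  frag <- render_lw(data.frame(i = 1, j = 2, lw = "tHS"), lay)
  expect_equal(sum(grepl("hoogsteen", frag)), 1L)   # open square
  expect_equal(sum(grepl("sugar", frag)), 1L)       # open triangle
  expect_equal(sum(grepl('fill="none"', frag)), 2L) # trans = open
  cis <- render_lw(data.frame(i = 1, j = 2, lw = "cHS"), lay)
  expect_equal(sum(grepl('fill="none"', cis)), 0L)  # cis = filled

  plain <- render_lw(data.frame(i = 1, j = 2, lw = "cWW"), lay)
  expect_equal(sum(grepl("lw-glyph", plain)), 0L)   # plain line only
  expect_equal(sum(grepl("<line", plain)), 1L)

  mixed <- render_lw(data.frame(i = c(1, 1, 3), j = c(2, 3, 4),
                                lw = c("cWW", "tSS", "cWH")), lay)
  expect_equal(sum(grepl("lw-glyph", mixed)), 4L)   # 2 per non-cWW pair
})

test_that("animated morphs hit both endpoints and reject size mismatches", {
  a <- rna_layout(cbind(0:8 * 8, 0))
  b <- rna_layout(cbind(0:8 * 8, 0:8 * 4))
  svg <- animate_layouts(a, b, duration = 2)
  expect_equal(count_matches("<circle", svg), 9L)
  expect_equal(count_matches('repeatCount="indefinite"', svg), 18L)
  # endpoint values appear verbatim in the animation attributes
  expect_true(grepl('values="0.00;0.00"', svg) ||
              grepl('values="64.00;64.00"', svg))
  expect_true(grepl(sprintf('values="%s;%s"', "0.00", "32.00"), svg))
  expect_equal(count_matches('dur="2s"', svg), 18L)

  # zero displacement: every animated value pair is start == end
  same <- animate_layouts(a, a)
  vals <- regmatches(same, gregexpr('values="[^"]*"', same))[[1]]
  halves <- strsplit(sub('values="', "", sub('"$', "", vals)), ";")
  expect_true(all(vapply(halves, function(h) h[1] == h[2], TRUE)))

  static <- animate_layouts(a, b, animate = FALSE)
  expect_equal(count_matches("<animate", static), 0L)

  expect_error(animate_layouts(a, rna_layout(cbind(0:9 * 8, 0))),
               "same size")
  expect_error(animate_layouts(a, b, duration = 0), "duration")
})

test_that("image similarity is exact on identical and constant images", {
  tps <- toy_templates()
  tp <- tps$tmpl_pk
  lay <- layout_radial(tp$sequence, tp$structure)
  r <- rasterize_svg(render_svg(tp$sequence, tp$structure, lay), size = 128L)
  sim <- image_similarity(r, r)
  expect_identical(sim$ssim, 1)
  expect_equal(sim$channel_diff, c(0, 0, 0))

  # constant images: closed-form SSIM
  a <- array(100, c(16, 16, 3)); b <- array(101, c(16, 16, 3))
  s <- image_similarity(a, b)
  C1 <- (0.01 * 255)^2
  expect_equal(s$ssim, (2 * 100 * 101 + C1) / (100^2 + 101^2 + C1),
               tolerance = 1e-12)
  expect_equal(s$ssim, 1, tolerance = 1e-3)
  expect_equal(s$channel_diff, rep(1 / 255, 3))

  # colour inverse: direct formula evaluation on the grey arrays
  inv <- 255 - r
  s2 <- image_similarity(r, inv)
  gA <- 0.299 * r[, , 1] + 0.587 * r[, , 2] + 0.114 * r[, , 3]
  gB <- 255 - gA
  C2 <- (0.03 * 255)^2
  muA <- mean(gA); muB <- mean(gB)
  vA <- mean((gA - muA)^2); vB <- mean((gB - muB)^2)
  cv <- mean((gA - muA) * (gB - muB))
  want <- ((2 * muA * muB + C1) * (2 * cv + C2)) /
          ((muA^2 + muB^2 + C1) * (vA + vB + C2))
  expect_equal(s2$ssim, want, tolerance = 1e-12)

  expect_error(image_similarity(a, array(0, c(8, 8, 3))),
               "dimension mismatch")
})

test_that("regression gate passes minor changes and fails layout shifts", {
  tps <- toy_templates()
  tp <- tps$tmpl_trna
  lay <- layout_radial(tp$sequence, tp$structure)
  svg <- render_svg(tp$sequence, tp$structure, lay)
  expect_true(compare_images(svg, svg)$pass)

  shifted <- render_svg(tp$sequence, tp$structure,
                        rna_layout(lay$coords + 20))
  expect_false(compare_images(svg, shifted)$pass)

  # a sub-pixel font tweak is below the acceptance threshold
  fontier <- render_svg(tp$sequence, tp$structure, lay, font_size = 6.02)
  expect_true(compare_images(svg, fontier)$pass)
})
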