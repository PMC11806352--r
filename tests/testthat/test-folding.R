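test_that("worked example: GGGAAACCC folds into exactly three pairs", {
  # derived oracle agrees that 3 is the maximum under the hairpin rule
  expect_equal(oracle_max_pairs("GGGAAACCC"), 3L)
  f <- fold_max_pairs("GGGAAACCC")
  expect_equal(f$pairs[c("i", "j")],
               data.frame(i = 1:3, j = 9:7), ignore_attr = TRUE)
  expect_true(all(f$pairs$predicted))
})

test_that("degenerate inputs: no complements, saturated mask, retained pairs", {
  expect_equal(nrow(fold_max_pairs("AAAA")$pairs), 0L)
  cons <- fold_constraint(forbidden = 1:9)
  expect_equal(nrow(fold_max_pairs("GGGAAACCC", cons)$pairs), 0L)
  cons <- fold_constraint(fixed_pairs = data.frame(i = 1, j = 9))
  f <- fold_max_pairs("GAAAAAAAC", cons)
  expect_true(any(f$pairs$i == 1 & f$pairs$j == 9 & !f$pairs$predicted))
})

test_that("infeasible fixed pairs are rejected before the DP", {
  expect_error(fold_max_pairs("GAAC", fold_constraint(
    fixed_pairs = data.frame(i = 1, j = 4))), "hairpin rule")
  expect_error(fold_max_pairs("GAAAAAAAG", fold_constraint(
    fixed_pairs = data.frame(i = 1, j = 9))), "pairing alphabet")
  expect_error(fold_constraint(fixed_pairs = data.frame(i = 1, j = 9),
                               forbidden = 9), "touches a forbidden")
  expect_error(fold_constraint(fixed_pairs = data.frame(i = c(1, 3),
                                                        j = c(8, 12))),
               "cross")
})

test_that("DP equals exhaustive enumeration on random short sequences", {
  set.seed(31)
  for (rep in 1:60) {
    s <- rand_seq(sample(6:14, 1L))
    expect_equal(nrow(fold_max_pairs(s)$pairs), oracle_max_pairs(s),
                 info = s)
  }
})

test_that("DP honours forbidden positions and fixed pairs like the oracle", {
  set.seed(37)
  for (rep in 1:25) {
    s <- rand_seq(12)
    forb <- sample(12, sample(0:4, 1L))
    got <- fold_max_pairs(s, fold_constraint(forbidden = forb))
    expect_equal(nrow(got$pairs), oracle_max_pairs(s, forbidden = forb))
    expect_false(any(c(got$pairs$i, got$pairs$j) %in% forb))
  }
})

test_that("enlarging the forbidden set never increases the pair count", {
  set.seed(43)
  for (rep in 1:15) {
    s <- rand_seq(14)
    forb <- integer()
    prev <- nrow(fold_max_pairs(s)$pairs)
    for (add in sample(14, 5)) {
      forb <- union(forb, add)
      cur <- nrow(fold_max_pairs(s, fold_constraint(forbidden = forb))$pairs)
      expect_lte(cur, prev)
      prev <- cur
    }
  }
})

test_that("local folding confines pairs to long inserted runs", {
  tps <- toy_templates()
  tp <- tps$tmpl_5s
  n <- nchar(tp$sequence)
  ins <- "GGGGAAAACCCC"
  q <- paste0(substr(tp$sequence, 1, 60), ins, substr(tp$sequence, 61, n))
  aln <- structure(list(ops = data.frame(op = c("M", "I", "M"),
                                         len = c(60L, nchar(ins), n - 60L)),
                        score = NA_real_,
                        posmap = c(1:60, rep(NA, nchar(ins)), 61:n),
                        revmap = c(1:60, 61:n + nchar(ins))),
                   class = "rna_alignment")
  qs <- transfer_structure(tp, aln)
  out <- fold_local(q, qs, aln)
  added <- out$pairs[out$pairs$predicted, ]
  expect_gt(nrow(added), 0L)
  run <- 61:(60 + nchar(ins))
  expect_true(all(added$i %in% run & added$j %in% run))
  expect_equal(nrow(added), oracle_max_pairs(ins))
  # template-derived pairs untouched
  expect_true(all(paste(qs$pairs$i, qs$pairs$j) %in%
                  paste(out$pairs$i, out$pairs$j)))

  # short insertions stay unfolded
  aln2 <- identity_alignment(n)
  expect_identical(fold_local(tp$sequence, qs <- transfer_structure(tp, aln2),
                              aln2), qs)
})

test_that("two insertions fold independently and their union is valid", {
  base <- "GGGGGAAAAACCCCC"                      # 15 nt scaffold
  insA <- "GGGAAAACCC"; insB <- "GCGCAAAAGCGC"
  q <- paste0(substr(base, 1, 5), insA, substr(base, 6, 10), insB,
              substr(base, 11, 15))
  posmap <- c(1:5, rep(NA, nchar(insA)), 6:10, rep(NA, nchar(insB)), 11:15)
  revmap <- match(seq_len(nchar(base)), posmap)
  aln <- structure(list(ops = data.frame(op = c("M","I","M","I","M"),
                                         len = c(5L, nchar(insA), 5L,
                                                 nchar(insB), 5L)),
                        score = NA_real_, posmap = posmap, revmap = revmap),
                   class = "rna_alignment")
  qs <- rna_structure(nchar(q))
  out <- fold_local(q, qs, aln)
  runA <- 6:(5 + nchar(insA))
  runB <- (11 + nchar(insA)):(10 + nchar(insA) + nchar(insB))
  added <- out$pairs[out$pairs$predicted, ]
  inA <- added$i %in% runA
  expect_true(all((added$i %in% runA & added$j %in% runA) |
                  (added$i %in% runB & added$j %in% runB)))
  expect_equal(sum(inA), oracle_max_pairs(insA))
  expect_equal(sum(!inA), oracle_max_pairs(insB))
})

test_that("global folding is a superset of the template structure", {
  tps <- toy_templates()
  tp <- tps$tmpl_5s
  aln <- identity_alignment(nchar(tp$sequence))
  qs <- transfer_structure(tp, aln)
  out <- fold_global(tp$sequence, qs)
  expect_true(all(paste(qs$pairs$i, qs$pairs$j) %in%
                  paste(out$pairs$i, out$pairs$j)))
  # already-maximal structures gain nothing
  s <- "GGGAAACCC"
  maxed <- fold_max_pairs(s)
  again <- fold_global(s, maxed)
  expect_equal(nrow(again$pairs), nrow(maxed$pairs))
  # empty constraint equals the unconstrained fold
  empty <- rna_structure(9)
  expect_equal(fold_global(s, empty)$pairs[c("i", "j")],
               fold_max_pairs(s)$pairs[c("i", "j")])
})

test_that("masked global folding keeps aligned-unpaired positions unpaired", {
  expect_equal(nrow(fold_global("GGGAAACCC", rna_structure(9),
                                mask = 1:9)$pairs), 0L)
  tps <- toy_templates()
  tp <- tps$tmpl_5s
  n <- nchar(tp$sequence)
  ins <- "GGGAAACC"
  q <- paste0(substr(tp$sequence, 1, 40), ins, substr(tp$sequence, 41, n))
  posmap <- c(1:40, rep(NA, nchar(ins)), 41:n)
  aln <- structure(list(ops = data.frame(op = c("M", "I", "M"),
                                         len = c(40L, nchar(ins), n - 40L)),
                        score = NA_real_, posmap = posmap,
                        revmap = match(seq_len(n), posmap)),
                   class = "rna_alignment")
  qs <- transfer_structure(tp, aln)
  mask <- build_default_mask(aln, tp)
  # mask is exactly the aligned positions unpaired in the template
  expect_true(all(is.na(tp$structure$partner[aln$posmap[mask]])))
  out <- fold_global(q, qs, mask = mask)
  paired <- c(out$pairs$i, out$pairs$j)
  expect_false(any(paired %in% mask))
  # paired positions are template-paired or inserted
  tmpl_paired <- which(!is.na(aln$posmap) &
                       !is.na(tp$structure$partner[ifelse(is.na(aln$posmap),
                                                          1L, aln$posmap)]))
  expect_true(all(paired %in% c(tmpl_paired, which(is.na(posmap)))))
  expect_error(fold_global(q, qs, mask = qs$pairs$i[1]), "conflicts")
})
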