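# Synthetic template library and mutated query generator.  These fixtures
# stand in for curated template collections so the whole pipeline is
# testable offline; biological realism of the toy families is a non-goal.

# Seeded RNG scope with a pinned generator, so fixtures are byte-stable
# across platforms and R sessions.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  old_kind <- RNGkind("Mersenne-Twister", "Inversion", "Rejection")
  set.seed(as.integer(seed))
  on.exit({
    RNGkind(old_kind[1], old_kind[2], old_kind[3])
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  force(expr)
}

# Random sequence compatible with a dot-bracket structure: paired positions
# get complementary letters, unpaired positions random letters.
.seq_for_structure <- function(structure) {
  n <- structure$length
  letters_ <- c("A", "C", "G", "U")
  duos <- matrix(c("G", "C", "C", "G", "A", "U", "U", "A", "G", "U"),
                 ncol = 2, byrow = TRUE)
  s <- sample(letters_, n, replace = TRUE)
  p <- structure$pairs
  for (k in seq_len(nrow(p))) {
    duo <- duos[sample.int(nrow(duos), 1L), ]
    s[p$i[k]] <- duo[1]; s[p$j[k]] <- duo[2]
  }
  paste(s, collapse = "")
}

#' Generate the synthetic toy template library
#'
#' Builds a deterministic library of four templates covering all selection
#' stages: a 76-nt tRNA-style cloverleaf (four helices around a multibranch
#' loop, Sprinzl-style numbering labels), a 120-nt 5S-like three-helix
#' template, a 300-nt `"long"`-category template (a chain of hairpins) and
#' a 14-nt pseudoknot template with one page-1 pair.  Coordinates come from
#' [layout_radial()].  The same seed gives byte-identical fixture files.
#'
#' @param library_dir optional directory to write the library into (with
#'   its stage index).
#' @param seed RNG seed for the fixture sequences.
#' @return Named list of four [rna_template()] objects.
#' @export
make_toy_templates <- function(library_dir = NULL, seed = 1L) {
  .with_seed(seed, {
    dbs <- list(
      trna = paste0(strrep("(", 7), "..", strrep("(", 4), strrep(".", 8),
                    strrep(")", 4), ".", strrep("(", 5), strrep(".", 7),
                    strrep(")", 5), strrep(".", 5), strrep("(", 5),
                    strrep(".", 7), strrep(")", 5), strrep(")", 7), "...."),
      fives = paste0(strrep("(", 16), "...", strrep("(", 12), strrep(".", 10),
                     strrep(")", 12), strrep(".", 5), strrep("(", 12),
                     strrep(".", 10), strrep(")", 12), "...",
                     strrep(")", 16), strrep(".", 9)),
      long = paste0(strrep(paste0(".....", strrep("(", 10), strrep(".", 8),
                                  strrep(")", 10)), 9), "..."),
      pk = "(((..[..))).]."
    )
    cats <- c(trna = "trna", fives = "family", long = "long", pk = "family")
    ids <- c(trna = "tmpl_trna", fives = "tmpl_5s", long = "tmpl_long",
             pk = "tmpl_pk")
    out <- list()
    for (nm in names(dbs)) {
      st <- parse_dotbracket(dbs[[nm]])
      sq <- .seq_for_structure(st)
      lay <- layout_radial(sq, st)
      labels <- if (nm == "trna") as.character(seq_len(st$length)) else NULL
      out[[ids[[nm]]]] <- rna_template(id = ids[[nm]], sequence = sq,
                                       structure = st, coords = lay$coords,
                                       labels = labels,
                                       category = cats[[nm]])
    }
    if (!is.null(library_dir)) {
      for (tp in out) write_template(tp, library_dir, overwrite = TRUE)
      write_library_index(library_dir)
    }
    out
  })
}

#' Mutate a template sequence into a query with known truth alignment
#'
#' Applies seeded point substitutions and single-nucleotide insertions and
#' deletions to a template's sequence and returns both the query record and
#' the true edit script (as an `rna_alignment` of query onto template), so
#' selection and layout accuracy can be scored against ground truth.
#'
#' @param template an [rna_template()].
#' @param sub_rate,ins_rate,del_rate per-position event rates in `[0, 0.2]`.
#' @param seed RNG seed.
#' @return A list with `record` (`id`, `sequence`) and `truth`
#'   (`rna_alignment`).
#' @export
mutate_query <- function(template, sub_rate = 0.05, ins_rate = 0,
                         del_rate = 0, seed = 1L) {
  rates <- c(sub_rate, ins_rate, del_rate)
  if (any(rates < 0) || any(rates > 0.2)) {
    stop("mutation rates must lie in [0, 0.2]")
  }
  .with_seed(seed, {
    tseq <- strsplit(template$sequence, "")[[1]]
    letters_ <- c("A", "C", "G", "U")
    qchars <- character(); ops <- character()
    for (p in seq_along(tseq)) {
      if (runif(1) < del_rate) {
        ops <- c(ops, "D")
      } else {
        ch <- tseq[p]
        if (runif(1) < sub_rate) ch <- sample(setdiff(letters_, ch), 1L)
        qchars <- c(qchars, ch)
        ops <- c(ops, "M")
      }
      if (runif(1) < ins_rate) {
        qchars <- c(qchars, sample(letters_, 1L))
        ops <- c(ops, "I")
      }
    }
    if (length(qchars) == 0L) stop("all positions deleted; lower del_rate")
    nq <- length(qchars); nt <- length(tseq)
    posmap <- rep(NA_integer_, nq); revmap <- rep(NA_integer_, nt)
    qi <- 0L; ti <- 0L
    for (op in ops) {
      if (op == "M") {
        qi <- qi + 1L; ti <- ti + 1L
        posmap[qi] <- ti; revmap[ti] <- qi
      } else if (op == "I") qi <- qi + 1L
      else ti <- ti + 1L
    }
    r <- rle(ops)
    truth <- structure(list(ops = data.frame(op = r$values,
                                             len = r$lengths),
                            score = NA_real_,
                            posmap = posmap, revmap = revmap),
                       class = "rna_alignment")
    list(record = list(id = paste0(template$id, "_mut", seed),
                       sequence = paste(qchars, collapse = "")),
         truth = truth)
  })
}
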