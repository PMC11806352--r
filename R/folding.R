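# Constrained maximum-base-pair folding of regions the template does not
# cover.  A Nussinov-style DP maximizes the pair count subject to fixed
# pairs, an exclusion mask and an optional region; thermodynamic energies
# are out of scope by design.

#' Build a folding constraint
#'
#' @param fixed_pairs data frame with columns `i`, `j`: pairs that must
#'   appear in the output (disjoint, mutually non-crossing).
#' @param forbidden integer vector of positions that may not pair.
#' @param region optional length-2 integer vector `c(lo, hi)` restricting
#'   where new pairs may form (both partners inside).
#' @param seq the sequence the constraint will be applied to (used to
#'   validate fixed pairs against the pairing alphabet and hairpin rule).
#' @return A list of class `fold_constraint`.
#' @export
fold_constraint <- function(fixed_pairs = NULL, forbidden = integer(),
                            region = NULL, seq = NULL) {
  if (is.null(fixed_pairs)) fixed_pairs <- data.frame(i = integer(),
                                                      j = integer())
  fixed_pairs <- as.data.frame(fixed_pairs)[c("i", "j")]
  fixed_pairs$i <- as.integer(fixed_pairs$i)
  fixed_pairs$j <- as.integer(fixed_pairs$j)
  if (any(fixed_pairs$i >= fixed_pairs$j)) stop("fixed pairs need i < j")
  if (anyDuplicated(c(fixed_pairs$i, fixed_pairs$j))) {
    stop("fixed pairs are not disjoint")
  }
  if (.any_crossing(fixed_pairs$i, fixed_pairs$j)) {
    stop("fixed pairs cross each other")
  }
  forbidden <- as.integer(forbidden)
  if (any(c(fixed_pairs$i, fixed_pairs$j) %in% forbidden)) {
    stop("a fixed pair touches a forbidden position")
  }
  if (!is.null(region)) {
    region <- as.integer(region)
    if (length(region) != 2L || region[1] > region[2]) {
      stop("region must be c(lo, hi) with lo <= hi")
    }
  }
  if (!is.null(seq)) {
    ok_pair <- c("AU", "UA", "GC", "CG", "GU", "UG")
    for (k in seq_len(nrow(fixed_pairs))) {
      i <- fixed_pairs$i[k]; j <- fixed_pairs$j[k]
      if (j - i <= 3L) {
        stop("fixed pair (", i, ",", j, ") violates the hairpin rule j - i > 3")
      }
      duo <- paste0(substr(seq, i, i), substr(seq, j, j))
      if (!duo %in% ok_pair) {
        stop("fixed pair (", i, ",", j, ") is not in the pairing alphabet (",
             duo, ")")
      }
    }
  }
  structure(list(fixed_pairs = fixed_pairs, forbidden = forbidden,
                 region = region), class = "fold_constraint")
}

#' Constrained maximum-pairing fold
#'
#' Nussinov-style dynamic programming maximizing the number of base pairs
#' from `{AU, UA, GC, CG, GU, UG}` with the hairpin rule `j - i > 3`,
#' subject to the constraint: all fixed pairs appear, no pair touches a
#' forbidden position, new pairs stay inside the region (if any), and
#' everything is mutually non-crossing.  Traceback is deterministic
#' (ties: `i` pairs with the smallest admissible partner, bifurcating
#' there).
#'
#' @param seq RNA sequence.
#' @param constraint a [fold_constraint()] (default: unconstrained).
#' @return An [rna_structure()]; pairs not in the fixed set are flagged
#'   `predicted`.
#' @export
#' @examples
#' to_dotbracket(fold_max_pairs("GGGAAACCC"))
fold_max_pairs <- function(seq, constraint = fold_constraint()) {
  seq <- normalize_rna(seq)
  n <- nchar(seq)
  # validate fixed pairs against this sequence before the DP
  constraint <- fold_constraint(constraint$fixed_pairs, constraint$forbidden,
                                constraint$region, seq = seq)
  fixed <- integer(n)
  fp <- constraint$fixed_pairs
  if (nrow(fp) > 0L) {
    if (max(fp$j) > n) stop("fixed pair index out of range")
    fixed[fp$i] <- fp$j
    fixed[fp$j] <- fp$i
  }
  forb <- rep(FALSE, n)
  forb[constraint$forbidden[constraint$forbidden <= n]] <- TRUE
  rlo <- 0L; rhi <- 0L
  if (!is.null(constraint$region)) {
    rlo <- constraint$region[1]; rhi <- constraint$region[2]
  }
  res <- .fold_cpp(seq, fixed, forb, rlo, rhi)
  if (length(res$i) == 0L) return(rna_structure(n))
  rna_structure(n, data.frame(i = res$i, j = res$j, page = 0L,
                              predicted = !res$fixed))
}

#' Local folding of inserted regions
#'
#' Folds each maximal inserted run of at least `min_len` nucleotides on
#' its own (all outside positions barred), adding the predicted pairs to
#' the query structure; template-derived pairs are untouched.  Runs
#' shorter than `min_len` stay unfolded loops.
#'
#' @param seq query sequence.
#' @param qstruct the query [rna_structure()] (template-derived pairs).
#' @param aln the `rna_alignment` identifying inserted runs.
#' @param min_len minimum insertion length to fold (default 6; the
#'   hairpin rule makes spans below 5 unfoldable anyway).
#' @return The augmented [rna_structure()].
#' @export
fold_local <- function(seq, qstruct, aln, min_len = 6L) {
  ins <- is.na(aln$posmap)
  if (!any(ins)) return(qstruct)
  runs <- rle(ins)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  add <- data.frame(i = integer(), j = integer())
  for (r in which(runs$values & runs$lengths >= min_len)) {
    lo <- starts[r]; hi <- ends[r]
    sub <- substr(seq, lo, hi)
    f <- fold_max_pairs(sub)
    if (nrow(f$pairs) > 0L) {
      add <- rbind(add, data.frame(i = f$pairs$i + lo - 1L,
                                   j = f$pairs$j + lo - 1L))
    }
  }
  if (nrow(add) == 0L) return(qstruct)
  pairs <- rbind(qstruct$pairs,
                 data.frame(i = add$i, j = add$j, page = 0L,
                            predicted = TRUE))
  rna_structure(qstruct$length, pairs)
}

#' Global folding constrained by the template structure
#'
#' Folds the whole sequence with the query's page-0 pairs as fixed
#' constraints; added pairs are flagged `predicted`.  Pseudoknot pages of
#' `qstruct` are carried through unchanged.
#'
#' @inheritParams fold_local
#' @param mask optional integer positions barred from pairing.
#' @return The augmented [rna_structure()].
#' @export
fold_global <- function(seq, qstruct, mask = integer()) {
  p0 <- qstruct$pairs[qstruct$pairs$page == 0L, , drop = FALSE]
  if (any(c(p0$i, p0$j) %in% mask)) {
    stop("exclusion mask conflicts with a fixed pair")
  }
  cons <- fold_constraint(fixed_pairs = p0[c("i", "j")], forbidden = mask)
  f <- fold_max_pairs(seq, cons)
  pk <- qstruct$pairs[qstruct$pairs$page > 0L, , drop = FALSE]
  rna_structure(qstruct$length, rbind(f$pairs, pk))
}

#' @rdname fold_global
#' @export
fold_global_masked <- fold_global

#' Default exclusion mask: template-aligned, template-unpaired positions
#'
#' Returns the query positions aligned to the template that are unpaired
#' in the template, so that global masked folding keeps every aligned
#' nucleotide in its template pairing state while insertions may fold.
#'
#' @param aln the `rna_alignment` of the query onto the template.
#' @param template the [rna_template()].
#' @return Sorted integer vector of query positions.
#' @export
build_default_mask <- function(aln, template) {
  m <- which(!is.na(aln$posmap))
  m[is.na(template$structure$partner[aln$posmap[m]])]
}
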