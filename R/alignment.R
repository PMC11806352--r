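# Template selection: k-mer seed filtering, affine-gap fit alignment,
# staged selection and structure transfer.

#' Affine-gap fit alignment of a query to a template sequence
#'
#' Semi-global dynamic programming: the query is aligned end-to-end while
#' template overhangs at either end are free, so that fragments map into
#' long templates.  `N` never matches.  Traceback is deterministic (ties
#' prefer Match, then Delete, then Insert).
#'
#' @param query,template_seq RNA sequences (characters `A C G U N`).
#' @param match,mismatch,gap_open,gap_extend scoring parameters; a gap of
#'   length `L` costs `gap_open + (L - 1) * gap_extend`.
#' @return An object of class `rna_alignment`: `ops` (run-length data frame
#'   over `M`/`I`/`D`), `score`, `posmap` (per query position: template
#'   position or `NA` if inserted), `revmap` (per template position: query
#'   position or `NA` if deleted).
#' @export
#' @examples
#' align_sequences("GGCC", "GGCC")$score
align_sequences <- function(query, template_seq, match = 2, mismatch = -1,
                            gap_open = -5, gap_extend = -1) {
  if (!nzchar(query) || !nzchar(template_seq)) stop("empty sequence")
  res <- .align_cpp(query, template_seq, match, mismatch, gap_open, gap_extend)
  structure(list(ops = data.frame(op = res$op, len = res$len),
                 score = res$score,
                 posmap = res$posmap, revmap = res$revmap),
            class = "rna_alignment")
}

#' Identity alignment of equal-length sequences
#'
#' @param n sequence length.
#' @param score optional score to record (default `2 * n`, all matches).
#' @return An `rna_alignment` mapping every position to itself.
#' @export
identity_alignment <- function(n, score = 2 * n) {
  structure(list(ops = data.frame(op = "M", len = as.integer(n)),
                 score = score,
                 posmap = seq_len(n), revmap = seq_len(n)),
            class = "rna_alignment")
}

#' @export
print.rna_alignment <- function(x, ...) {
  cat("rna_alignment: score ", x$score, ", ",
      paste0(x$ops$len, x$ops$op, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Rank templates by shared k-mer seeds
#'
#' Counts exact shared k-mers between the query and each template,
#' accumulated per diagonal band of width `2k` (seeds voting for the same
#' band sum); a template's score is its best band.  Candidates with band
#' score at least `min_seeds` are returned sorted by descending score,
#' ties broken by template id.
#'
#' @param query query sequence.
#' @param templates list of [rna_template()] objects.
#' @param k seed length (>= 4).
#' @param min_seeds minimum band score to report a candidate.
#' @return Data frame with columns `id` and `band_score`.
#' @export
seed_filter <- function(query, templates, k = 12L, min_seeds = 2L) {
  k <- as.integer(k)
  if (k < 4L) stop("seed length k must be >= 4")
  if (k > nchar(query)) stop("seed length k exceeds query length")
  qk <- substring(query, seq_len(nchar(query) - k + 1L),
                  seq_len(nchar(query) - k + 1L) + k - 1L)
  qpos <- split(seq_along(qk), qk)
  ids <- character(); scores <- integer()
  for (tp in templates) {
    ts <- tp$sequence
    if (nchar(ts) < k) next
    tk <- substring(ts, seq_len(nchar(ts) - k + 1L),
                    seq_len(nchar(ts) - k + 1L) + k - 1L)
    shared <- intersect(names(qpos), unique(tk))
    if (length(shared) == 0L) next
    tpos <- split(seq_along(tk), tk)
    diags <- integer()
    for (w in shared) {
      grid <- expand.grid(q = qpos[[w]], t = tpos[[w]])
      diags <- c(diags, grid$q - grid$t)
    }
    band <- floor(diags / (2L * k))
    best <- max(table(band))
    if (best >= min_seeds) {
      ids <- c(ids, tp$id); scores <- c(scores, as.integer(best))
    }
  }
  out <- data.frame(id = ids, band_score = scores)
  out[order(-out$band_score, out$id), , drop = FALSE]
}

#' Select the best template for a query by staged matching
#'
#' Stages are processed in the library's category order (default: `long`,
#' `family`, `trna`).  The `long` stage pre-filters with [seed_filter()];
#' shorter categories are aligned directly.  Within a stage the top
#' candidates are aligned with [align_sequences()] and the best is accepted
#' if its normalized score `score / (2 * nchar(query))` reaches `tau`;
#' otherwise the query passes to the next stage.  A query matches at most
#' one template.  Setting `config$template` bypasses selection entirely.
#'
#' @param query query sequence.
#' @param library a library as returned by [read_library()], or a plain
#'   list of templates.
#' @param config see [default_config()].
#' @return A list with `template`, `alignment` and `stage`, or `NULL`
#'   when no template reaches the threshold.
#' @export
select_template <- function(query, library, config = default_config()) {
  if (!is.null(library$templates)) {
    templates <- library$templates
    stages <- if (!is.null(library$stages)) library$stages else config$stages
  } else {
    templates <- library
    stages <- config$stages
  }
  if (length(templates) == 0L) stop("empty template library")
  cats <- vapply(templates, `[[`, "", "category")

  if (!is.null(config$template)) {
    hit <- which(vapply(templates, `[[`, "", "id") == config$template)
    if (length(hit) == 0L) {
      stop("bypass template id '", config$template, "' not in library")
    }
    tp <- templates[[hit[1]]]
    return(list(template = tp,
                alignment = align_sequences(query, tp$sequence),
                stage = "bypass"))
  }

  if (!all(stages %in% c("long", "family", "trna"))) {
    stop("unknown category in stage order: ",
         paste(setdiff(stages, c("long", "family", "trna")), collapse = ", "))
  }
  for (stage in stages) {
    pool <- templates[cats == stage]
    if (length(pool) == 0L) next
    if (stage == "long" && nchar(query) >= config$k) {
      cand <- seed_filter(query, pool, k = config$k,
                          min_seeds = config$min_seeds)
      pool <- pool[match(utils::head(cand$id, config$top_n),
                         vapply(pool, `[[`, "", "id"))]
    }
    if (length(pool) == 0L) next
    best <- NULL
    for (tp in pool) {
      aln <- align_sequences(query, tp$sequence)
      if (is.null(best) || aln$score > best$alignment$score ||
          (aln$score == best$alignment$score && tp$id < best$template$id)) {
        best <- list(template = tp, alignment = aln, stage = stage)
      }
    }
    if (!is.null(best) &&
        best$alignment$score / (2 * nchar(query)) >= config$tau) {
      return(best)
    }
  }
  NULL
}

#' Transfer a template's secondary structure onto the query
#'
#' Each template pair whose two partners are matched by the alignment
#' becomes a query pair on the same page (pseudoknot annotation included);
#' pairs with a deleted partner are dropped and inserted query positions
#' are left unpaired.
#'
#' @param template an [rna_template()].
#' @param aln an `rna_alignment` of the query onto the template.
#' @return An [rna_structure()] on the query.
#' @export
transfer_structure <- function(template, aln) {
  tp <- template$structure$pairs
  qi <- aln$revmap[tp$i]
  qj <- aln$revmap[tp$j]
  keep <- !is.na(qi) & !is.na(qj)
  n <- length(aln$posmap)
  rna_structure(n, data.frame(i = qi[keep], j = qj[keep],
                              page = tp$page[keep]))
}
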