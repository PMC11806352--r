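---
title: "How rnasketch draws RNA secondary structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How rnasketch draws RNA secondary structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnasketch)
```

## The problem and the model

A secondary structure is a set of base pairs over a sequence.  We store it
as 1-based pairs partitioned into *pages*: page 0 is the largest
non-crossing (nested) subset and carries all geometry; pages ≥ 1 hold
pseudoknotted pairs, which are drawn as connectors but never move a
nucleotide.  Page assignment is greedy first-fit over pairs ordered by
increasing 5′ position (ties by decreasing 3′ position); on every pair set
with up to six pairs we have checked it against an exhaustive
minimal-colouring search, and it agreed in all sampled cases.  The greedy
order is part of the format contract, not an optimality claim.

The nested skeleton decomposes into a tree: maximal helices (runs of
directly stacked pairs) and the loops between them, classified by
branching degree (hairpin, internal, multibranch, exterior).  Both layout
engines and the locality analysis work on this tree; during its
construction every backbone edge is assigned to the unique element that
owns it, which is what lets us say precisely which element an insertion or
deletion touched.

## Drawing metrics

All geometry uses one spacing constant: `BASE_SPACING = 8` drawing units
between backbone neighbours, base-pair partners `PAIR_DISTANCE = 8` units
apart, and a helix rise of 8 units per stacked pair.  The absolute scale
is arbitrary in SVG; using a single constant keeps every geometric rule
closed-form (and hence testable against independently computed
coordinates).  The y axis grows downward, the screen convention, and
templates store coordinates the same way.

## Template-based layout

Matched positions inherit the template's coordinates exactly — not
"approximately": the identity case must reproduce the template bit for
bit, and the tests assert a maximum deviation of exactly zero.  Edits are
absorbed locally:

* **Hairpin loops** containing an indel are redistributed uniformly on the
  circle through the closing pair's two bases.  The circumference is
  `(m + 2) * BASE_SPACING` for `m` loop nucleotides (the `+ 2` accounts
  for the closing bases' slots), the radius is clamped below by half the
  closing-pair distance so the circle always reaches its anchors, and the
  centre sits on the perpendicular bisector of the closing pair, on the
  side of the original loop centroid.  Members walk the long way around
  from the 5′ to the 3′ anchor.
* **Internal, multibranch and exterior loops** keep every helix anchor
  fixed and re-place only the unpaired run that contains the edit, on a
  circular arc between its flanking anchors with arc length
  `(g + 1) * BASE_SPACING` for `g` run nucleotides, bulging away from the
  loop centroid.  Because the backbone fixes which gap each nucleotide
  belongs to, this per-gap rule is the "redistribute between anchors"
  behaviour; runs without an edit do not move at all.  We deliberately
  treat internal loops by the anchors-fixed rule rather than the full
  circle rule: it preserves more of the template and gives strictly
  tighter locality.
* **Helices** that gained or lost pairs are re-laddered along the template
  helix axis (outermost-to-innermost direction of the template's stacked
  run), anchored at the outermost pair that still maps onto a template
  pair.  Pair chords keep the template's anchor separation.
* **Terminal exterior runs** (overhangs) extend collinearly from the last
  placed backbone direction.

A structure may contain pairs with no template counterpart at all (from
constrained folding below).  Such novel helices do not move anything:
their positions are placed by the enclosing loop's arc rule, as an
unfolded run, and the predicted pairs are drawn on top as dashed
connectors.  Any position that no rule has placed (possible only inside
novel-helix subtrees) falls back to arc placement between its nearest
placed neighbours.  This keeps the engine total without a tree-edit
machinery, at the cost of not re-opening space for large novel stems —
overlaps are *counted* and reported, never resolved, for template-based
layouts.

## Template-free (radial) layout

The exterior loop runs left to right along a horizontal line, 5′ end at
the origin; helices leave it toward −y.  Each loop is a circle with one
`BASE_SPACING` slot per nucleotide on its cycle, passing exactly through
the closing pair; child helices leave the circle radially at the midpoint
of their two anchor slots, with the outer pair re-centred so partners are
exactly `PAIR_DISTANCE` apart.  The engine is deterministic — identical
input gives bit-identical output — which is what makes byte-level SVG
regression diffs meaningful.

Only this one de-novo engine ships; the choice between alternative layout
engines is modelled by `choose_layout()`, which takes any set of candidate
layouts and picks the one with the fewest overlaps (ties: input order; a
forced name bypasses the choice).  The overlap score counts intersecting
drawn segments (backbone plus page-0 pair connectors, excluding pairs of
segments that share a nucleotide) plus nucleotide pairs closer than half
the base spacing that are neither neighbours nor partners.  This metric is
this package's own quantitative definition; it is validated against an
O(n⁴) brute-force intersection count on random layouts.

## Template selection

Selection is staged: `long` templates first, then `family`, then `trna`;
a query matches at most one template, and unmatched queries fall through
to the next stage.  The `long` stage is pre-filtered with a seed-and-extend
style k-mer filter: exact shared k-mers (default k = 12) vote for
query-minus-template diagonals, votes are summed in diagonal bands of
width 2k, and templates whose best band collects at least `min_seeds = 2`
votes proceed, ranked by band score.  Candidates are then aligned with a
semi-global affine-gap DP (match +2, mismatch −1, gap open −5, extend −1,
gap of length L costs open + (L−1)·extend; `N` never matches).  The query
is aligned end-to-end while template overhangs are free, so a fragment
maps into the interior of a long template.  The best candidate is accepted
when score / (2·|query|) ≥ τ, with τ = 0.5 — the value a perfect match
scores on half its length; τ is a package constant, chosen once, and
exposed in the configuration.  Ties between equally scoring templates go
to the lexicographically smallest template id, and the traceback breaks
ties Match > Delete > Insert, so the whole pipeline is reproducible.

The template's structure is then transferred through the alignment: a
template pair survives if both partners are matched (keeping its page,
pseudoknots included), pairs with a deleted partner are dropped, and
inserted positions start unpaired.

## Constrained folding

Regions the template does not cover can be folded with a Nussinov-style
maximum-base-pair DP: pairs from {AU, UA, GC, CG, GU, UG}, hairpin rule
j − i > 3, everything non-crossing, deterministic traceback (a position
pairs with its smallest admissible partner).  Constraints are fixed pairs
(must appear; validated against the alphabet and hairpin rule before the
DP), forbidden positions, and an optional region for new pairs.  Three
modes mirror common practice: *local* folds each inserted run of at least
6 nt in isolation (below 6 the hairpin rule leaves almost nothing to find
— the minimum pairable span is 5 — so shorter runs stay unfolded loops);
*global* folds the whole molecule with the transferred pairs fixed;
*global-masked* additionally forbids template-aligned positions that are
unpaired in the template, so the template's pairing state is preserved
exactly while insertions may still fold.  Base-pair counting is a
deliberate stand-in for an energy model: the interface contracts
(constraints, masks, regions, dashed rendering of predictions) are the
point, thermodynamics is out of scope.  In the drawing pipeline, global
modes first drop transferred pairs that mutations have made
non-complementary on the query, since they could not be fixed in any fold
of that sequence.

## Rendering, data layers and the regression harness

SVG output is deterministic text with a stable element order (layers,
backbone, connectors, glyphs, labels) and fixed two-decimal coordinates.
Data layers colour per-position values as filled circles behind the
nucleotides.  The alignment-confidence layer uses bin edges
{0, 0.8, 0.85, 0.9, 0.95} with an Okabe–Ito-derived colour-blind-safe
palette; values in [0.95, 1] are intentionally *not* highlighted, so a
clean diagram means a confident alignment.  Only the top edge of that
scheme is externally fixed; the four lower edges and the colours are
package constants.

The regression harness rasterizes SVG onto a 512×512 canvas with a small
in-repo painter (lines, circles, rectangles, polygons; text as a filled
box — full SVG fidelity is a non-goal) and compares images with a global,
single-window SSIM on the greyscale conversion plus mean absolute
per-channel differences.  Both diagrams are painted in the *first*
diagram's viewBox: with per-image auto-fitted viewBoxes a pure translation
would be invisible, and translated copies must fail the gate.  The gate
(SSIM ≥ 0.99 and diff ≤ 2/255) passes sub-pixel perturbations, such as a
tiny font-size change, and fails layout shifts; because text is painted as
hard-edged boxes the harness is more conservative about font changes than
a glyph renderer would be.

Animated morphs interpolate each nucleotide linearly between two
equal-length layouts with declarative SVG animation (no scripting),
default duration 3 s, looping; a static fallback renders the first frame.

## The synthetic fixture library

`make_toy_templates()` builds four deterministic templates spanning every
selection stage: a 76-nt cloverleaf (four helices around a multibranch
loop, per-position numbering labels standing in for Sprinzl positions,
category `trna`), a 120-nt three-helix template (`family`), a 300-nt chain
of nine hairpins (`long`), and a 14-nt template with one pseudoknotted
pair.  Sequences are drawn with a pinned RNG (Mersenne-Twister /
Inversion), paired positions get complementary letters so folds can
reproduce the structures, and coordinates come from the radial engine.
`mutate_query()` applies seeded substitutions and single-nucleotide indels
and returns the true edit script, so selection accuracy and layout
locality can be scored against ground truth.

What the fixtures emulate is the *pipeline contract* — staged matching,
coordinate inheritance, label transfer, pseudoknot plumbing — not
biological families: there are no covariance models, no conserved motifs,
no realistic length or composition distributions.  Passing tests therefore
demonstrate algorithmic correctness on controlled inputs, not recovery
performance on real template libraries.

Test problem sizes (200 mutated queries at 5% substitutions and 2%
indels for selection recovery; 200 random sequences up to 14 nt against
the exhaustive folding oracle; 100 single-indel queries for locality; 500
random layouts for the overlap oracle) were chosen so each property is
exercised across all fixture templates while the whole suite stays
desk-scale.

## Numerical choices and degenerate inputs

* Loop circles clamp their radius at half the anchor distance, so the
  circumference rule cannot produce a circle that misses its anchors.
* Arc placement solves the chord–arc-length equation
  `2 (L/θ) sin(θ/2) = d` for the subtended angle by bisection to 1e−12;
  if the requested arc is no longer than the chord the points fall back to
  the straight segment, and coincident flanks fall back to a logged
  semicircle of radius `(m+1)·BASE_SPACING/π`.
* Ambiguous `N` bases never match in alignment and never pair in folding.
* Characters outside `A C G U N` are replaced by `N` with a warning rather
  than an error; `T` silently becomes `U`.
* In FASTA input, a structure line is recognized by content (bracket
  alphabet with at least one true bracket symbol), so an all-`A` sequence
  line is never mistaken for pseudoknot-letter pages.
* The interchange JSON writer is canonical (fixed key order, jsonlite
  number formatting), which is what makes write→read→write byte-identity
  a testable contract.  Residue indices in the dialect are 1-based
  throughout, matching how biologists number sequences and how R indexes
  vectors.

## Known limitations

* Template matching is pure sequence alignment; there is no profile or
  covariance-model scoring, so remote homologs that only align at the
  structure level will not be matched.
* Large insertions are placed on arcs without moving neighbouring
  elements; the resulting overlaps are reported by `count_overlaps()` but
  not resolved.
* The folding engine maximizes pair count, not free energy, and never
  predicts pseudoknots.
* The rasterizer covers exactly the primitives the renderers emit; it is
  a regression instrument, not an SVG viewer.
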