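# rnasketch

Template-based drawing of RNA secondary-structure diagrams in R.

RNA 2D diagrams carry meaning through their layout: tRNAs are read as
cloverleafs, rRNAs in the community-standard orientations, and related
sequences are easiest to compare when they are drawn the same way.  Generic
layout engines redraw every molecule from scratch, so two nearly identical
sequences can end up in completely different shapes.  `rnasketch` solves
this the way curated-template pipelines do: a query sequence is matched
against a library of templates (sequence + structure + per-nucleotide x,y
coordinates), the template's structure and coordinates are inherited, and
only the loops and helices touched by insertions or deletions are
rearranged locally.  The result is a diagram that is recognizably "the
same picture" as the template, with provenance flags saying which
nucleotides moved.

It is aimed at people building RNA visualization or annotation pipelines
in R who need reproducible, diffable diagram output rather than interactive
editing.

## What is inside

* **Structure I/O** — dot-bracket parsing with pseudoknots (bracket
  families `( ) [ ] { } < > Aa…Zz`; pairs are partitioned into non-crossing
  *pages*, page 0 being the nested skeleton), FASTA with an optional
  structure line, Leontis–Westhof base-pair codes (`cWW`, `tHS`, …).
* **Template selection** — a k-mer seed filter (shared k-mers voting on
  diagonal bands, default k = 12) prunes large templates, then semi-global
  affine-gap alignment (match +2, mismatch −1, gap open −5, extend −1; free
  template end gaps so fragments map into long templates) ranks candidates
  in staged order `long → family → trna`.  A query matches at most one
  template; acceptance requires score ⁄ (2·|query|) ≥ τ = 0.5.
* **Template-based layout** — matched positions inherit template
  coordinates bit-for-bit.  A hairpin loop containing an indel is
  redistributed uniformly on the circle through its closing pair with
  circumference (m + 2)·s, where s = 8 drawing units is the base spacing;
  in internal/multibranch/exterior loops the helix anchors stay fixed and
  only the edited unpaired run is re-arced; helices that gained or lost
  pairs are re-laddered along the template helix axis at 8 units per pair.
* **Template-free layout** — a deterministic radial engine (exterior loop
  on a horizontal line, helices as straight ladders, loops on circles),
  an overlap score (crossing drawn segments + close non-neighbours), layout
  choice by minimal overlaps, and conversion of any layout into a new
  library template.
* **Constrained folding** — a Nussinov-style maximum-base-pair DP
  (pairs from AU/GC/GU, hairpin rule j − i > 3) with fixed pairs, exclusion
  masks and region restriction, in three modes: *local* (fold each inserted
  run ≥ 6 nt on its own), *global* (whole molecule with template pairs
  fixed), *global-masked* (additionally bar template-aligned positions that
  are unpaired in the template).  Predicted pairs are drawn dashed.
* **Rendering** — deterministic SVG diagrams with per-position data layers
  (including the alignment-confidence layer where posteriors in
  [0.95, 1] are deliberately *not* highlighted), pseudoknot connectors,
  Leontis–Westhof glyphs (circle = Watson–Crick, square = Hoogsteen,
  triangle = sugar; cis filled, trans open), single-polyline thumbnails and
  animated SVG morphs between equal-length layouts.
* **Regression harness** — an in-repo rasterizer and global SSIM
  (greyscale 0.299R + 0.587G + 0.114B, C1 = (0.01·255)², C2 = (0.03·255)²)
  with a pass/fail gate (SSIM ≥ 0.99, mean channel diff ≤ 2⁄255).
* **Synthetic fixtures** — a deterministic toy template library (76-nt
  cloverleaf with Sprinzl-style numbering labels, 120-nt 5S-like template,
  300-nt long template, 14-nt pseudoknot) and a mutator that produces
  queries with a known truth alignment.

## Worked example

```r
library(rnasketch)

libdir <- tempfile()
tps <- make_toy_templates(libdir, seed = 1)         # writes the toy library

# a mutated tRNA-like query with 5% substitutions, 2% insertions/deletions
mq <- mutate_query(tps$tmpl_trna, sub_rate = 0.05,
                   ins_rate = 0.02, del_rate = 0.02, seed = 7)
fa <- tempfile(fileext = ".fasta")
writeLines(c(">query", mq$record$sequence), fa)

out <- tempfile()
cmd_draw(fa, libdir, out)
#> record=query status=ok template=tmpl_trna score=133 fold=off overlaps=0
```

The log line says the 75-nt query was matched to the planted cloverleaf
template (`tmpl_trna`) with alignment score 133, drawn without constrained
folding, and the finished diagram has zero overlapping elements.  `out` now
holds `query.svg` (full diagram), `query.thumb.svg` (continuous-line
thumbnail) and `query.json` (the interchange document; its field layout is
frozen in `inst/schema/rna2d-dialect.json`).  Inspecting the layout
directly:

```r
sel <- select_template(mq$record$sequence, read_library(libdir))
lay <- layout_from_template(mq$record$sequence,
                            transfer_structure(sel$template, sel$alignment),
                            sel$template, sel$alignment)
lay
#> rna_layout: 75 nt (inherited=74, rearranged=0, inserted=1)
```

74 of 75 nucleotides sit exactly on the template's coordinates; one
inserted nucleotide was placed on a local arc.  A shell entry point with
the same functionality ships as `exec/rnasketch`
(`rnasketch draw|animate|compare|fixtures`).

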