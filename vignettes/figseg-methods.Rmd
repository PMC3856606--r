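---
title: "Segmenting multi-panel biomedical figures: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting multi-panel biomedical figures: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(figseg)
```

## The problem

Figures in biomedical articles are usually compound: one image holds several
experimental panels (a gel, a micrograph, a bar chart), each marked with a
short label such as "(A)" inside the image and again in the caption. For
figure-based retrieval, classification, or evidence linking, the unit of
interest is the *panel plus its subcaption*, not the compound figure.
Classical low-level segmentation struggles here because panels of different
modality can share pixel statistics, and text-heavy panels (sequence
alignments, blot annotations) look nothing like natural images.

figseg implements a hybrid strategy: it combines three *independent*
estimates of the panel structure — the caption's label tokens, the label
tokens recovered from OCR inside the image, and the connected components of
the binarized image — and then partitions the figure geometrically along
low-cost cut lines anchored at the label positions.

## Pipeline

1. **Harvest** (`harvest_document()`): a typed operator stream (one record
   per text line or placed image, as PDF generators emit them) is walked by
   a small FSM. Paragraphs starting with a figure cue ("Fig.", "Figure",
   case-insensitive) are merged across consecutive one-line text operators
   into caption objects; image operators become figure objects. Figures
   entirely outside the page's text rectangle are dropped as journal logos.
   Maximal runs of adjacent image operators preceding a caption are merged
   into one figure: each fragment's scaling factor is its placed size over
   its native size, and the merged canvas is the placements' bounding box
   rendered at the resolution of the *smallest* scaling factor, so the
   sharpest fragment is never downsampled. Citations masquerading as
   captions are removed by descriptor clustering: the first two words with
   digit runs collapsed to `#` ("Figure #.", "(Fig. #)"), keeping the
   cluster with the most unique figure-number links. Matching minimizes
   `C = d · p` greedily per page (`d` = boundary distance, `p` = 1 within a
   column, 10 across columns), then pools leftovers across pages with
   `C = d · p · (1 + |Δpage|)`.
2. **Caption segmentation** (`segment_caption()`): hand-coded lexical rules
   recognize parenthesized single labels, ranges ("(A-C)", "(a to c)",
   "(A, B, and C)"), and bare delimited labels ("B.", "c)"), over Latin
   letters, Roman numerals ≤ XII and integers ≤ 20. False positives are
   removed by sequence filtering (below), and the caption is split at the
   surviving token positions; a range token's following text is duplicated
   once per label in the range.
3. **In-image labels** (`recover_labels()`): OCR tokens are classified as
   simple ("A"), right-closed ("A)"), or closed ("(A)") label candidates,
   grouped by (alphabet, category), and scored with
   `confidence = 1 / (1 + Gaps · Panels)`, where `Panels` is the largest
   label position in the group and `Gaps` the number of missing positions.
   A complete sequence therefore always beats a gapped one.
4. **Image preprocessing** (`preprocess_figure()`): grayscale conversion
   (BT.601 weights), 256-bin histogram, triangle-method threshold (maximum
   perpendicular distance between histogram counts and the peak-to-tail
   line), minority-side binarization, OCR text-box removal, 4-connected
   labeling, an area filter at 50 px, and transitive merging of overlapping
   component boxes.
5. **Panel segmentation** (`run_figure()`): the three counts are reconciled
   (consensus → CC arbitration → decision tree), gapped label sequences are
   completed geometrically, a layout graph links each label node to its
   closest band-sharing neighbors, each edge contributes a perpendicular
   minimum-cost cut, crossing cuts are resolved by stopping the costlier
   one, and the resulting faces are paired with subcaptions by label.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `min_cc_area` | 50 px | components smaller than this are noise |
| `penalty_factor` | 10 | cross-column figure–caption match penalty |
| `text_box_padding` | 0 px | padding around OCR boxes before clearing |
| connectivity | 4 | pixel adjacency for component labeling |
| alphabet priority | latin > roman > arabic | cross-alphabet tie rule |
| roman bound | XII | largest numeral accepted as a label |
| arabic bound | 20 | largest integer accepted as a label |

The area threshold and the penalty factor are the two values with stated
operating points; the alphabet bounds are package choices sized to figures
with up to 16 panels (corpus figures average about 3).

## Count estimation

Subcaptions are the most reliable count source. The estimator is:

* `n_subcaptions == n_labels > 0` → that value (*consensus*);
* else if the component count equals exactly one of the two → that one
  (*cc_arbitrated*);
* else a CART decision tree over
  `(n_subcaptions, n_labels, n_cc, gaps)` predicts the count (*model*),
  floored at 1. The tree replaces a C4.5 model; with four small integer
  features and bounded classes, an impurity-greedy CART with deterministic
  tie-breaks (first feature, smallest threshold) is equivalent in capacity
  and reproducible. All-zero evidence means a single unlabeled panel.

## Geometry: cuts, crossings, gap filling

Cut candidates are the integer coordinates strictly between the two node
anchors of an edge; the cost of a candidate is the summed extent, along the
edge axis, of the components its full-span perpendicular line would slice
(zero in whitespace gutters). Ties go to the candidate closest to the
corridor midpoint, then the smaller coordinate. Where a vertical and a
horizontal cut cross, the costlier cut is truncated at the crossing and
keeps the side containing its originating edge; equal-cost crossings
coexist, which is exactly what a clean grid needs. Faces are labeled by a
wall-aware flood fill, so every pixel belongs to exactly one region; if a
face ends up with zero or several label nodes the partition degrades to
nearest-anchor blocks and is flagged.

Gap filling discretizes the figure into blocks from the detected labels.
One row or column: a missing label goes to the midpoint of its sequence
neighbors, or is extrapolated by the median neighbor spacing at sequence
ends; with a single detected label the spacing falls back to
`figure_extent / Panels` and the axis to the longer figure side. Grids are
checked for row-major and column-major reading order; a missing position
inherits its row band's center and its column band's center, only if that
block is empty.

Design points the source method leaves open, decided here:

* **Cross-page disparity** is `1 + |Δpage|`: same-page costs unchanged,
  linear growth.
* **"Forming a sequence"** is the longest strictly-increasing subsequence
  of label positions, ties to the earliest caption offset (checked against
  an exhaustive-subsequence oracle in the tests).
* **Ambiguous I/V/X** tokens are read as Roman exactly when an unambiguous
  Roman token co-occurs (caption and OCR paths alike). Letting the
  confidence heuristic arbitrate instead is unsound: a lone stray "I"
  forms a complete one-member Roman sequence with confidence 1.0 and would
  always beat a genuinely gapped Latin group.
* **The caption head's figure number** ("Figure 12.") is exempt from label
  lexing; otherwise every Arabic-labelled caption would be corrupted by its
  own figure number.
* **Column tags**: an object is left/right if its box fits the respective
  half of the page text rectangle with 5% tolerance, else double.
* **Foreground polarity**: after thresholding, the minority pixel side is
  the foreground, which handles dark-on-light and inverted panels with one
  rule.
* **Triangle tail**: the non-zero histogram extreme farther from the peak;
  distance ties resolve toward the tail.

## The synthetic world

`generate_figure()` renders panels on grids (1×1 to 4×4) or ragged rows:
white background, one dark content component per panel (about 70×55 px,
jittered), 14 px whitespace gutters, and a label glyph from a built-in 5×7
bitmap font at each panel's top-left whose box doubles as a clean OCR
token — no OCR engine runs in the tests. Captions come in per-label, range,
and unlabeled styles; a corruption mode appends a decoy duplicate token
like "(C)" mimicking abbreviation collisions. `corrupt_ocr()` drops tokens
and confuses characters (D→I style) at stated rates, deterministically.
Rows that span multiple columns in ragged layouts get near-full-width
content, which is what makes cutting through them expensive and exercises
the crossing-stop rule.

For regular grids the generator also computes the expected cut coordinates
analytically from its own layout arithmetic (the first zero-cost gutter
column at or after the corridor midpoint), so end-to-end tests can demand
*exact* panel-box equality rather than loose overlap.

What a green suite does establish: exact recovery on clean grids and
ragged fixtures, ≥95% restoration of a dropped label's block, 100% decoy
removal, exact logo/fragment/matching behavior on synthetic documents, and
≥90% held-out accuracy of the count model on its own decision branch. What
it does not: real-PDF operator extraction (the adapter boundary is JSONL),
real OCR noise statistics, photometric variety (stains, JPEG artifacts,
anti-aliased text), rotated or overlapping panels, and vector-drawn
figures, which the operator model does not represent at all.

## Numerical and degenerate-input choices

* Histograms with a single non-zero bin threshold at that bin with a
  warning; uniform images produce an empty foreground.
* Label anchors closer than 2 px along an edge axis are an error (labels
  overlap; no cut corridor exists).
* Empty operator streams, captions without labels, and token-less figures
  are all valid degenerate inputs, producing empty outputs or a single
  `∅`-labeled panel rather than errors.
* Robustness fixtures for dropped labels use figures with at least three
  panels: with one detected label in a 1×2 figure the missing position is
  underdetermined (the best estimate is off by exactly half the gutter), so
  including that shape would test arithmetic luck, not the method.

## Known limitations

* Figures drawn as vector primitives never appear as image operators and
  are invisible to the harvest stage.
* A multi-panel figure with *no* recoverable label tokens degrades to a
  single flagged panel; component-only layout recovery is out of scope.
* The greedy matcher is not an optimal assignment; like the source method
  it can cascade a bad early match on pathological pages.
* Subcaption pairing is purely label-based; a caption using a different
  alphabet than the in-image labels yields panels without subcaptions.
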