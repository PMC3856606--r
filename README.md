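# figseg

Segmentation of compound (multi-panel) biomedical figures into unimodal
panels paired with their subcaptions.

Biomedical publications routinely validate a result with several
experimental modalities in one figure — a gel next to a micrograph next to
a bar chart — marked with panel labels such as "(A)" both inside the image
and in the caption. Retrieval, triage and evidence-linking systems need the
*panel + subcaption* pair, not the compound image, but low-level
segmentation alone cannot find the panel structure: different modalities
share pixel statistics, and text-heavy panels defeat edge- or color-based
cues. figseg is for tool builders in literature mining and biocuration who
need that decomposition to be automatic and testable.

## Method

For a figure with caption text and OCR tokens, three independent estimates
of the panel count are combined:

* `n_s` — subcaptions, from lexical analysis of the caption (parenthesized
  labels, ranges like "(A-C)" expanded, bare delimited labels; false
  positives removed by longest-increasing-subsequence filtering with
  alphabet priority latin > roman > arabic);
* `n_l` — in-image labels, from OCR tokens classified as simple /
  right-closed / closed label candidates, grouped by type and scored with
  `confidence_i = 1 / (1 + Gaps_i · Panels_i)`;
* `n_cc` — merged 4-connected components of the binarized figure (triangle
  threshold, text boxes removed, area ≥ 50 px, overlapping boxes merged).

If `n_s = n_l` that is the count (consensus); else if `n_cc` matches
exactly one of them, that one wins; else a retrainable decision tree over
`(n_s, n_l, n_cc, gaps)` predicts it. Missing labels are re-inserted
geometrically (midpoint/grid-alignment rules), a layout graph `G = (V, E)`
links each label node to its closest horizontal and vertical neighbors, and
each edge contributes a perpendicular cut at the coordinate minimizing the
summed extent of intersected components; where cuts cross, the costlier one
stops at the intersection. Regions are then paired with subcaptions by
label. Document harvesting (figure–caption pairs from an operator stream,
logo removal, N-to-1 fragment merging at the smallest scaling factor,
greedy cost matching `C = d · p · disparity` with cross-column penalty
`p = 10`) is included for end-to-end use.

## Worked example

```r
library(figseg)

fx  <- generate_figure(fixture_spec(rows = 2, cols = 2, seed = 42))
res <- run_figure(fx$image, fx$truth$caption, fx$truth$tokens)
res$decision
res$panels[, c("label", "x_min", "y_min", "x_max", "y_max", "subcaption")]
```

prints

```
decision: consensus  n_panels: 4
  label x_min y_min x_max y_max                 subcaption
1     A     0     0    96    86    Overlay lysate overlay.
2     B    96     0   234    86     Signal control lysate.
3     C     0    86    96   206 Interaction control assay.
4     D    96    86   234   206 Construct extract profile.
```

The four regions partition the 234×206 px fixture exactly at its whitespace
gutters; `decision: consensus` records that caption and OCR label counts
agreed, and each panel carries the caption fragment that follows its label
token. A dropped OCR token, a decoy "(C)" in the caption, ragged layouts,
and noisy corpora are exercised the same way — see
`vignettes/figseg-methods.Rmd` for the model, parameters and design notes.

A command-line interface covering segmentation, harvesting, caption
analysis, fixture synthesis, evaluation and count-model training is
installed at `inst/cli/figseg.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "figseg.R", package = "figseg"))')" \
    synth figure --rows 2 --cols 2 --seed 42 --out fx/
```

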