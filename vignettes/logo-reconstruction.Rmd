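---
title: "Reconstructing PWMs from sequence logo images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing PWMs from sequence logo images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(logolift)
```

## The inversion model

A DNA sequence logo encodes a 4 × L probability matrix `P` graphically:
the letter stack at position `j` has total height equal to the column's
information content `I_j = 2 + Σ_i P_ij log2 P_ij` bits, and each letter
within the stack has height `P_ij · I_j`. Reconstruction must go the
other way, and the naive route — measure each letter's share of the
stack and read probabilities off directly — fails exactly where logos
are least informative: a low-IC column is only a few pixels tall, so a
one-pixel measurement error becomes a large probability error, and the
direct estimate systematically inflates the information content.

`logolift` therefore measures only two robust quantities per column —
the total stack height and the ratio of the two tallest letters — and
recovers probabilities by solving the information-content equation
under one of two model cases:

* **Single strong letter.** The three weak letters are assumed equally
  probable, `p_weak = (1 − p_1st)/3`, giving the one-parameter equation
  `I(p) = 2 + p log2 p + (1 − p) log2((1 − p)/3)`, which is strictly
  increasing on `p ∈ [0.25, 1]` with `I(0.25) = 0` and `I(1) = 2`, so
  the inverse is well defined.
* **Two strong letters.** When the second-tallest letter spans at least
  3 pixel rows (`secondary_min_px`, configurable) it is treated as a
  strong letter with `p_2nd = p_1st · h_2nd / h_1st` fixed by the
  measured pixel-height ratio `r`; the remaining two letters share
  `p_weak = (1 − p_1st − p_2nd)/2`. On the feasible interval
  `p_1st ∈ [1/(1+3r), 1/(1+r)]` — from "second letter no stronger than
  the weak pair" up to "weak pair extinct" — the equation is again
  monotone in `p_1st`.

The restriction of the single-strong inverse to `[0.25, 1]` is a
modelling choice: below 0.25 the "strong letter" premise is violated
and the map ceases to be monotone. A letter with only 1–2 pixel rows is
deliberately *not* promoted to a strong letter; it is folded into the
equal weak share. Likewise when a third letter clears the 3-pixel bar:
the model has exactly two cases, and the third letter joins the weak
pair. These choices trade per-letter detail for robustness to pixel
noise, which is the point of the method.

## Numerical solution

Both equations are solved by bracketing plus bisection to a residual of
1e-4 bits. For the single-strong case a precomputed table of `I(p)` at
0.01 probability steps over `[0.25, 1]` (76 entries, endpoints `(0.25,
0)` and `(1, 2)`) supplies the bracket; nearest-entry lookup alone would
bound the error only loosely, and refinement is cheap and
deterministic. Measured information content can land slightly outside
`[0, 2]` because stack heights are counted in whole pixel rows; values
within 0.05 bits of the range are clamped, larger excursions raise an
error. A two-strong measurement whose `(I, r)` pair is infeasible —
possible on corrupt or heavily compressed images — falls back to the
single-strong case with a warning, except that a small overshoot above
the `p_weak = 0` boundary is clamped to the boundary solution
`(1/(1+r), r/(1+r))`, because with two letters of equal measured height
a single-strong fallback would be qualitatively wrong. Ties between
equal tallest letters are broken alphabetically; this fixes labels, not
probabilities.

## Image pipeline

**Color classification.** Every pixel is assigned to the nearest of six
fixed RGB centroids — black (0,0,0), white (255,255,255), red
(200,25,32), green (57,178,65), blue (43,60,147), yellow (240,173,10) —
under Euclidean distance, with the standard DNA color code green = A,
blue = C, yellow = G, red = T. Anti-aliased edge pixels simply go to
whichever centroid is nearest; the resulting ±1-row height jitter is
absorbed by the entropy inversion. Logos drawn in non-standard colors
are out of scope.

**Noise removal.** Non-white connected components smaller than
`noise_min_component_px` (default 4; 4-connectivity via
`EBImage::bwlabel`) are reclassified as white, which deletes specks and
the dashes of dashed background rules. A solid 1-pixel horizontal black
rule spanning at least half the image width strictly inside the colored
content is also removed; the X axis never matches this pattern because
nothing is drawn below it. The operation is idempotent and never
creates foreground.

**Axes and scale.** Axes are assumed black: a vertical black run
covering ≥ 50% of the image height near the left edge is the Y axis, a
horizontal run covering ≥ 50% of the width near the bottom is the X
axis. With both axes present the pure logo region is the box they
frame — this keeps near-blank columns inside the region — and the Y-axis
pixel length defines the 2-bit scale. Without axes the region is the
bounding box of colored pixels (which automatically excludes tick marks
and black label text) and the tallest stack is assumed to carry the
maximum 2 bits. That assumption is forced — with no drawn scale there is
nothing else to anchor to — and it systematically inflates the
reconstruction when the true maximum column is weaker; this is a known,
uncorrected bias, so axis-less logos of uniformly weak motifs
reconstruct too sharp.

**Column segmentation.** Colored pixels are projected onto the X axis;
peaks are maximal positive runs separated by zero gaps (a 3-px
moving-maximum closing is applied first only when single-pixel gaps
fragment individual letters). The spacing between consecutive peak
centers is voted: the mode of the rounded spacings wins (ties toward
the smaller width, which favors more columns and is recoverable by the
later fine-adjustment), and the final width is the mean of the spacings
within 1 px of the mode — averaging the consensus set recovers
fractional pitch that per-spacing rounding discards, while spacings
across a blank column (≈ twice the pitch) stay excluded. The column
count is the region width over this width, rounded; boundaries are laid
out uniformly and each internal boundary is snapped to the nearest
projection minimum within ±25% of a column width, a bounded correction
that cannot destroy the voted global layout. A user-supplied column
count bypasses detection entirely and yields uniform boundaries — the
rescue for fused letters and very low-resolution logos, where no
reliable minima exist to snap to.

**Column measurement.** Within one column interval the stack height is
the number of pixel rows containing any letter-colored pixel, and each
nucleotide's height is the number of rows containing at least one pixel
of its color; block identity follows the majority color (consensus
voting). Glyph-shape recognition (OCR) is deliberately avoided: logo
fonts are stretched far from their natural aspect ratio and color alone
identifies the base.

**Failure rescues.** Recoverable anomalies produce warnings, not
errors: an empty column becomes uniform (0.25 each), an infeasible
two-strong pair falls back, a column-count override that disagrees with
detection is honored and flagged. Hard errors are reserved for
unreadable input, blank images, and alpha-channel PNGs (rejected unless
`flatten_alpha = TRUE` composites them over white). For composite
figures the `crop` option applies before any analysis, mirroring how a
user rescues a logo embedded in a larger panel; reconstruction works
best when the crop leaves no left or right margin.

## The synthetic corpus: what it does and does not show

There is no desk-available collection of published logo images paired
with their true PWMs, so accuracy is verified by round-trip on logos the
package renders itself. `render_corpus()` draws each PWM column from a
Dirichlet(1,1,1,1) distribution (uniform on the probability simplex),
samples motif lengths uniformly from 6–15, and renders at 600 × 200 px
with axes — the corpus behind the headline numbers; `eval_roundtrip()`
reconstructs every image and reports the per-logo flattened Pearson
correlations. The evaluation corpus in the test suite and acceptance
script uses 100 logos, small enough to run in well under a minute per
seed yet large enough that the median is stable to ±0.001 across seeds.

The renderer emulates the features the pipeline depends on — exact
information-content scaling, largest-letter-on-top stacking, the
standard color code, black axes, white background, PNG/JPEG/GIF output —
and records its ground-truth geometry so geometry tests never re-derive
it from pixels. Its letterforms are analytic block glyphs, not a real
font, and it draws no anti-aliasing (JPEG output adds real compression
artifacts). Its measurement path shares no code with the
reconstructor's. Consequently a passing round trip demonstrates the
pipeline end to end on clean, well-formed logos, but it does not
exercise scanned-figure pathologies: heavy anti-aliasing, sub-pixel
letter widths, non-standard palettes, or surrounding figure clutter
beyond what the crop/column-count rescue tests construct.

One accuracy limit is intrinsic to the inversion model rather than the
implementation: a column holding three or four mid-probability letters
is forced into "at most two strong letters plus equal weak shares", so
its reconstruction error is bounded away from zero no matter how clean
the image. Dirichlet(1) columns produce such flat columns regularly,
while real transcription-factor motifs are typically sharper, so the
corpus is conservative in this respect: the median correlation is
dominated by well-modelled columns, but the corpus *minimum* is set by
whichever logo drew the flattest columns. The per-logo distribution from
`eval_roundtrip()` makes this visible directly (`autoplot()` draws the
standard boxplot).

## Correlation metric

The accuracy metric is the Pearson correlation between the two matrices
flattened entry-wise in fixed row-major (A, C, G, T) order. Flattened
Pearson is the primary definition because it weighs every entry equally
and is insensitive to motif length; a per-column-averaged variant is
exposed via `pwm_correlation(..., method = "percol")`. Two equal
constant matrices (e.g. both uniform) are defined to correlate at 1;
correlation against a constant matrix is otherwise undefined and raises
an error rather than returning a misleading value.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `secondary_min_px` | 3 px | minimum pixel rows for a strong secondary letter; absolute, not resolution-scaled (configurable when working with very large scans) |
| `noise_min_component_px` | 4 px | connected components below this are background noise |
| axis run threshold | 50% of dimension | minimum black-run length to count as an axis |
| snap window | ±25% of column width | how far a column boundary may move to a projection minimum |
| IC clamp slack | 0.05 bits | tolerated pixel-noise overshoot outside [0, 2] |
| solver tolerance | 1e-4 bits | bisection residual for both inversion equations |

## File formats

Reconstructed PWMs are written as CSV (rows A, C, G, T × positions, 6
decimals), MEME minimal motif format (letter-probability matrix with
uniform background — the probability form, since MEME's interchange
format is probability-based), and a TRANSFAC-like tab-delimited
`PO A C G T` probability table as this package's named "enologos-style"
dialect (the historical renderer's exact on-disk format is not publicly
documented). JASPAR PFM count matrices are read and column-normalized.
All writers round-trip through their readers within 1e-6 per entry.

## Known limitations

* Protein logos (20-letter alphabet), probability-scaled (non-IC)
  logos, negative/below-axis letters, multi-row wrapped logos, and
  per-letter outline styles are out of scope.
* Non-standard letter colors are misclassified; color auto-detection is
  not attempted.
* Without a Y axis, the tallest-stack-equals-2-bits assumption inflates
  weak motifs.
* The two-case inversion model caps worst-case accuracy on very flat
  columns, as discussed above.
* GIF support covers the common case (first frame, non-interlaced,
  ≤ 256 colors) via the package's own codec.
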