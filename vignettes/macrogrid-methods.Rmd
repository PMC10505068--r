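---
title: "Locality-normalised quantification of protein macroarrays"
author: "macrogrid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locality-normalised quantification of protein macroarrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(macrogrid)
```

# The measurement problem

A protein macroarray scan is a single 16-bit grayscale image (nominally
2250 × 2250 px at 10 px/mm) of 57 600 printed dots: 240 × 240 dots grouped in
48 × 48 cells of 5 × 5, with a high-contrast black *marker* dot at every cell
centre and the remaining 24 positions holding 12 duplicate clone pairs. Three
properties make naive quantification fail:

* **Geometric warp.** The membrane substrate distorts non-linearly; a global
  grid fit accumulates errors of several dots' width over the array.
* **Heterogeneous background.** Both the additive offset and the
  multiplicative gain vary smoothly across the membrane, and measurably even
  within one cell. There is no reference feature for absolute calibration.
* **Null results.** Markers carry no protein, and a position-dependent
  fraction of dots is blank (clone absent or failed); both must be excluded
  from any statistic estimated from a dot's neighbourhood.

`macrogrid` addresses each in turn. This vignette records the model, the
parameters that matter, the numerical conventions, and the design decisions
that were genuinely open — together with what the synthetic-data tests do and
do not demonstrate about real scans.

# Two-stage positioning

Stage one interpolates the 48 × 48 marker grid bilinearly between the four
operator-supplied corner-marker coordinates, at fractions $i/(n-1)$. Bilinear
(rather than projective) interpolation suffices because scan rotation is
negligible for arrays this large and stage two absorbs the residual: each
marker is re-located inside a ±22 px window (`window`, default the cell
half-width) around its interpolated position.

Within the window the marker is a small (< 1 % of the window area)
high-contrast dark blob. Balanced bimodal split rules (Otsu) fail in exactly
this situation — the between-class variance peaks at a split of the dominant
background mode — so the threshold is the dark-tail midpoint
$q_{0.01} + 0.3\,(q_{0.5} - q_{0.01})$ of the lightly smoothed window
(Gaussian, sd 1 px; symmetric smoothing does not move a blob centroid). The
0.3 weight keeps the threshold below plain background even when bright clone
dots inflate the window median. Selected pixels are restricted to the compact
blob around the darkest pixel; the refined centre is the squared-darkness
weighted centroid, rounded to integer pixels (dots are summed over fixed 9 × 9
blocks, so sub-pixel anchoring would buy nothing). Squared weights halve the
jitter contributed by threshold-edge pixels.

A window with no plausible blob — fewer than 4 selected pixels, or a weighted
spread (mean squared distance) above 20 px², the signature of scattered noise
rather than a compact marker — falls back to the interpolated position and is
flagged. A marker overwhelmed by an adjacent saturating clone's bloom is the
realistic fallback case; the run aborts only if more than `maxFallbackFrac`
(default 5 %) of markers fall back. Positioning accuracy is therefore
specified *for markers that exist as the darkest object in their window*,
which is the printed design of the arrays.

The array is then reconstructed cell by cell: the ±22 px tile around each
refined marker is copied into a fixed 2160 × 2160 mosaic in which dot
$(c, r)$ always occupies the 9 × 9 block at $(9c+1, 9r+1)$. `qcSample`
extracts 6 × 6 evenly spaced cells and checks that the central block is the
darkest of each cell's 25 — the quick visual and programmatic QC for a
mis-anchored grid.

# Background model

Offsets are treated as homogeneous only at the dot level: each dot's offset
estimate is its tile's **minimum pixel**, the intensity of the pixel
expressing no luminance. Two numerical conventions follow from it:

* Subtraction clamps at zero. Intensities are non-negative; the residual
  background after subtracting the minimum is near zero by construction.
* A dot whose signal fills the whole tile has no luminance-free pixel; its
  "offset" is abnormally high. Such offsets are flagged when they deviate
  from their locality median by more than 3 local MADs and are replaced by
  that median. Here the MAD carries the usual 1.4826 normal-consistency
  factor: this is an outlier-*detection* rule calibrated against noise (k = 3
  keeps the false-flag rate of symmetric noise below 1 %), not a reported
  unit. Detection and replacement both read the raw offsets (two passes), so
  repairs cannot cascade. Markers and blanks participate in offset localities
  — offsets describe background, which exists under every dot.

The **locality** is the set of dots within a Euclidean radius measured in dot
units, boundary included: 29 dots at radius 3, 49 at radius 4 (4 and 24 of
which lie outside the centred 5 × 5 cell). Radius 4 is the default — large
enough for stable medians and MADs, small enough that gain is locally
homogeneous; radius 3 remains available via `radius =`.

Each dot is then summed over its entire 9 × 9 tile with no shape mask. Gain
is deliberately *not* estimated: with no reference value only relative gain
exists, and the scoring stage cancels it.

# Null removal by the divergence of the intensity field

A dot carrying signal is a bright, centred blob: the gradient of the
intensity field converges into it, i.e. the blob is a **sink**. The sink
score implements this as minus the interior sum of the discrete Laplacian
(the divergence of the gradient) of the Gaussian-smoothed (sd 1 px),
background-subtracted tile — running on the subtracted image keeps the smooth
background's own curvature out of the score. The operator is linear: flat
tiles score 0, bright blobs positive, dark (marker-like) blobs negative with
equal magnitude, and the classification is invariant under affine intensity
maps when the threshold is automatic.

Markers are classed by known position. The automatic blank threshold is
`median − 2 × MAD` over all non-marker sink scores; it errors out (suggesting
an absolute `tau`) when the score MAD is zero, as on degenerate constant
images. The rule is deliberately conservative on real-looking data: weakly
expressing clones in low-gain regions may be classed blank and excluded,
which costs a little locality sample size but never creates a false positive
call. Blank pairing (blanks occur as clone pairs, at most two pairs per cell)
is an array property the generator reproduces, not an algorithm step the
classifier enforces.

# Scoring: the number of MADs from median

For each valid dot $d$ with locality sample $S$ (valid dots only, clipped at
borders, self included — the median is insensitive to self-inclusion):

$$\mathrm{score}(d) = \frac{\mathrm{sum}(d) - \mathrm{median}(S)}
{\mathrm{MAD}_{\mathrm{raw}}(S)},$$

with the **raw** MAD (median of absolute deviations, no 1.4826 factor): the
score's unit *is* the MAD, and rescaling would silently redefine the
conventional threshold of 3. The score is signed — overexpression means
significantly *higher* intensity; negative deviants are not outliers of
interest. Dots with a zero sample MAD are flagged `degenerate`, dots with
fewer than `minSample` (default 9) valid neighbours `sparse`; neither is
scored nor callable. Positives are dots with score **strictly** greater than
the threshold (default 3; a dot at exactly 3 is not called).

Because median and MAD come from the dot's own locality, any locality-wise
affine transform of the sums cancels exactly — the formal content of "local
offset and gain are eliminated", and the property that makes scores
comparable across samples and time points (`stackResults` assembles the long
comparison table). The package tests this directly: global affine maps change
scores by $<10^{-9}$, and a regional ×5 gain block moves locality-interior
spiked-dot scores by far less than 10 % (exactly to floating-point precision
when the block scaling is applied to the stored image, since the transform is
then locality-wise affine; gain applied *before* noise would leave a residual
of order the noise-to-signal ratio).

A clone is **positive** only when both replicate dots are validly scored and
both exceed the threshold; a clone with an unscored replicate is
`unevaluable`, never positive. The shipped pair map pairs the 24 non-marker
positions of each cell point-symmetrically about the marker — a documented
synthetic stand-in for the manufacturer's clone-library pairing, replaceable
by any table with columns `x, y, clone_id, replicate`.

# The synthetic generator

`simulateArray` renders the features the pipeline must survive, each behind a
parameter of `simSpec()` (defaults in parentheses; intensities on the 16-bit
scale):

* smooth background offset surface, 400 ± 150, and gain surface 1 ± 0.3
  (low-order polynomial plus one sinusoid, seeded);
* smooth geometric warp of the print grid, ≤ 3 px (`warpMaxPx`);
* marker dips: multiplicative absorption 0.85 of the local image, Gaussian
  profile sd 2 px — printed black ink over whatever lies beneath;
* clone dots: truncated-Gaussian point spread, sd 1.6 px, truncation radius
  4 px so a dot's emission stays inside its own tile (and tile-corner pixels
  stay pure background — which is what makes flat-background recovery exact);
* basal expression amplitude 6000 ± 25 % per clone, both replicates sharing
  the clone's level;
* 48 signal pairs at amplitude 8000–20000 above basal, plus 2 *strong* pairs
  at 120000 with a wide (sd 3.5 px, radius 8 px) bloom that fills the dot and
  clips at 65535 — the offset-outlier code path;
* blank pairs at regional rates 0.05/0.15 (left/right half), at most two
  pairs per cell;
* Gaussian read noise sd 50 plus mild shot noise (variance 0.5 per intensity
  unit).

One design choice deserves its rationale. Dot sums inherit noise not only
from the 81 summed pixels but, dominantly, from the *tile-minimum offset
estimator*: subtracting the minimum of 81 noisy pixels injects roughly
81 × sd(min) ≈ 2000 units of correlated, right-skewed noise into every dot
sum. If basal expression were modelled i.i.d. (any distribution), the
finite-sample fluctuation of each locality's MAD would put a floor of order
$10^{-3}$ under the probability that a top-of-range basal clone pair crosses
3 MADs — visible as false positive pairs on any realistically sized array.
Real membranes do not behave this way because their bacterial background is
*consistent*: neighbouring dots sample the same expression distribution. The
generator reproduces that stationarity by **stratifying** basal levels across
each cell's 12 pair slots (one level per equal sub-band of the ±25 % range,
randomly permuted, uniform within band). Every locality then sees nearly the
same bounded level distribution, its MAD is stable, and the maximum basal
deviation sits a comfortable margin below 3 MADs. This was designed from the
noise analysis above, not fitted to test outcomes. Residual false positives
survive only where the stationarity breaks — borders and blank-dense
neighbourhoods shrink the valid sample — at a measured rate of order
$10^{-4}$ per pair.

What passing the synthetic tests does **not** show: robustness to scanner
PSF/MTF, to rotation beyond what refinement absorbs, to chemistry artefacts
(speckle, smears), or to real clone-library expression distributions, which
are heavier-tailed than any bounded model — on real data the score histogram
has a long right tail and the fixed threshold is a screening convention, not
a significance statement.

# Problem sizes and defaults

The shipped demo (`demoSpec()`) uses 24 cells per side (120 × 120 dots,
1080 px ROI): every code path — warp, heterogeneous fields, blank regions,
saturating strong pairs, pair validation — on an array that runs end-to-end
in well under a minute. Unit tests use 6–12 cells per side; pure-geometry
checks use the full 240-dot layout, whose constants are exact regardless of
size (the layout is fully parameterised, so small arrays exercise identical
code). `scripts/acceptance.R` recomputes the headline quantities (disc
counts, geometry, marker recovery, background recovery and retention,
invariances, demo precision/recall, MAD-oracle agreement) from scratch at a
caller-chosen seed.

# Known limitations

* Corner coordinates must be supplied; there is no automatic corner finder.
* No sub-pixel dot registration: integer anchoring is part of the summation
  design and costs up to half a pixel of marker accuracy.
* The automatic blank threshold under-calls weak clones in low-gain regions
  (conservative by construction); supply an absolute `tau` to tune.
* One membrane format family: square cells with a centre marker. Hexagonal
  packings, multi-field membranes and multi-page scans are out of scope.
* Scores are screening statistics; no multiplicity correction is applied or
  implied.
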