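---
title: "Spatial-temporal refinement of categorical land-cover rasters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial-temporal refinement of categorical land-cover rasters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdlrefine)
```

## The problem

Annual categorical land-cover rasters such as the USDA Cropland Data Layer
are produced by per-pixel classification of satellite imagery. At 30 m
resolution, pixels that straddle field edges, farm ponds, tree lines or
roads mix several land covers in one footprint and are the dominant source
of misclassification: isolated wrong pixels inside otherwise homogeneous
fields, and speckle along boundaries. Such errors are visually obvious —
a single "corn" pixel in the middle of a lake — because two independent
lines of evidence contradict them: the spatial context (all neighbors
disagree) and the temporal context (the pixel's own multi-year history
disagrees). The filter implemented here corrects a pixel only when both
lines of evidence agree with each other, and leaves it alone otherwise.

## The decision tree

**Spatial evidence.** Each pixel is compared with its eight connected
neighbors (8-connectivity is essential: linear features such as roads and
streams are only one pixel wide and would be destroyed by a 4-connected
rule). Pixels whose full 3×3 window shares one class (*uniform*) need no
investigation. The rest are *isolate* (all 8 neighbors share one other
class), *boundary* (the top neighbor class holds 5–7 positions), or *mix*
(no class reaches 5). Isolate and boundary pixels are candidates; mix
pixels carry too little spatial information and are never altered — they
are the known residual error class of this method, and resolving them
would need external field-boundary data or a different model entirely.

One wording subtlety: the boundary definition speaks of "contiguous"
same-class neighbors. We count same-class neighbors in the ring without
requiring them to be mutually adjacent around it, for two reasons: the
complementary mix definition ("no class with more than four neighbors")
reads as a count criterion, and a plain count is deterministic and easy to
verify against a brute-force oracle. With the count rule the four
categories are mutually exclusive and exhaustive by construction, which
the test suite checks property-style on random rasters. The ring-adjacency
reading would only reclassify a small set of boundary windows as mix —
i.e. make the filter slightly more conservative — and is not implemented.

**Temporal evidence.** For every candidate, the nine preceding annual
layers are reduced to the *dominating historical classification*: the
class appearing in at least 7 of 9 years if it is a constant feature
(water, forest, wetlands, developed — the twelve registry codes), or at
least 5 of 9 years for regular classes under land-use change such as
rotated crops. The asymmetry encodes the assumption that constant features
do not genuinely change — their historical signal should be nearly
unanimous, with a 2-year allowance for historical misclassification —
while crop rotation legitimately fragments the history of farmed pixels.
The regular threshold cannot go below 5: with 9 years, any threshold ≤ 4
would allow two classes to dominate simultaneously, and 5 > 9/2 guarantees
uniqueness. The constructor enforces this (`regular_min > n_years/2`) for
non-default configurations too.

**Decision.** A candidate with neighborhood majority M, historical
dominant D and current class C is rewritten to D when M = D ≠ C; kept when
C = D (the history corroborates the outlier — real ponds in fields look
exactly like this); and discarded (left unchanged) when M ≠ D or no D
exists. The refinement value is always D, which on the rewrite branch is
identical to M; no other value is ever written, a *conservativeness*
invariant the tests assert on random inputs.

**Road post-processing.** Roads fail both evidence channels in a
characteristic way: a road pixel misclassified as crop has crop neighbors
on both sides (M = crop) while its history says developed (D = road), so
it is discarded as a conflict. When an external rasterized road reference
mask is supplied, discarded candidates under the mask whose history shows
at least `road_history_min` (default 3 of 9) developed/road years are
restored to their most frequent historical road code, ties broken toward
the lowest code for determinism. The threshold, the eligible code set
(default: the registry's developed codes 82, 121–124) and mix-pixel
eligibility (default off — the candidate vocabulary belongs to
isolate/boundary pixels) are all configuration, because no published rule
fixes them; 3 of 9 is permissive enough to catch roads whose history is
too noisy for the 7/9 constant rule, yet requires corroboration beyond the
mask alone. Pixels kept because C = D are not road-eligible: evidence that
corroborates the current class should not be overridden.

**Iteration.** Passes are synchronous — every decision in a pass reads the
previous pass's raster — so results are independent of scan order and
bit-reproducible. Neighborhood profiles are recomputed each pass (a
corrected outer pixel can turn its neighbor into a correctable isolate),
but dominance is computed once from the original history and never from
refined output: the year being refined must not contaminate its own
evidence. Iteration stops when a pass changes nothing; a `max_iterations`
cap (default 10) guards against oscillation, which the stopping rule
cannot exclude a priori — a road-step rewrite can in principle re-enable a
spatial-temporal rewrite and vice versa. In practice the synthetic
benchmark converges in 2–4 passes; a result that hits the cap is flagged
(`converged = FALSE`) rather than silently accepted.

## Edge and nodata policy

Border pixels lack a full ring and are excluded (`edge`), not padded:
padding would fabricate observations. Any nodata cell in the 3×3 window
likewise excludes the pixel (`nodata`), because a majority over fewer than
eight neighbors has no defined threshold semantics. In the temporal
direction, a nodata year counts toward no class and does *not* shrink the
denominator — thresholds are absolute counts ("7 of 9"), so a pixel with
only four valid historical years can never dominate. This is the
conservative reading: missing history weakens, never strengthens, the case
for rewriting a pixel. Ties in the neighbor majority return no majority
class; since a tie can reach at most count 4, this never interacts with
the ≥ 5 refinement requirement.

## The synthetic benchmark

`generate_scene()` builds the default study landscape: a 120×120 grid
(14 400 pixels, 30 m cells) of 12-pixel square fields under strict annual
corn/soybean rotation with adjacent fields one year out of phase, two water
ponds and a forest patch (constant), one horizontal and one vertical road
line (constant, with a matching reference mask), nine rectangular zones,
and ten simulated years — nine history layers plus the current year.
`inject_noise()` then flips 1% of interior current-year pixels to a random
wrong class (isolate-type noise), optionally jitters field-edge pixels, and
independently flips 5% of each history layer's pixels, emulating historical
misclassification that dominance must see through. All randomness is
seed-fixed; scene construction itself is deterministic.

The scene sizes were chosen to keep the full test suite in the tens of
seconds while exercising every branch of the decision tree (all six
neighborhood categories, both threshold types, conflicts, the road step,
and multi-pass cascades). What the generator does **not** emulate: spectral
confusion (noise is uniform over wrong codes, while real confusion is
structured), irregular field geometry, gradual land-use change such as
urban expansion, and spatially correlated error patches. Passing the
benchmark therefore demonstrates the filter's logic and its conservatism
guarantees, not the accuracy figures to expect on real imagery-derived
products.

**The rotation parity effect.** A consequence worth stating plainly:
under a *strict* two-year rotation, the current-year crop occupied the
field in only 4 of the 9 preceding years — among any nine consecutive
years, exactly four share parity with the following year — so the
historical dominant of a rotating field pixel is always the *other* crop
and never confirms the current year. Errors injected into such fields are
discarded as conflicts (M = truth ≠ D), not corrected; the filter's
corrections on this scene concentrate in the constant water/forest patches
and on roads. Real rotations are not strictly periodic (continuous corn,
corn-corn-soy and similar sequences are common), which is precisely what
makes the 5-of-9 rule useful in practice. The benchmark keeps the strict
rotation because it is the clean worst case: it demonstrates that where
history cannot corroborate, the filter abstains instead of guessing — at
the cost of leaving rotation-field noise uncorrected. Accordingly, the
recovery criterion is conditioned on *recoverable* pixels
(`recoverable_mask()`): injected errors whose true class equals both the
noisy-raster neighbor majority and the historical dominant. The package
restores 100% of these, alters no clean pixel in a uniform truth
neighborhood, and converges within four passes on this fixture.

A second deliberate artifact: pixels at the corner where four fields meet
sit on an exact 4–4 neighbor split. Injected noise next to such a corner
can tip the balance to 5, and because the adjacent crop is also the
historical dominant (the same parity effect), the filter flips the corner
pixel — a small, bounded "corner erosion" visible as the `damaged` count
in `score_recovery()`. It is a faithful consequence of the decision rules
on a knife-edge geometry, not an implementation artifact; the affected
pixels are never uniform-neighborhood pixels.

## Numerical and format choices

Rasters are exchanged as ESRI ASCII grids: single-band, integer, plain
text, with an explicit nodata tag, and losslessly convertible to and from
GeoTIFF with GDAL. Cell values are validated as integers on read; grid
geometry is a lower-left corner plus square cell size; CRS identity is
checked as a tag string only — reprojection is out of scope and must
happen upstream in GIS tooling. Nearest-neighbor resampling (for reference
masks of mismatched shape) maps each output cell center to the nearest
input cell center using exact integer arithmetic, with equidistant ties
resolved to the lower index; being a nearest rule, it can never invent a
class code. Acreage conversion uses 1 acre = 4046.8564224 m² with a
configurable cell area (default 900 m² for a 30 m grid).

County-level agreement is summarized by the squared Pearson correlation
between paired acreage vectors — the scatter-plot statistic — rather than
R² about the 1:1 line; the identity-line variant, which additionally
penalizes bias, is available via `about_identity = TRUE`. Percentage
differences to a reference are signed and averaged, so over- and
under-estimates can cancel across counties; `absolute = TRUE` gives the
magnitude version.

## Known limitations

* Mix pixels are never corrected; on real products they are the main
  residual error source.
* The method assumes the history stack is co-registered and on the same
  class legend across years; it verifies shape, grid and nodata
  consistency but cannot detect legend drift.
* Strictly periodic rotations are invisible to the 5-of-9 dominance rule
  (parity effect above); such pixels are protected from wrong rewrites but
  cannot be fixed.
* The road step depends entirely on the quality of the supplied mask; the
  rasterization rule that produced it (all-touched vs. center) materially
  affects which pixels are eligible and is the mask producer's choice.
* Oscillation between the road and spatial-temporal branches is possible
  on adversarial inputs; it is bounded by `max_iterations` and reported
  via `converged`, never silently accepted.
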