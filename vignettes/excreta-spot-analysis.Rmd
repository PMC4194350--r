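---
title: "Methods: faecal-spot detection, quantification and group statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: faecal-spot detection, quantification and group statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

excretaScan turns a high-resolution RGB scan of a clear plate bearing
dye-stained fly excreta into (i) a per-deposit table of graphical
variables, (ii) per-plate physiological summaries normalised by fly count,
and (iii) statistical comparisons between user-defined groups of plates.
This vignette documents the model behind each stage, the tunable
parameters and their defaults, the numerical conventions, and what the
bundled synthetic-plate generator does and does not establish about real
data.

# Detection model

## Adaptive local-mean thresholding

Deposits are dye-dark objects on a light background. Transparency
scanners produce smooth, low-frequency background variation (illumination
falloff, plastic tint), which defeats any global threshold; we therefore
binarise each pixel against a local statistic:

> pixel (x, y) is foreground ⇔ grey(x, y) < mean(window centred on (x, y)) − offset

with the greyscale image the luma-weighted channel sum
(0.299, 0.587, 0.114 by default — configurable, e.g. a pure-blue weighting
could be substituted for heavily acidified samples). The local statistic
is the *arithmetic mean* over a square window: the simplest estimator
consistent with compensating smooth background drift, exact and fast via a
summed-area table.

Two properties follow directly and are enforced by tests:

- a uniform image yields no foreground (any positive offset);
- adding a constant to every pixel leaves the binary map unchanged, so
  detection is invariant to global exposure shifts.

**Window** (default 51 px at 1200 dpi): must comfortably exceed the
diameter of typical deposits, otherwise the local mean inside a large spot
is dragged down and its interior drops out; at 1200 dpi deposits are a few
hundred to a few thousand pixels in area (diameters roughly 10–40 px), so
51 px leaves the window majority-background everywhere. **Offset**
(default 0.06 intensity units in [0,1]): larger than the residual local
background fluctuation (a few thousandths on a clean scan), far smaller
than the deposit-background contrast (≈ 0.3–0.6 in luma for blue
deposits). Borders are handled by symmetric reflection padding, which
introduces no artificial intensity step, so image edges generate no
spurious foreground.

One honest limitation: luma-based contrast fades for *light yellow*
deposits (hue < 60°, lightness above ≈ 0.5), where the luma of the spot
approaches the background. Strongly acidified and dilute excreta may need
a lower offset or blue-weighted greyscale conversion; the defaults target
the common blue-to-orange, mid-lightness regime.

## Labelling, hole filling, size filter

Foreground pixels are grouped by 8-connectivity (diagonally touching
pixels are one deposit: the conservative choice for visually continuous
excreta), labelled 1..n in raster order of first pixel. The labelling is a
compiled flood fill; tests cross-check it against an independent
union-find oracle. Enclosed background holes (glare inside dark spots) are
filled per component — defined as background not reachable from the image
border, so open cavities are untouched; the operation is idempotent and
only grows components. Finally an inclusive size filter [40, 50000] px at
1200 dpi removes sub-deposit specks (dust) and oversized structures
(moulding shadows). At other resolutions the default bounds are rescaled
by (dpi/1200)² with a warning; shape features remain resolution-sensitive,
so comparisons should only be drawn between identically processed scans.

Confluent (touching) deposits are a known failure mode. An optional
single-pass morphological opening (disc radius 1, off by default) shaves
pixel-scale bridges before labelling; no split of genuinely merged
deposits is attempted — they surface as single large objects and are the
main reason the manual `include` flag exists (10–20% of detected objects
on real plates can be artefacts of one kind or another).

# Per-deposit variables

- **Position**: centroid, 0-based pixels from the top-left corner,
  x rightward, y downward.
- **Area**: pixel count of the (hole-filled) component.
- **Perimeter**: chain-code arc length of the outer contour, traced
  through border-pixel centres by Moore-neighbour border following —
  1 per axial step, √2 per diagonal step; a closed 10×10 square traces
  4·(10−1) = 36. Components with fewer than 3 distinct border points
  return 0 (such specks are removed by the size filter anyway).
- **Circularity**: 4π·area/perimeter², clamped to [0,1] (discretised
  contours of small compact objects can overshoot 1, e.g. a 3×3 square),
  with the degenerate perimeter-0 case defined as 1.
- **ROD flag**: circularity strictly below the cutoff (default 0.5; a
  value exactly at the cutoff is non-ROD). The cutoff is deliberately
  user-facing: it encodes where the valley of the bimodal shape
  distribution sits for a given prep, and a consistent numerical cutoff
  removes operator bias on "transitional" deposits.
- **Colour**: mean RGB over the pixel set, and the HSL transform *of that
  mean colour* (hue 0–359 integer degrees, S and L in [0,1] full
  precision). We use the hue of the mean rather than a circular mean of
  per-pixel hues: it avoids circular-statistics ambiguity and matches the
  plate-level pooling rule (below) applied to a single object. Achromatic
  colours take H = 0 and S = 0 by convention.
- **IOD**: area × (1 − meanL). Linear in area at fixed lightness,
  decreasing in lightness at fixed area. Its interpretation as dye content
  assumes the scanner has been calibrated so lightness is linear in dye
  concentration — a wet-lab responsibility the software cannot check.

## The chain-code perimeter bias

The chain-code metric is the standard contour arc length of binary image
analysis, but it is *biased upward* on smooth shapes: a digital straight
line at angle θ costs cosθ + (√2−1)sinθ per unit length, which averages
≈ 1.055 over an octant. A rasterised disc therefore measures a perimeter
about 5% above 2πr, and its circularity plateaus near 0.90 rather than
converging to 1 — only the *analytic* circle attains exactly 1. The value
is also not monotone in radius (rasterisation jitter). This bias is
harmless for classification — both deposit classes shift together, and the
round/oblong classes sit at ≈ 0.9 vs ≈ 0.4, far either side of the 0.5
cutoff — but it means measured circularities should be compared only
between identically processed images, never against analytic values. We
keep the convention because it is the field's standard and any smoothed
(unbiased) estimator would break the exact small-shape identities (square
= 36) that make the implementation testable.

# Plate summaries

Within one plate, for the whole deposit set and the ROD / non-ROD subsets
separately (only `include = TRUE` rows):

- totals — spot count, area, IOD — divided by the user-entered fly count;
- unweighted arithmetic means of area, perimeter, circularity;
- pooled colour: the mean over the union of all spot pixels, i.e. the
  colour of the single merged object. This is *exactly* the area-weighted
  mean of the per-deposit mean colours, which is how it is computed — so
  an exported deposit table is sufficient to re-derive every summary value
  (the basis of the curation workflow).

Empty subsets report zero totals and *missing* means (never zeros), so
downstream statistics skip them instead of being biased toward zero. The
ROD fraction n_rod/n_all is attached to the `all` row. The summary also
records filename, timestamp and a one-line detection-parameter snapshot,
as part of the audit contract.

# Group statistics

The unit of replication is the plate. Descriptives (mean, sample SD,
median, min, max) and pairwise two-sample tests are computed per selected
plate-level variable:

- **Student's t** (pooled variance, df = n₁+n₂−2) is the default
  parametric test, as named; Welch's form is available behind a flag.
  Degenerate inputs are resolved explicitly (two constant equal samples:
  t = 0, p = 1; constant unequal: ±∞, p = 0).
- **Mann–Whitney U** is the non-parametric alternative. U counts pairs won
  by the first group (ties half), so U₁+U₂ = n₁n₂. The two-sided p is
  exact by enumeration when n₁+n₂ ≤ 16 without ties — enumeration is cheap
  at the 6–8 plates per group typical of these assays — and otherwise uses
  the normal approximation with tie and continuity corrections.
- **Jarque–Bera** (JB = n/6·(S² + (K−3)²/4), biased moments, asymptotic
  χ²(2) p-value) is reported per group as *guidance* for choosing between
  the two tests; it never switches the test automatically. Below n = 30
  the asymptotic law is unreliable and a `small_sample` flag is set — at
  realistic plate counts the flag is essentially always on, which is the
  honest state of affairs. (The original small-sample table interpolation
  of some libraries is not reproduced; the χ²(2) law is the documented
  asymptotic choice.)
- **Holm–Bonferroni** is applied across the family formed by *all*
  comparisons requested in one call — that is what controls the
  familywise error rate of the analysis actually run. The correction is
  skippable (`correct = FALSE`), which is the right choice when the
  scientific claim is a *lack* of effect and Type II errors are the
  danger.

# The synthetic-plate generator

`generatePlate()` draws, from a seeded private RNG stream (the caller's
stream is untouched, and output is bit-identical per seed):

- a background at base intensity 0.88 with a ±0.04 smooth sinusoidal
  gradient — enough spatial drift that a global threshold would misbehave
  while the local-mean rule is unaffected;
- round deposits: hard-edged discs, radius 6–14 px, lightness 0.35–0.55;
- oblong deposits (the ROD class): capsules of width 7–11 px and aspect
  ratio 5.5–7.5, darker (lightness 0.15–0.30) to mimic concentrated
  deposits. The aspect range was fixed analytically before any testing: a
  capsule of aspect a has circularity 4π((a−1)+π/4)/(2(a−1)+π)² ≈ 0.45 at
  a = 5.5, and the chain-code bias pushes measured values lower, so the
  class sits safely below the 0.5 cutoff while discs sit near 0.9 — a
  bimodal distribution with a wide empty valley, as on real plates;
- hue 210–250° (blue, neutral pH) for both classes by default, saturation
  0.55–0.80; acidified plates can be emulated by setting hue ranges below
  60°;
- 12 artefact specks of radius 1–2 px (area ≤ 13 px, below the 40 px
  size-filter minimum);
- rejection-sampled placement with a 4 px margin between bounding circles
  (non-overlapping by default; a capacity error after 10⁴ attempts).

`scoreDetection()` matches a truth spot when exactly one detected centroid
falls in its footprint, and reports recall, precision and ROD-class
accuracy.

**What passing these tests shows — and does not.** The generator
establishes that the pipeline is correct on its own terms: geometry,
colour arithmetic, classification, aggregation, determinism. It does *not*
model anti-aliased or diffuse deposit edges, partial transparency,
overlapping or confluent excreta, scanner noise, dust, or plate moulding
shadows. Real plates will show lower precision (hence the curation
workflow) and boundary-pixel effects on colour; validation figures from
synthetic plates (recall/precision/ROD accuracy near 1) are upper bounds,
consistent with, but not a substitute for, the >95% manual-annotation
agreement reported for the assay on real female plates.

# Batch processing, store and determinism

The experiment store is one directory per experiment — `config.csv`,
`deposits_<plate>.csv` (editable `include` column), `summaries.csv`,
`audit.csv` — replacing a database backend with diff-able files while
keeping the same hierarchy. Batch results are keyed and written sorted by
plate id, so the store's data content is independent of configuration
order; one audit entry is written per processing *attempt* (failures are
recorded, not fatal). The analysis pipeline is entirely seed-free:
identical inputs and parameters give byte-identical deposit CSVs across
re-runs. Wall-clock state exists only in the `timestamp` columns of the
summary table and the audit trail — it is audit metadata, deliberately
excluded from the determinism contract.

The GUI curation loop is replaced headlessly: edit `include` flags in the
exported deposit CSV, then `resummarizeExperiment()` recomputes summaries
from the tables alone (possible because pooled colour is recoverable from
per-deposit means — see above) and appends audit entries.

# Problem sizes used in the test-suite

Unit and property tests run on small fixtures (≤ 64×64 oracle images,
420×420 synthetic plates with 10 deposits). The end-to-end acceptance
checks use 20 seeded 1000×1000 plates of 60 deposits each (~1200 scored
deposits), 1000-replicate null calibration of the t-test at n = 8 per
group, and 200 replicates of n = 5000 for the Jarque–Bera size check —
sizes chosen to give stable statistics in well under a minute each on one
CPU.

# Known limitations

- No splitting of merged/confluent deposits; they must be excluded (or
  accepted) manually.
- Luma contrast fades for light yellow deposits; adjust offset or
  greyscale weights for heavily acidified samples.
- Circularity values are pipeline-specific (chain-code bias): compare
  within, not across, processing pipelines.
- IOD assumes lightness–dye linearity, which is a scanner calibration
  property the software cannot verify.
- Jarque–Bera guidance is weak at realistic plate counts (n < 30); choose
  the test on substantive grounds when in doubt.
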