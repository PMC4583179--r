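---
title: "Fuzzy rule-based edge detection: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fuzzy rule-based edge detection: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuzzedge)
```

## The model

`fuzzedge` detects edges with a Mamdani fuzzy inference system over the 3×3
neighbourhood of each pixel. The inputs are the eight absolute differences
ΔPj = |Pj − P| between the centre pixel and its neighbours, indexed
row-major (P1=NW, P2=N, P3=NE, P4=W, P5=E, P6=SW, P7=S, P8=SE). Each
difference is graded by two trapezoidal fuzzy sets on [0, 255]:

| set    | trapezoid (r, s, t, u) | meaning                          |
|--------|------------------------|----------------------------------|
| Lower  | (0, 0, 25, 75)         | the neighbour matches the centre |
| Higher | (25, 75, 255, 255)     | strong local contrast            |

A difference of 25 or less is unambiguously *Lower*; 75 or more is
unambiguously *Higher*; between the two the memberships cross linearly at
50. The knowledge base holds twelve rules, all with consequent *Edge*. Each
combines one of four adjacent *Higher* pairs — (ΔP1, ΔP2), (ΔP1, ΔP4),
(ΔP2, ΔP3), (ΔP4, ΔP6) — with a single *Lower* difference on the far side
of the mask (ΔP8, ΔP7 or ΔP5). The pairs are directional templates: a real
edge produces strong contrast on one side of the mask *and* at least one
quiet direction, whereas an impulse produces strong contrast everywhere.
That asymmetry — every rule needs a quiet direction — is the entire
noise-robustness mechanism, and it is checked directly by the impulse tests.

Inference is standard Mamdani: rule strength is the min over its
antecedent memberships (don't-care inputs do not participate), strengths
aggregate by max per consequent, and each output set is clipped at its
aggregate strength. The output axis carries two Gaussian sets, NonEdge
(m = 10, d = 3.5) and Edge (m = 245, d = 3.5) — Gaussians because they are
smooth and non-zero over the whole working range of the score, which keeps
the centroid well defined at every strength combination. Because the
knowledge base states no non-edge rules, an implicit else routes
`1 − max(strengths)` to NonEdge, guaranteeing a non-empty aggregate and a
score that varies continuously from ~10 (quiet neighbourhood) to ~245
(saturated edge template). The crisp score is the discrete centroid
c = Σ qx·zx / Σ qx over the output universe, and a pixel is flagged when
c ≥ 127.5, the natural symmetric cut at the midpoint of the two output
centres.

## Numerical choices

* **Universe resolution.** The centroid is computed on 512 evenly spaced
  samples of [0, 255]. At 256 samples the worst-case discretization error
  against a 10×-denser centroid measures 0.80 grey level (the clipped
  Gaussians have near-flat plateaus whose edges quantize at O(h)); at 512
  samples it is 0.27, inside the half-grey tolerance our oracle tests
  demand, while a 314×192 image still scores in about three seconds. The
  resolution is config-exposed.
* **Ties at the threshold.** The sample grid is symmetric about 127.5, so a
  neighbourhood whose best rule fires at exactly 0.5 (a 50-grey-level
  contrast) defuzzifies to exactly 127.5 in exact arithmetic. Scores within
  1e-9 of the threshold count as at-threshold and are flagged, making the
  binarization deterministic under floating-point summation order.
* **Degenerate trapezoids.** Vertical flanks (r = s or t = u) evaluate as
  step functions rather than dividing by zero. Below r the degree is 0 even
  when r = s; clamping to the universe — which maps out-of-range inputs to
  the boundary degree — happens at the fuzzy-set level, not in the raw
  membership function.
* **Gaussian tails.** Mathematically the output Gaussians are positive
  everywhere; in double precision their far tails underflow to exactly 0
  (already at ~180 grey levels from the centre for d = 3.5). Nothing in
  the pipeline depends on strict positivity.
* **Border policy.** The outermost 1-pixel frame is never flagged: the mask
  is undefined there and padding would fabricate edges. Edge-map
  constructors enforce this, so evaluation metrics are border-consistent
  across detectors.
* **Contrast rounding.** The contrast stage rounds its defuzzified output
  to the nearest integer grey level with ties to even (base R `round`).

## The contrast pre-stage

Smooth clinical images carry edges of 30–40 grey levels, below the 50-level
midpoint of the Higher membership, so the detector alone responds weakly or
not at all. The pre-stage maps every pixel through a three-rule Mamdani
system (Darker→Darkest, Grey→Grey, Brighter→Brightest). Its default
membership parameters are this package's own choice:

* input: Darker = trapezoid (0, 0, 80, 127), Grey = (105, 124, 131, 150),
  Brighter = (128, 175, 255, 255);
* output: Darkest = Gaussian(5, 20), Grey = Gaussian(127.5, 20),
  Brightest = Gaussian(250, 20).

They were chosen once, from the induced transfer function: symmetric about
mid-grey (so mid-grey is a fixed point and the transfer is unbiased),
monotone non-decreasing at every grey level, and expanding a 110/145 step
to roughly 84/171 — comfortably past the Higher midpoint, so a
low-amplitude boundary becomes detectable after intensification. A first
candidate with a wider Grey input set (plateau spanning 120–135) produced
an m-shaped transfer that *compressed* mid-range contrast to 34 levels and
defeated the stage's purpose; the narrower Grey set fixes that.
Intensification is inherently compressive in the dark and bright plateaus:
an image confined to [0, 80] maps almost entirely to the Darkest centre.
The expansion guarantee applies to ranges straddling mid-grey.

## Noise model and calibration

Salt-and-pepper corruption flips each pixel independently with probability
p to 0 or 255 (equal odds). MSE is the plain mean of squared differences
and PSNR is 10·log10(255²/MSE) for 8-bit data. Noise level is specified as a
target PSNR in dB and realized by bisection on p: every probe reuses the
same seed, so the corrupted set grows monotonically with p and the realized
PSNR is monotone along the bisection path. Default tolerance is 0.25 dB;
targets below the PSNR of full corruption are rejected as non-bracketable.

## Baselines

Sobel, Prewitt and Roberts convolve with the standard kernel pairs
(Roberts' 2×2 crosses embedded in a 3×3 frame) and threshold the gradient
magnitude by Otsu's method on its histogram — an automatic, parameter-free
policy is the fairest default for cross-detector comparisons, and the
policy in force is logged in every report. LoG smooths at
sigma = 2, applies the 4-neighbour Laplacian and gates zero-crossings at a
tenth of the maximum crossing slope. Canny (sigma = 1, hysteresis fractions
0.1/0.2) uses non-maximum suppression quantized to four directions, strict
on the forward neighbour so plateau ties thin to a single pixel, and keeps
weak components that touch a strong pixel (8-connected). Two numerical
guards matter: Gaussian smoothing uses replicate (not circular) boundary
handling, since wrap-around fabricates frame edges on any image whose
opposite borders differ; and FFT-backed convolution leaves ~1e-12 residue
on flat regions, so responses below 1e-6 are treated as exactly zero.

## Synthetic fixtures and what they do (not) show

All experiments run on generated images with analytic ground truth:

* `makeRainbow()` — 314×192, five horizontal stripes (levels 30, 80, 130,
  55, 105) centred on a 200-level background: six interfaces, with
  contrasts 170/50/50/75/50/95. The 50-contrast interfaces exercise the
  exact membership midpoint.
* `makeStep()`, `makeUniform()`, `makeCheckerboard()` — closed-form
  geometries for the invariance suite.
* `makeSmoothPhantom()` — 270×290, a uniform 110 background with three
  soft-edged blobs of amplitude 35: a low-contrast stand-in for a smooth
  clinical slice, sized and levelled to the regime the contrast stage
  exists for.

Truth maps mark *both* sides of every intensity interface, while the
detector, whose rule templates are one-sided, flags the side whose N/W-ward
neighbours differ. Against a two-sided truth its pixel-wise sensitivity
therefore sits near 50% by construction even when every boundary is found;
specificity and false-edge counts are the discriminating metrics, and
component counts confirm completeness of the boundary set. These fixtures
emulate piecewise-constant anatomy with impulse noise; they do not contain
texture, partial-volume gradients, bias fields or correlated noise, so
passing results here demonstrate the mechanism, not clinical performance.

## Problem sizes

The shipped tests and the acceptance script run the full 314×192 band
fixture (once clean, and at 25 dB for five seeds in the robustness
ordering test), 512×512 uniform images for the binomial and calibration
checks, and 16–32 pixel squares wherever a brute-force per-pixel oracle is
the comparison. These sizes keep every individual check in the seconds
range while leaving the binomial statistics tight (3-sigma on n = 262144).

## Known limitations

* The rule base is directionally asymmetric (its Higher pairs favour the
  NW/W quadrant), so mirroring an image changes individual flags unless the
  neighbour convention is mirrored with it; the property tests do exactly
  that. The asymmetry is a property of the rule table itself.
* Edge maps are unthinned and unlinked: no non-maximum suppression or
  hysteresis is applied to the fuzzy score field.
* Sensitivity of the one-sided detector against two-sided truth saturates
  near 50% (see above); a ±1-pixel tolerance band is available in
  `falseEdgeCount()` but is off by default.
* The 24/25 dB calibration targets and the 512×512 / 270×290 / 314×192
  geometries define the study conditions the harness runs under; absolute
  false-edge counts depend on the underlying image content, so across
  different images they are comparable only in ordering and magnitude, not
  count for count.
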