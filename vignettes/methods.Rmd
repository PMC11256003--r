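---
title: "Methods: phantom-based sensitivity assessment and its design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phantom-based sensitivity assessment and its design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmisense)
```

## The measurement problem

A fluorescence imaging system's "sensitivity" is usually reported as an SNR
or a contrast measured on a phantom, but both quantities are families of
formulas, and both depend on where the background is taken. This package
operationalizes one widely used protocol — nine identical fluorescent wells
buried at increasing depth (0.2, 0.4, 0.6, 0.8, 1.0, 1.33, 1.66, 2.0,
3.0 mm) below a scattering, absorbing matrix — and computes *all* the common
variants side by side, because the choice among them changes not only the
numbers but the ordering of systems.

Two background definitions are carried through everything:

* **b1** — a concentric annulus around each well, outer radius 40% larger
  than the well radius. It sits where fluorescence leaks out of the well, so
  it measures background *including* local signal spill.
* **b2** — a well-sized disk far from all wells, unaffected by leakage.

## Pipeline model and assumptions

**Well localization.** The image is binarized with Otsu's threshold and
well candidates are found by a circular Hough transform on the mask
boundary. Deep wells are routinely too dim to cross the threshold; this is
expected, not an error. The design template (well layout in arbitrary
design units) is then registered onto the detections with a similarity
transform (scale, rotation, translation) fitted by closed-form least
squares on mutually-nearest matches; the final well set is *entirely*
template geometry — nine wells, one common radius — so per-well intensity
differences cannot distort the ROI geometry.

A subtlety the tests pin down: a 3 × 3 grid detected only partially can be
translation-ambiguous (a five-well "L" matches the template in two lattice
positions). The registration resolves ties physically: detected wells must
be the shallow, bright ones, so among equal-inlier hypotheses the one
matching the shallowest template wells wins. This makes registration
deterministic and invariant to which subset (≥ 3) of wells was detected.

**Rotation** is fitted by default but can be constrained to zero
(`allow_rotation = FALSE`); phantom images are usually roughly axis-aligned
and the constraint stabilizes the fit for very sparse detections.

**ROI construction.** Pixel membership is by pixel-center coordinates
(0-based, inclusive `|p − c| ≤ r`), which makes mask areas testable against
analytic disk/annulus areas (they agree within 2% at the radii used).
Overlap policy: annulus pixels inside any other well's disk are removed, and
pixels shared by two annuli are dropped from both. The background of one
well must never double-count a neighbor's signal; this choice is recorded in
every report's provenance block.

**Statistics.** The per-ROI standard deviation is the *population* form
(divisor n) by default: ROIs contain hundreds of pixels, so the distinction
from the sample form is negligible, and the population form matches common
imaging practice. A `std = "sample"` switch exists, and the convention used
is stamped into the provenance.

**Raw counts only.** All metrics are computed on raw camera counts.
Display-normalized images would silently corrupt SNR₁ and SNR₂, which are
scale-dependent (they grow as √k under intensity scaling k, while SNR₃,
SNR₄ and both contrasts are scale-invariant — property-tested). Saturated
pixels are retained but counted per ROI and reported.

**Dark frames.** If a dark image (excitation off) is supplied, it is
subtracted pixel-wise with clipping at zero before analysis, and the result
is flagged; whether dark correction was applied is part of every report
because SNR₁'s photon proxy (below) depends on it.

## Metric definitions and numerical choices

All SNR values are in dB with the amplitude convention 20·log₁₀. This is
forced by the detection-limit pairing: a signal twofold the noise must equal
6 dB, and 20·log₁₀(2) = 6.02.

* **SNR₁ = √n.** The photon count n is proxied by the (dark-corrected) mean
  well intensity in counts; no camera gain calibration is attempted, and the
  proxy is recorded in provenance. Without gain, SNR₁ comparisons across
  systems reflect count scales, not absolute photon statistics — a known
  limitation of this variant, and part of why variants disagree.
* **SNR₂.** The typeset form of this family is ambiguous between
  S/√(S + N) and S/(S + N). The default is S/√(S + N): it is the standard
  photon-limited signal-plus-background form and keeps SNR₂ on a scale
  comparable to SNR₁. Both interpretations are implemented
  (`snr2_interpretation = "shot"` / `"ratio"`), and the active one is
  stamped into provenance.
* **SNR₃ = (μ_S − μ_N)/σ_S**, **SNR₄ = (μ_S − μ_N)/σ_N.** A background
  brighter than the signal gives a negative linear ratio; in dB this is
  reported as the explicit non-detect sentinel (−Inf) rather than NaN, so
  plots and scoring have bounded, deliberate semantics. σ = 0 (possible
  only on degenerate, e.g. noise-free synthetic, data) is an error, not a
  sentinel: it means the formula's denominator does not exist.
* **Michelson C_M = (I_max − I_min)/(I_max + I_min)** and **Weber
  C_W = (I_s − I_b)/I_b** use the maximum well pixel and the minimum
  background pixel. When both extremes come from the same pair, the
  algebraic identity C_W = 2·C_M/(1 − C_M) holds and is verified
  numerically in the tests.

## Benchmark scoring

Assuming normal signal statistics, a measurement reaches 95% confidence
when the signal is twofold the noise; that fixes reference values of 6 dB
(SNR), 1/3 (Michelson) and 1 (Weber). Each variant's nine per-well values
are compared with their reference through the symmetric mean absolute
percentage error, with two conventions worth stating:

* **sMAPE for SNR uses the dB scale**, because the reference is stated in
  dB and per-depth results are conventionally plotted in dB. The linear
  alternative would change the numbers; the choice is logged.
* **Non-detect sentinels enter sMAPE as Xᵢ = 0**, contributing the maximal
  term 1 — bounded and pessimistic rather than silently dropped.
* **BM = (sMAPE_SNR + sMAPE_contrast)/N with N = 2**: the sMAPE already
  averages over the n = 9 wells, and each BM cell combines exactly one SNR
  and one contrast variant, so N is the number of metrics combined.

**Ranking convention.** Within each of the 28 cells, systems are ranked by
BM score with rank K = best assigned to the *highest* score by default. The
references are detection-limit values, so for systems operating above
threshold a larger deviation from them reflects greater sensitivity.
Whether "larger BM is better" is, however, genuinely convention-dependent
(systems below threshold also deviate), so the package treats it as a
configuration switch (`higher_is_better`) rather than a fact; ties are
broken lexicographically by system id and flagged.

## The synthetic world

The generator exists so every stage of the pipeline can be exercised and
tested against ground truth. It renders each well as a disk of amplitude
A₀·exp(−μ·depth) convolved with a Gaussian of σ = σ₀ + s·depth over a
uniform background, then applies Poisson shot noise on photon counts,
Gaussian read noise, clipping and integer quantization to the camera bit
depth. Defaults (chosen once, stated here, not tuned): background 500
counts and peak A₀ = 20000 counts for 16-bit cameras (a bright but
unsaturated exposure), μ = 1 mm⁻¹ (the deepest 3 mm well keeps ≈ 5% of the
surface amplitude — a dynamic range that spans "obvious" to "near
threshold"), σ₀ = 1 px growing by 1.5 px/mm, unit photon gain, 10 counts
read noise. The 8-bit preset uses a 20-count black level (≈ 8% of range,
typical of consumer sensors; a near-zero black level would make the minimum
background pixel zero and Weber contrast undefined) and peak 180 counts.
Six presets mirror a realistic camera suite's bit depths (one 8-bit, five
16-bit) and sensor formats, scaled down by a recorded factor (default ÷4)
so the full suite renders in seconds.

What the generator does *not* emulate: real tissue optics (no diffusion
model — a single effective attenuation), autofluorescence gradients,
vignetting or flat-field structure, spatially correlated noise, and
camera-specific gain/offset maps. A green synthetic test therefore
establishes that the *pipeline* is correct (geometry recovery, formula
implementation, scoring, ranking, determinism), not that any physical
system has a particular sensitivity. Determinism is per-configuration: a
config's seed drives a locally scoped RNG, so identical (template, config)
pairs give bit-identical images regardless of surrounding R code.

## Degenerate inputs and edge behavior

* Constant images have no Otsu threshold (degenerate histogram — error).
* Otsu uses a 256-bin histogram for any bit depth; 16-bit data are binned
  for thresholding only and the returned threshold is mapped back to raw
  counts. Ties take the lowest qualifying threshold.
* An empty binary mask yields zero detected circles (not an error);
  registration needs ≥ 3 matched circles and enforces an RMS-residual bound
  (default 25% of the well pitch) as a registration-quality gate.
* A failing system in a multi-system run is logged and skipped; ranking
  proceeds if at least two systems survive.

## Known limitations

* SNR₁'s photon proxy ignores camera gain; absolute SNR₁ values are only
  comparable within a system, not across detector technologies.
* The b1/b2 placement comes from the design template; for real phantom
  images the template (including the b2 location) must be set to the
  physical phantom's drawing via the YAML interface.
* TIFF support covers the baseline uncompressed 8/16-bit formats cameras
  typically export (and is cross-validated against an independent reader in
  the tests); compressed TIFFs must be converted first. PNG is read at
  8/16 bit but written at 8 bit only.
* Repeatability/error analysis across repeated acquisitions is out of
  scope: the pipeline quantifies single images.
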