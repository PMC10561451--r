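---
title: "Methods: foci-based high-content screening with fociscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: foci-based high-content screening with fociscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fociscreen)
```

## The assay and what the package computes

DNA double-strand breaks (DSBs) recruit 53BP1, which switches from a diffuse
intranuclear distribution to discrete foci at damage sites. In an
EGFP-53BP1 reporter cardiomyocyte line, foci are directly visible in the
green channel, so the per-cell focus count — and, at the well level, the
fraction of cells that are "foci-positive" — is a quantitative readout of
DSB burden. Doxorubicin (DOX) induces foci dose- and time-dependently;
compounds that suppress the DOX-induced increase are candidate
cardioprotectants. `fociscreen` implements the complete desk-scale analysis
chain for such a screen:

1. **synthetic data** — a two-channel microscope emulator with exact ground
   truth;
2. **segmentation** — nucleus instance detection and single-cell crop
   extraction;
3. **foci quantification** — threshold-based (granularity-style) per-cell
   focus counting;
4. **classification** — a trainable three-class phenotype classifier
   (foci-positive / foci-negative / non-signaling);
5. **screen statistics** — % foci-positive well summaries, robust percent
   of samples (RPS) plate normalization, replicate aggregation, hit
   ranking, 4PL IC50 fitting, and Mann-Whitney QC.

Two readouts coexist deliberately: the classical threshold backend reports
*mean foci per evaluable cell*, the classifier backend reports *% foci-positive
cells*, defined as `100 * n_pos / (n_pos + n_neg)`; non-signaling cells
(no detectable reporter) never enter the denominator.

## The generator defines the study conditions

The generator is not a fixture factory; it is the package's model of the
assay, and its defaults are the conditions under which every quantitative
claim in the test suite is evaluated.

* **Geometry.** 1024 x 1024 px fields at 0.325 um/px (a typical 40x
  objective sampling), ~150 nuclei per field (Poisson), nucleus radius
  18 +/- 3 px (~12 um diameter), non-overlapping by rejection sampling. A
  `touching` stress flag plants tangent pairs to exercise watershed
  splitting.
* **Brightness heterogeneity.** Per-nucleus nuclear-stain gain is uniform
  on [0.3, 1.0]; per-cell reporter expression is log-normal
  (meanlog 0, sdlog 0.5) with a point mass `p_nonsignal = 0.1` at zero.
  The paper-scale observation this emulates is that green brightness
  varies strongly between cells and is undetectable in some; the actual
  non-signaling fraction of the cell line is not published, so 0.1 is a
  declared free parameter, not a measured value.
* **Dose law.** Mean foci per signaling cell follows a saturating
  hyperbola, `mu(d, e) = lambda0 + (1 - e) * (lambda_max - lambda0) *
  d / (d + ec50)`, with Poisson per-cell counts;
  `lambda0 = 1`, `lambda_max = 10`, `ec50 = 0.25 uM`. Only monotone
  dose/time trends are known for the real assay, so the functional form is
  a modeling choice: the simplest saturating monotone law with realistic
  (Poisson) cell-to-cell variance. At the screening condition (0.5 uM DOX)
  it gives ~7 foci per signaling cell, i.e. ~83% foci-positive wells
  against ~0.4% in controls — a wide, realistic assay window. A compound's
  activity is a fractional suppression `e` of the dose-induced increment.
* **Rendering and noise.** Nuclei are soft-edged disks; foci are Gaussian
  spots (sigma 2 px) with amplitude 3x the cell's own diffuse green level
  (15% log-normal jitter), planted uniformly in the inner 75% of the
  nucleus. The camera model is Poisson photon noise plus Gaussian read
  noise (sd 10) over a 200-count background, clipped to 16 bits. A
  `focus_min_separation` option builds well-separated benchmark crops for
  counting validation; the default (0) allows overlapping foci as in real
  damage patterns.
* **Screens.** 96-well plates with 4 control and 4 DOX wells each and 88
  compound wells; 315 compounds thus occupy 4 plates per replicate, 3
  replicates (the 48 control wells per screen are consistent with the
  scale of published control-well counts). Fast mode draws per-well true
  cell records directly from the statistical law — no pixels — so a whole
  screen simulates in seconds while retaining exactly the sampling noise
  of a finite cell count (~600 cells/well by default). Image mode renders
  every field. The mode is recorded in provenance.
* **Determinism.** Everything is a pure function of (config, seed). Child
  seeds derive from a counter scheme, `(s * 48271 + k) mod (2^31 - 1) + 1`,
  so wells and fields are individually reproducible.

What the generator does *not* model: optics (PSF), 3-D structure,
photobleaching, cytoplasmic signal, uneven illumination beyond an optional
low-order background gradient, and segmentation-confusable debris. Tests
passing against this generator therefore demonstrate the pipeline's
correctness under controlled conditions and its robustness to the modeled
variation (brightness, expression, noise) — not performance on real
microscope exports.

## Segmentation

The published pipeline used a trained U-Net whose weights are not
available; `fociscreen` substitutes a deterministic classical pipeline with
the same contract, chosen because the binding requirement is robustness to
per-nucleus staining brightness, which locally normalized thresholding
provides without any training artifact: Gaussian smoothing (sigma 2) →
adaptive mean thresholding (window ~1.5x nucleus radius, offset 0.01 of
full scale) → hole filling → opening → distance-transform watershed
(tolerance 2) → area filter (nucleus radius mean +/- 3 sd, i.e.
~250–2400 px²). Coordinates are 1-based (row, col) matrices, the R
convention. Border-touching nuclei are excluded from crop extraction by
default because their truncated masks bias both counts and classes; the
policy is configurable.

Measured on 20 default fields, object-level F1 (5 px match radius) is
~0.97; the residual errors are border-clipped nuclei whose visible-part
centroid legitimately moves away from the planted center.

Crop normalization maps the green channel to [0, 1] by within-crop
percentiles (1 and 99.5 by default): `g' = clip((g - v_low) /
(v_high - v_low), 0, 1)`. Percentile anchoring is exactly equivariant under
affine intensity transforms, which is the mechanism that makes downstream
analysis insensitive to reporter brightness. A crop with anchor spread
below `eps` is zeroed and flagged `low_dynamic_range`; the raw green mean
and the anchors are kept so absolute signal presence remains measurable.

## Foci counting

The threshold backend mirrors granularity-style analysis: white top-hat
with a disk of radius `ceiling(d_max / 2)` isolates structures smaller
than a focus diameter upper bound; the detection threshold is
`median + k * 1.4826 * MAD` of the top-hat response inside the nucleus
(robust statistics, so bright foci cannot inflate their own cutoff), with
an absolute prominence floor (0.1 normalized units) that keeps the
MAD-based cutoff meaningful on nearly noise-free crops. Local maxima are
accepted greedily (strongest first, row-major tie-break) at
`min_separation = 3 px`. Clipped foci form flat tops; maxima tied within
`plateau_tolerance = 1e-3` are collapsed to one detection per connected
plateau. The software defaults (`d_min = 3`, `d_max = 9`, `k = 4`) derive
from the generator's focus width because the original analysis-software
parameter values are unpublished; all are exposed in `foci_params()`.

Cells flagged `low_dynamic_range` return `not_evaluable` rather than a
zero count — deciding that a cell is non-signaling is the classifier's
job. Well means are over evaluable cells only, and a well with none gets a
missing value, never 0. Whether the published per-cell averages included
zero-green cells is unstated; excluding them is this package's documented
choice.

## Classification

Truth labels: zero expression → `non_signaling`; otherwise foci-positive
iff the true focus count reaches `positivity_threshold` (default 5). The
threshold is the single largest unconstrained choice in the system — no
published value exists — so it is a configuration value carried in model
provenance rather than a constant.

The default backend (`feature_baseline`) is weighted multinomial logistic
regression on a fixed 13-feature vector (signal presence, texture,
top-hat energy, embedded threshold counts, a 3-scale granularity spectrum,
mask area). Two design points matter:

* The two raw-intensity features (`raw_green_mean`, `anchor_spread`) scale
  with reporter gain, so the backend excludes them from its design matrix
  and judges signal presence by noise-referenced log-SNR contrasts, which
  are scale-invariant. This is what makes classification agree at the
  99-100% level when a crop's green channel is scaled by 0.5-2x.
* Class imbalance is handled by weights inversely proportional to class
  support, because non-signaling cells may be rare.

Training is deterministic (identical data → identical coefficients) and
takes seconds on ~3,000 crops. A second backend (`nnet_pixels`, a
single-hidden-layer network on the 16 x 16 mean-pooled normalized green
channel) provides a pixel-level learner under the same contract; it is
stochastic in initialization and less accurate at small training sizes,
and is not the default. Ties on equal probabilities resolve in the fixed
class order non_signaling < foci_negative < foci_positive. "Macro
accuracy" throughout is mean per-class recall (balanced accuracy).

## Screen statistics

* **RPS.** `RPS_i = 100 * S_i / median(S)` with the median over the
  *compound wells* of the same plate; control and DOX wells are excluded
  from the median on the reading that they are not compounds. Per-plate
  median RPS is exactly 100 by construction. A zero plate median is an
  error, not an NA.
* **Ranking.** Per-compound mean RPS over available replicates (count
  recorded; a compound missing from a replicate keeps its other
  replicates rather than being dropped), ascending rank, ties broken by
  compound id so ranking is deterministic; the 12 lowest-mean-RPS
  compounds are selected by default.
* **QC.** ECDF of mean RPS; fixed-width (10 RPS units) histograms of
  per-well RPS for control versus selected-compound wells; a Mann-Whitney
  comparison between the two groups. The U statistic counts pairs
  `x_i > y_j` with half-weight for ties; p-values are exact (tie-free
  null distribution) for `n1 * n2 <= 400`, by full enumeration of group
  assignments when ties are present and feasible, and otherwise by normal
  approximation with tie correction. P-values are reported unadjusted —
  screen ranking itself involves no hypothesis testing.
* **IC50.** Four-parameter logistic on log-dose,
  `y = bottom + (top - bottom) / (1 + (d / IC50)^hill)`, least squares
  with multi-start initialization from dose quantiles and `top >= bottom`
  enforced by fitting the span on [0, inf). The published analysis states
  IC50s without naming a model; 4PL is the field default. A zero dose maps
  to a configurable pseudo-dose (1% of the smallest positive dose) for
  log-scale handling. Flat or unfittable data return
  `converged = FALSE` with no IC50 — never a fabricated estimate.
  Measured recovery: noise-free round trips within 1%; median relative
  IC50 error ~8% at 5% multiplicative noise over 200 simulated curves.

## Problem sizes and numerical choices

The test suite and the acceptance script evaluate: segmentation on 20
default 1024² fields; counting on 1,000 default-SNR crops (benchmark foci
separated by >= 2 x d_max = 18 px, where counting is near-exact) plus 200
noise-free crops (exact); the classifier on a 3,000-crop corpus with a
70/15/15 split; screens at 315 x 3 with ~300-600 cells per well; 200
Monte-Carlo dose-response curves. These sizes give stable estimates at
interactive runtimes. Degenerate inputs are handled explicitly throughout:
empty fields, blank crops, wells with no signaling cells, flat
dose-response data, and overcrowded placement all produce typed errors,
flags, or missing values rather than silent zeros.

## Known limitations

* The classical segmenter requires roughly convex, moderately separated
  nuclei; dense clumps beyond tangent pairs will undersegment.
* Overlapping foci merge into single detections, so threshold counts
  saturate at high damage; the dose trend stays monotone but compressed.
  The % foci-positive readout is less affected, which is one reason it is
  the default screen readout.
* The classifier is trained on the generator's rendering; applying it to
  real images would require retraining on labeled real crops (the
  training interface accepts any labeled crop set).
* The published screen's "17 primary hits / 7-method overlap" outcome
  depends on the authors' compound library and images and is not
  reconstructable from the text; only the 12-lowest-mean-RPS rule is
  implemented.
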