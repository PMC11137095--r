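---
title: "Methods: annotation-free MSI assessment from H&E slides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: annotation-free MSI assessment from H&E slides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemsi)
```

## The problem

Microsatellite instability (MSI) in endometrial carcinoma predicts response
to immune checkpoint inhibition, but molecular MSI testing (PCR, IHC, NGS)
is not performed universally. `hemsi` implements a weakly supervised
pipeline that estimates MSI status directly from a routine H&E whole-slide
image (WSI): no pixel-level annotations are required, only slide-level
labels for whatever classifier backend is plugged in.

The pipeline is deliberately modular. The two learned components — a
per-pixel tumor segmenter and a per-patch MSI classifier — are *backends*
behind narrow functional contracts; the package ships mock backends wired
to synthetic ground truth, so the surrounding machinery is fully testable
on a laptop, and a real trained model can be substituted without touching
the pipeline code.

## Pipeline model

### Foreground patch selection

A slide is a pyramid $Q^l$, $l = 1 \dots L$, from the low-magnification
thumbnail ($l = 1$) to full resolution ($l = L$). Tissue localization runs
entirely at level 1. Under Beer–Lambert, stains mix additively in optical
density, $OD_c = -\log_{10}(I_c / I_{0,c})$, and a pixel's OD vector
$\varphi$ relates to its stain amounts $\Upsilon$ through a normalized
stain basis $\hat M$ (rows: hematoxylin, eosin, residual over R, G, B):
$\varphi = \Upsilon \hat M$, so $\Upsilon = \varphi \hat M^{-1}$.

The built-in basis uses the standard H&E rows (hematoxylin
$(0.6442, 0.7166, 0.2668)$, eosin $(0.0928, 0.9541, 0.2831)$). Two-stain
work leaves the third row empty, which makes the matrix singular; we
complete it as the normalized cross product of the stain rows — the
conventional completion that adds an orthogonal residual axis without
moving the H/E geometry. This is a documented package choice, not an
inference about any particular upstream implementation.

Cytoplasm-rich tissue is located on the *eosin* amount channel (clipped at
zero) by dual thresholding: pixels with eosin OD in $[t_{low}, t_{high}]$
survive. By default $t_{low}$ is Otsu's threshold over the zero-clipped
channel — the white background contributes a mode at zero, which is
exactly the bimodality Otsu assumes — and $t_{high}$ is the 99.5th
percentile of the positive values, cutting saturated ink and specks. Pen
marker ink is flagged separately in HSV space (saturated hues outside the
pink–purple H&E transmission band, plus dark achromatic pixels for black
ink) and dilated 3 px; the foreground mask then undergoes morphological
opening and closing (disk radius 2 px) and removal of components under
64 px. All parameters live in `fps_config()`.

Accepted level-1 regions map to the full-resolution grid of
$\iota \times \iota$ patches (default $\iota = 512$). With $L$ levels and
per-level factor $f$ the cumulative scale from level 1 is $f^{L-1}$; the
exponent is exposed through the pyramid object rather than hard-coded,
since level-numbering conventions vary between slide readers. A grid tile
is accepted when at least half its level-1 footprint is foreground *and*
the footprint is disjoint from the marker mask; border tiles smaller than
$\iota \times \iota$ are discarded, never padded, because the attention
score's denominator assumes complete patches.

### Attention scoring and cleaning

The segmenter backend maps a patch to per-pixel probabilities over
background / non-tumor tissue / tumor-like classes ($h = 0, 1, 2$). A
pixel is kept iff its argmax class is tumor-like; argmax ties resolve
toward the lower class index, so ambiguity never counts as tumor. The
attention score $\xi$ is the exact count ratio
$\mathrm{card}(c) / \iota^2$ — integer arithmetic, no floating drift — and
a patch is valid iff $\xi > \alpha$ (strict; default $\alpha = 0.1$).
Suppressed pixels are filled with white in the cleaned raster, the
background-equivalent fill for transmitted-light imagery. The classifier
consumes the cleaned raster by default (`wsid$use_cleaned`), the raw patch
optionally: upstream descriptions are ambiguous on this point, and
cleaning is the reading consistent with validating *cleaned* patches.

### Iterative patch sampling

Representatives are chosen greedily: the first pick is the global
$\xi$-argmax; each later pick is the argmax among candidates at distance
$\geq \Delta$ from all prior picks; the process stops at feasibility
exhaustion or at `max_n` picks. Distances are Euclidean between
*patch-grid indices* — patch units match the magnitude of the default
$\Delta = 3$, and a Chebyshev metric is selectable. Score ties break
row-major (smaller row, then column) for determinism. Because no upstream
stopping rule is stated, the cap defaults to 50 patches per patient —
enough that feasibility exhaustion, not the cap, is the usual terminator
on desk-scale slides. For multi-patient slides the constraint applies
within a slide; cross-slide distance is treated as infinite.

### Weighted softmax integrated decision

Each representative gets an MSI-Low probability $\gamma_j$ from the
classifier backend and a decision weight from its attention score:

$$\omega(\xi) = \begin{cases}
0.01 & \xi < 0.5\\
0.95 & \xi = 1\\
\frac{\lfloor 10\xi\rfloor + \lceil 10\xi\rceil}{2}\cdot\frac{1}{10} & \text{otherwise}
\end{cases}$$

a non-decreasing step function with range $\{0.01\} \cup [0.5, 0.95]$:
patches under half tumor-like barely count, fully tumor-like patches count
most. The slide probability is the softmax-of-weights pooling
$\gamma' = \sum_j \gamma_j e^{\omega_j} / \sum_j e^{\omega_j}$ — a convex
combination, so $\gamma'$ is bounded by the extreme patch probabilities,
equals the plain mean under equal weights, and is monotone in each
$\gamma_j$. The call is MSI-High iff $\gamma' < \delta$ (default
$\delta = 0.5$; the boundary goes to MSI-Low). Since low $\gamma'$ means
MSI-High, $\gamma$ is oriented as the MSI-Low class probability; the
evaluation module treats MSI-High as the positive class, matching the
clinical screening framing. Slides with no valid representative patch
return an explicit *unclassifiable* status, never a default call.

## Synthetic slides and mock backends

The generator plants ground truth and renders it through the exact inverse
of the analysis path: per-pixel hematoxylin/eosin amounts are drawn on
disc-shaped tissue regions (tumor discs nested inside tissue discs, so
tumor $\subseteq$ tissue by construction), rendered to RGB via
$I = I_0 \cdot 10^{-(a_H \hat M_H + a_E \hat M_E)}$, overdrawn with pen
strokes, and block-mean downsampled into a pyramid. Deconvolving a
noiseless rendered slide therefore recovers the planted amounts to
machine precision — the package's strongest internal oracle.

Default conditions: tumor regions hematoxylin-dense (0.90 vs 0.45 OD
units) and slightly eosin-poorer (0.45 vs 0.55), Gaussian amount noise
SD 0.05, one pen stroke (blue or black, 24 px wide), canvas
1024×1024 with $L = 4$. The canvas is a quarter of slide scale in each
dimension with the test preset $\iota = 128$, preserving the
patch-to-canvas ratio of $\iota = 512$ at production scale; geometry-free
stages are unaffected by this choice and the $\iota = 512$ preset remains
available. Cohort presets mirror the endometrioid strata imbalance:
`"G1G2-like"` plants 30% MSI-High, `"G3-like"` 41%.

The mock segmenter emits one-hot planted classes with an optional
per-pixel flip rate; the mock classifier emits
$\gamma = 0.5 \pm \beta/2 + \mathcal N(0, \sigma)$ by planted label, with
$\beta$ the label-signal strength. Both are deterministic per (patch
coordinates, seed) regardless of evaluation order. The noise models
(Gaussian on amounts and $\gamma$, uniform class flips) are explicit
stand-ins — real stain variation, scanner artifacts, nuclear texture and
classifier miscalibration are *not* emulated, so passing synthetic tests
demonstrates the correctness of the pipeline machinery, not clinical
performance.

## Numerical choices

- **Intensity floor.** $OD = -\log_{10}(\max(I, \varepsilon)/I_0)$ with
  $\varepsilon = 10^{-6}$: total on black pixels, never binding on 8-bit
  data (whose smallest positive value is 1), and exactly invertible for
  planted amounts up to ~5 OD units.
- **Negative amounts** are kept by the linear solve (noise can produce
  them) and clipped at zero only where non-negativity is consumed — the
  eosin foreground map.
- **Decile arithmetic.** $10\xi$ is snapped to the nearest integer when
  within $10^{-9}$ before floor/ceiling, guarding against binary
  representation of exact decile scores (e.g. $0.7 \times 10$).
- **Degenerate inputs.** Empty foreground, empty candidate sets and empty
  representative sets propagate as warnings ending in an unclassifiable
  status; zero-area synthetic tissue is a validation error; per-patient
  pipeline failures are contained and reported, not fatal.
- **Determinism.** All randomness flows from integer seeds through
  scoped RNG (the caller's random stream is never perturbed); per-patch
  sub-seeds are derived by integer hashing of coordinates, keeping results
  independent of patch evaluation order.

## Problem sizes in the test suite

Unit tests run on 256 px canvases ($L = 3$, $\iota = 64$). The
property and end-to-end suites use the default 1024 px generator with
$\iota = 128$: ten slides for attention-score exactness, a 40-patient
cohort (G1G2-like imbalance) for noiseless label recovery, and five
40-patient cohorts with flip rate 0.1, $\beta = 0.6$, $\gamma$-noise 0.1
for degraded-signal accuracy. Sampling equivalence is checked against an
independent brute-force greedy oracle on 50 random 100-candidate sets and
exhaustively traced for all set sizes up to 12.

## Known limitations

- Marker detection is a fixed HSV rule; deeply stained pure-hematoxylin
  pixels sit near the hue boundary of blue ink and can be misflagged in
  tissue essentially devoid of eosin. The band is configurable.
- The dual thresholds assume the thumbnail's eosin histogram is bimodal
  (background vs tissue); slides that are almost entirely tissue would
  push Otsu's threshold into the tissue mode.
- Stain-vector estimation and stain normalization are out of scope by
  design: the pipeline consumes raw slides with a fixed reference basis.
- No automatable criterion exists for excluding slides with suboptimal
  staining; such QC remains manual.
- Greedy spaced sampling is not globally optimal dispersion; it matches
  the stated iterative rule.
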