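---
title: "CalciumStream: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CalciumStream: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CalciumStream)
```

CalciumStream implements a causal, frame-by-frame processing chain for
head-mounted miniscope (one-photon) calcium imaging, of the kind used to
drive closed-loop feedback in freely behaving animals. This vignette
explains the models behind each stage, the tunable parameters and their
defaults, what the synthetic-session generator does and does not emulate,
and the numerical choices made where the design was genuinely open.

## The processing chain

Each 8-bit grayscale frame (nominally a 512 x 512 working subwindow of the
sensor) passes through four causal stages:

1. **Motion stabilization.** A 128 x 128 stabilization window, chosen over
   anatomically distinctive features, is filtered with a 17 x 17 zero-sum
   contrast kernel and cross-correlated against a fixed reference template
   (the mean of the first 1000 contrast-filtered windows). The integer
   argmax of the correlation within a +/-16-pixel search radius is the
   frame's rigid displacement (dx, dy); the frame is translated by its
   negation. The estimate for a frame uses only that frame and the fixed
   template, so the stage is strictly causal.
2. **Background removal.** The corrected frame is smoothed with a 3 x 3
   mean filter; the background is estimated by grayscale morphological
   opening (erosion then dilation) with a flat 19 x 19 square structuring
   element and subtracted; negative values clip to zero. Opening is
   anti-extensive and idempotent, so the enhanced image is non-negative,
   never exceeds the smoothed image, and re-estimating the background of a
   background changes nothing — all three properties are tested.
3. **Trace extraction.** ROIs are binary pixel masks: either the
   *contour-free* mosaic — the 32 x 32 grid of 16 x 16-pixel tiles with
   every border tile excluded, leaving 1024 - 124 = 900 tiles of 256
   pixels — or *contour-based* masks ingested from a label image (one
   neuron per label, confined to a 25 x 25 bounding region). The trace is
   the plain sum of enhanced intensities over the mask's pixels; no
   demixing is performed, so a tile trace may mix several cells, the way
   multi-unit electrode channels mix spikes.
4. **Population decoding.** For position, a bank of M = K/2 binary linear
   classifiers maps N traces to a cyclic Gray code over K = 24
   circularized track bins; the decoded bin maximizes the inner product
   between the real-valued unit outputs and the bin's codeword. For
   behavior, a fixed binary tree of linear classifiers assigns one of five
   task categories per frame, followed by causal majority smoothing over a
   trailing 5-frame window.

Small contour masks (fewer than 50 pixels) additionally pass through a
*drop filter* that bounds the per-frame decrease of a trace: with
`delta = G * C * q` (G = 255 the pixel ceiling, C the mask pixel count,
q = 0.9 a sensitivity constant), `F(f) = max(T(f), F(f-1) - delta)`. The
rationale is physiological: a genetically encoded indicator with a 0.7-s
half decay time loses only ~5% of its fluorescence over a 50-ms frame, so
large sudden drops in a small mask's sum are motion slippage, not biology.
Spike-like events can be inferred by thresholding the successive-frame
difference at Phi = 2.5 standard deviations of the training-epoch
differences, but decoding operates on raw trace amplitudes by default,
which is both cheaper and empirically more accurate than decoding inferred
counts.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| stabilization window | 128 | px | large enough to average texture, small enough for per-frame FFTs |
| contrast kernel | 17 x 17, DoG sigma 2.5 | px | zero-sum centre-surround operator of the stated size |
| reference frames | 1000 | frames | ~50 s of quiescence at 20 Hz |
| search radius | 16 | px | observed shifts are of order 10 px |
| mean filter / SE | 3 / 19 | px | speckle smoothing vs neuron-scale structure removal |
| tile / frame | 16 / 512 | px | 900 interior tiles of 256 px |
| drop filter G, q, limit | 255, 0.9, 50 | — | literal product G x C x q; masks >= 50 px unfiltered |
| spike threshold | 2.5 | SD | threshold on successive-frame differences |
| track, bins | 250 cm, K = 24 | — | circularized loop of 2L = 500 cm, ~20.8 cm of path per bin |
| hit tolerance | 30 | cm | hit rate rho counts frames within +/-30 cm |
| smoothing window | 5 | frames | causal majority over current + 4 previous |
| shift controls | 500..2500 | frames | five circular misalignments, accuracies averaged |
| SVM cost | 1 | — | fixed L2 regularization for all linear units |

The closed-loop latency model is `tauF = tauL + tauT + tauI`: light
gathering `tauL = I/2` (boxcar integration over the frame interval I,
verified in a test by locating the cross-correlation peak between a
band-limited signal and its boxcar-binned version), transmission
`tauT = P * C` with `P = W(B - 1) + R` effective raster-ordered pixels
(1-based bottom row B and right column R of the subwindow; for the
centered 512 x 512 subwindow of a 608 x 608 sensor, P = 340,432 and
tauT = 20.5 ms at a 60.24-ns pixel clock), and processing
`tauI = 0.888 ms + 47.3 us x M` output units, or a supplied worst-case
bound. These FPGA/ARM constants are configuration defaults describing the
reference hardware, not quantities this package measures. Exposure time is
reported as I - 1 ms (A/D conversion consumes the last millisecond).

## The synthetic-session generator

Every stage is tested against synthetic sessions with known ground truth,
generated by `generateTrajectory()`, `generatePlaceCells()`,
`renderSession()` and `generateBehaviorSession()`:

* **Trajectory**: constant-speed alternating runs on a 250-cm track
  (default 50 cm/s, capped at 150 cm/s) with a configurable end dwell;
  the circularized bin index is a deterministic function of position and
  direction (rightward legs occupy bins 1–12, leftward 13–24).
* **Cells**: truncated 2D Gaussian footprints scattered over the frame
  interior; Gaussian spatial tuning (default 20 cm FWHM) gated by running
  direction, field centers tiling the track. Indicator dynamics follow a
  peak-hold exponential decay with a 0.7-s half-time, so an isolated
  impulse halves after 14 frames at 20 fps.
* **Scene**: a low-order polynomial background plus a static smooth random
  texture (the "anatomy") that moves rigidly with the brain — without
  stationary texture, frames with no active cell near the stabilization
  window would leave registration unconstrained, which is not how real
  tissue behaves. Additive Gaussian sensor noise, clipped to 0..255.
* **Motion**: integer-pixel rigid translation only, as a script of
  transient *jitter* events (which return to baseline) and persistent
  *shift* events. Integer shifts make recovery exactly checkable.
* **Behavior sessions**: five mutually exclusive frame categories
  (pre-trial = 1 s before initiation, correct/incorrect choice, reward
  retrieval = 2 s after magazine entry, intertrial elsewhere; 10-s
  intertrial interval and 5-s timeout by default). Cells respond to their
  preferred category with a configurable per-event probability, because
  real neurons are unreliable across trials; reward-locked jitter emulates
  oscillatory brain motion during food consumption as 2-frame wobble bouts
  spanning the reward window, optionally with a per-event occurrence
  probability.

The generator deliberately omits optical point-spread simulation,
photobleaching, non-rigid deformation and spiking biophysics. Passing
tests on these sessions therefore demonstrates the *algorithmic*
correctness and causal structure of the pipeline — exact shift recovery,
oracle-equal trace sums, decodable population geometry — not performance
on real tissue, where non-rigid motion, correlated noise and neuropil
contamination are harsher.

## Numerical choices

* **Correlation scoring.** Displacement scores are zero-normalized
  cross-correlations over the valid overlap (Lewis running-sum form,
  computed with zero-padded FFTs). A raw padded correlation is biased
  toward small lags on smooth textures because the overlap shrinks with
  the lag; normalizing by overlap statistics removes the bias and makes
  recovery of integer shifts exact on noiseless sessions. Ties at the
  argmax break toward the smallest |dx| + |dy|, then smallest dy, then dx.
* **Window filtering.** The contrast convolution of the stabilization
  window draws on frame context around the window where available, so the
  filtered window moves rigidly with the scene instead of acquiring a
  static boundary ridge from edge replication of a bare crop.
* **Boundary handling.** Both enhancement filters use edge replication
  (for min/max filters this equals restricted-window morphology).
  Correction fills vacated borders with zeros; the excluded border tiles
  absorb the contamination.
* **Degenerate inputs.** A textureless stabilization window yields (0, 0)
  flagged low-confidence; a constant trace yields Phi = 0, is flagged, and
  emits no events; zero-variance tuning curves report a missing similarity
  score rather than a value.
* **Decision boundaries.** The spike threshold comparison is strict
  (`>`); `F(1) = T(1)` initializes the drop filter; nearest-codeword ties
  resolve to the lowest bin; majority-smoothing ties resolve to the most
  recent raw label among the tied.
* **Linear units.** All binary classifiers are L2-regularized linear
  hinge-loss (SVM) units with fixed cost, fitted on standardized inputs
  (zero-variance inputs dropped); the margin sign is oriented by agreement
  with the training targets, which keeps the bank deterministic.
* **Gray code.** Row m of the M x K code is +1 exactly for the K/2
  categories in the cyclic half-window starting at m. This is the natural
  M = K/2 cyclic code: adjacent category columns differ in exactly one
  row, so a single-unit error costs one bin, and validity of the adjacency
  is enforced by the class itself.
* **Behavior tree.** Node order peels the most frequent categories first:
  intertrial vs events, then pre-trial, then reward retrieval, then
  correct vs incorrect choice. The topology is configurable; absent
  categories degrade to unreachable leaves with a warning.
* **Event scoring.** An event counts as predicted if any frame in its
  window carries the predicted label (with frame-level sensitivity and
  precision also reported); the shuffle null permutes window labels among
  windows with positions fixed, seeded. Pearson p-values use the standard
  t transform with n - 2 degrees of freedom, and both the tuning
  similarity S and the motion-artifact score Omega share the transform
  `-log10(P) * sign(R)`, so S = 2 marks p = 0.01.
* **Distance error.** lambda is the circular distance between bin centers
  along the circularized 2L loop — the decoder's actual target space —
  so diametrically opposite predictions score 250 cm on a 250-cm track.

## Problem sizes used by the test suite

The shipped tests run the full pipeline at reduced scale so the whole
suite completes in minutes on one CPU: working frames of 64–160 px
(tile mosaics of 4–100 interior tiles), sessions of 160–7700 frames,
reference epochs of 40–200 frames, 1–50 cells, and shuffle nulls of
50–400 permutations. Geometry checks (the 900-tile mosaic, the 124
excluded border tiles) use the full 512-pixel frame, which costs nothing.
The decoding recovery experiment uses a 160 x 160, 3000-frame, 50-cell
session: its test-epoch median distance error is required to stay below
one bin width (~20.8 cm) and to beat the circular-shift control trained on
misaligned data.

## Known limitations

* Stabilization is rigid and integer-valued; subpixel or non-rigid motion
  is out of scope, and displacement beyond the search radius saturates.
* Trace extraction does not demix; contour traces are contaminated by
  fluorescence from outside their boundaries, exactly as the real-time
  constraint dictates.
* The drop filter's permissible drop `G * C * q` is proportional to mask
  size and is effectively inert for q near 1 on bright traces; it matters
  for small masks and aggressive q.
* The latency model describes a specific reference hardware path; on other
  hardware the transmission and processing constants must be re-measured.
* Synthetic sessions are far cleaner than in vivo recordings; accuracy
  numbers obtained on them are upper bounds, not forecasts.
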