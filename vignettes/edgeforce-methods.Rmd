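---
title: "Methods: window-sampled edge dynamics, traction cytometry and event-aligned statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: window-sampled edge dynamics, traction cytometry and event-aligned statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edgeforce)
```

# The measurement problem

A migrating cell probes its surroundings with local membrane protrusions
and retractions. Each such excursion of a ~1 µm stretch of cell edge is a
transient event with an onset, a velocity maximum (Vmax) and an end, and it
is accompanied by local changes in Rho-GTPase signaling (Rac1-GTP,
RhoA-GTP, read out by ratiometric FRET biosensors) and in the traction
stress the cell exerts on its substrate (read out by fiducial-bead traction
force microscopy on a soft gel, 6.9 kPa by default here). The scientific
questions are about *timing*: which signal changes first, by how many
seconds, and what happens to edge motion and traction when Rac1 activity is
perturbed at a defined phase of an event.

`edgeforce` implements the full quantification chain:

1. **imaging** — FRET/donor ratio stacks and stage-drift registration;
2. **tfm** — bead-image particle image velocimetry (PIV) and regularized
   Fourier-transform traction cytometry (FTTC);
3. **windowing** — segmentation, 1 µm edge-sector × 1 µm depth-window
   sampling, per-sector edge velocity, window-mean signals;
4. **events** — smoothing, protrusion/retraction detection with the
   distance/duration filters, event-aligned ensembles with bootstrap
   confidence bands;
5. **xcorr** — lagged cross-correlation between signal pairs;
6. **perturb** — difference-in-difference (DID) quantification of
   optogenetic perturbations and a resampling false-discovery-rate test;
7. **synthdata** — a seeded generator producing movies, bead-image pairs
   and window tables with known ground truth for every stage.

No imaging data ship with the package: every analysis stage is validated
against the synthetic generator, whose defaults encode the study
conditions.

# The synthetic generative model

`synth_config()` fixes the acquisition and biology parameters; the
defaults are the study conditions and are not tuned per analysis:

* cadence 10 s (5 s for perturbation movies), pixel 0.2 µm, substrate
  E = 6.9 kPa with Poisson ratio 0.5 (incompressible-gel convention —
  the Poisson ratio of the gel is not independently measured);
* per edge sector, alternating protrusion/retraction events with distance
  ~ U(1.5, 4) µm and duration ~ U(90, 240) s, separated by quiescent gaps
  ~ U(60, 180) s. The gap floor of 60 s keeps the activity bumps of
  consecutive events from overlapping inside a ±120 s alignment window, so
  recovered peak times are attributable to single anchors;
* displacement ramps are half-cosines, so the edge velocity peaks exactly
  at the event midpoint — Vmax sits at an analytically known frame;
* Rac1-GTP = baseline + bump(onset − 40 s) − bump(protrusion Vmax) +
  bump(retraction Vmax); bumps are Gaussians with σ = 15 s (signal
  kinetics are not otherwise constrained; 15 s gives bumps clearly
  narrower than events but wider than a frame) and unit gain;
* RhoA-GTP mirrors Rac1 advanced by 25 s (midpoint of the 20–30 s range),
  with inverted Vmax bumps;
* traction force = baseline + 30 Pa/unit × Rac1 delayed by 40 s. An
  optional RhoA coupling term exists (`rhoa_force_coupling`) and is off by
  default: the observed negative RhoA–force correlation already follows
  from the RhoA–Rac1 mirror structure, so an extra coupling would
  double-count it;
* signals are spread over depth windows with fixed profiles (GTPase
  activity concentrated within 2 µm of the edge, traction peaking
  4–6 µm inward) plus i.i.d. Gaussian noise (default SD 0.5, i.e. half
  the bump amplitude);
* two seeds: a schedule seed (the biology) and a noise seed, so noise can
  be varied with fixed event schedules.

The movie renderer draws a star-convex cell whose per-wedge radius follows
the schedule, with the FRET/donor ratio encoding Rac1 plus a constant
offset (`ratio_offset = 1`) that keeps the FRET channel bright enough for
threshold segmentation at the Rac1 nadir. What the generator deliberately
does *not* emulate: non-convex cell shapes, optical PSFs beyond Gaussian
blur, photobleaching, bleed-through, and spatially correlated biological
noise. Passing tests therefore demonstrate correctness of the
*quantification chain*, not robustness to every pathology of real imaging.

# Windowing

Segmentation is per-frame Otsu thresholding followed by
largest-component selection, hole filling and a light opening. The contour
is extracted as the ordered boundary chain, smoothed with a short circular
moving average (stair-step chains otherwise overestimate perimeters) and
pushed half a pixel outward (boundary pixel centers sit inside the true
interface). The edge is divided into `round(perimeter / 1 µm)` sectors of
equal arc length; the count is frozen on the first frame and sectors are
propagated by anchoring sector 1 at the contour point nearest its previous
anchor. Depth windows are 1-µm bands of the inward distance transform.

Per-sector edge displacement between consecutive frames is the signed area
swept by the edge inside the sector's wedge divided by the sector arc
length (gained minus lost pixels; pixels are assigned to the sector of
their nearest contour point). On disk phantoms this reproduces uniform
radial growth exactly in the mean; per-sector scatter reflects pixel
quantization. Velocity is the forward difference of displacement, so the
displacement series telescopes exactly from the velocity series; event
detection internally uses the central difference to locate Vmax without
the half-frame bias of one-sided differences.

# Event detection and ensembles

Window series are smoothed with a cubic smoothing spline in the classic
penalized form `p·Σ(y−f)² + (1−p)·∫f″²` (default p = 0.5, exposed; the
smoothing strength is not dictated by the data model, and the default is
reported in output metadata). Phases are delimited by alternating extrema
of the smoothed displacement; plateau ends are trimmed so onset/end mark
where motion actually starts and stops. Phases moving < 1 µm or lasting
< 1 min are discarded (≥ semantics: exactly 1 µm / 60 s is retained).
Signals are z-scored per window series before ensemble averaging
(per-window scope; a per-cell option exists). Ensembles anchor each
retained event at one of the four anchor types, stack (depth × relative
time) slabs over −120…+120 s — events truncated by the movie contribute
partial slabs — and report the mean over available entries with percentile
bootstrap confidence bands obtained by resampling events, not time points.
Analyses default to depth window 2 (1–2 µm from the edge): the first
window is contaminated by segmentation error in real data, and the
generator mirrors that convention.

The "fifth-window" temporal-alignment check compares the across-sector
traction profile at depth 5 between neighbouring frames and flags
numerically identical (duplicated) or decorrelated (dropped/corrupted)
frames. It is report-only: the original corrective action is not
specified, so the package refuses to silently mutate data.

# Traction force microscopy

**PIV.** Interrogation windows (default 32 px at 8 px spacing) are matched
by FFT cross-correlation for the integer shift; the subpixel refinement
evaluates the exact (zero-padded, non-circular) normalized cross-correlation
of a shrunken template on a Fourier-interpolated grid and takes its
maximum. This estimator is exact for rigid shifts (the NCC maximum is at
the true displacement by Cauchy–Schwarz), avoiding the ~0.05 px bias that
3-point Gaussian peak fits suffer from the cross-bead correlation
background. A second pass warps the deformed image by the first-pass field
(image-deformation PIV), suppressing the bias that displacement gradients
across a window otherwise induce. Flat windows are flagged invalid;
outliers fail a normalized-median test, are replaced by the local median
and flagged. Invalid nodes are gap-filled by neighbour interpolation
before inversion.

**FTTC.** The forward/inverse relation is the Boussinesq half-space
solution in Fourier space; the inverse uses zeroth-order Tikhonov
regularization with a dimensionless weight relative to the largest kernel
gain (default λ = 0.02, chosen once by L-curve on the synthetic
smooth-patch fixture). The DC term is zeroed (no net force). Because a
measured field is not periodic, the inverse taper-pads the field to twice
its extent before the FFT; `smooth_displacement_field()` (Gaussian,
σ = 1 node) is the recommended pre-filter, since node-level PIV jitter is
amplified by the inverse operator in proportion to wavenumber while true
substrate displacement is smooth over several nodes.

**Round-trip accuracy.** The package's round-trip check renders beads under
a smooth zero-net Gaussian traction dipole (500 Pa, σ = 12.8 µm on an
80-node, 128-µm domain), runs PIV and the regularized inverse at defaults,
and compares to the true traction over the measured interior excluding a
one-window-wide rim: the PIV grid cannot observe the outermost margin of
the field of view, and the inversion is unconstrained there, so rim error
reflects the truncated domain rather than the method. Relative RMS error
is 7–8% across seeds at these study conditions.

# Cross-correlation and perturbation statistics

Lagged correlations are computed per event/window pair over the
overlapping segment at each lag (positive lag = second series follows the
first) and averaged across pairs — preserving the event count for
uncertainty statements — rather than correlating grand means; both are
defensible, and the per-event route is the default because it keeps n
explicit. `max_lag` defaults to 120 s to match the alignment window.

DID analysis aligns control events (completed before activation) on onset,
computes the mean time to Vmax, groups perturbed events by
`t_act − (onset + expected Vmax)` within a ±2.5 s tolerance (half the 5-s
perturbation cadence) and subtracts the control mean curve from each
group's mean curve; distance curves are cumulative displacement from
onset. The synthetic perturbation injects a pure additive velocity step
from the activation time onward (plus an optional traction step), which is
the minimal model consistent with the qualitative predictions being
tested: activation before protrusion Vmax must produce a later and higher
Vmax and a longer excursion, and before retraction Vmax an earlier and
shallower one.

The resampling FDR procedure subsamples the control group to the perturbed
size (10,000× at full scale), compares per-time-point within-group spread
against the pooled two-group spread with a two-sample t test on absolute
deviations (a Levene-type statistic; the exact deviation functional is not
pinned down, so squared deviations are available behind `spread_stat`),
repeats the comparison with shuffled labels for a null P value, converts
both P sets to Storey positive-FDR Q values (π0 by the smoother method),
sets the threshold at the 0.1th percentile of the randomized Q values —
read literally from the procedure's description; a fixed 0.001 cutoff is
available behind `threshold_mode` — and declares significance when the
mean grouped Q falls below the threshold.

# Numerical choices and degenerate inputs

* Ratio pixels with denominator below 1e-6 of the dynamic range are
  missing, never infinite; windows with < 25% defined pixels are missing.
* Constant series cannot be z-scored and are excluded from ensembles.
* Vmax ties break toward the earliest frame.
* All-zero frames fail registration and carry the previous offset forward.
* All stochastic steps are seeded; identical (config, seed) pairs
  reproduce outputs bit-for-bit, and derived seeds stay within 32-bit
  range.

# Problem sizes used in the shipped checks

The packaged tests and the acceptance script run the generator at
moderated sizes chosen to exercise the estimators well inside their
asymptotic regime: 500 window series for lag recovery, ~500 detected
protrusions for onset-lead recovery, 1000 × 100-series replicates for
bootstrap coverage, a 640-px bead image for the traction round trip, 50
events per offset group for DID, and 100 seeded replicates at 1000
resampling iterations for the FDR calibration. These are the package's
study sizes; scaling any of them up only narrows the Monte-Carlo scatter.

# Known limitations

* One cell per movie; multi-cell scenes are out of scope.
* Sector propagation disallows topological merges/splits; strongly
  concave contours where normals cross are handled best-effort through the
  nearest-contour-point assignment.
* The FTTC assumes an infinitely thick substrate; finite-thickness
  corrections and 3D TFM are out of scope.
* The spectral content of traction beyond the PIV Nyquist frequency is
  unrecoverable by construction; regularization trades residual noise
  against peak attenuation, and λ should be re-derived (L-curve) if bead
  density, window size or substrate stiffness change materially.
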