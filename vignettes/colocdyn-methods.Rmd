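---
title: "colocdyn: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{colocdyn: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the models the
pipeline fits, the parameters that matter and why their defaults are what
they are, what the synthetic movies do and do not emulate, and the design
choices made where the design was genuinely open. It states no empirical
result that the test suite or the acceptance script does not itself
compute.

## The detection model

Fluorescent objects near the diffraction limit appear in a confocal image
as peaked blobs. The detector models each blob as an elliptical
Lorentzian over a locally constant background:

$$I(x,y) \;=\; B + \frac{A}{1+u}, \qquad
u = \left(\frac{x''}{w_x}\right)^2 + \left(\frac{y''}{w_y}\right)^2,$$

where $(x'', y'')$ are coordinates rotated by the orientation $\varphi$
about the center $(c_x, c_y)$. The Lorentzian's virtue for this data is
its heavy tails: out-of-focus halo and scattered light decay much slower
than a Gaussian, and fitting a Gaussian to such blobs biases widths
downward and backgrounds upward. The half-maximum contour of the fit is
exactly the ellipse $u = 1$ with semi-axes $(w_x, w_y)$ and area
$\pi w_x w_y$ — this ellipse, not a pixel mask, is the object's footprint
in everything downstream.

Assumptions worth stating: one locally constant background per fit
window; object shapes well described by a single anisotropic peak; no
sub-frame motion blur (objects are treated as stationary within a frame).

**Coordinate convention.** Pixel indices are 0-based and the physical
center of pixel column $j_0$ is $(j_0 + 0.5)\,\mathrm{px\_size}$.
Declared once in `?movie_stack` and used everywhere; all outputs are in
micrometers.

### Candidate search

Local maxima of a lightly smoothed frame (Gaussian, sd 1 px) that exceed
the frame median plus `threshold_k` (default 5) robust scale units (MAD),
thinned to a minimum separation of half the expected diameter. The MAD is
used because the spots themselves contaminate any non-robust scale
estimate. Smoothing is applied only for the search; fits always see raw
pixels.

### Fitting

Bounded Levenberg–Marquardt (via minpack.lm) with an analytic Jacobian.
Initial values: background from the window's lower quartile, amplitude
from the seed pixel above it, widths from half the expected diameter,
orientation 0. Convergence: relative tolerance `1e-8` on parameters and
on the residual sum, at most 200 iterations. A fit is *rejected* — a
recorded outcome, not an error — when it fails to converge, when the
amplitude is non-positive, when a semi-axis ends at the width bounds
(0.5 px to half the window; a fit pinned at a bound is a background or
blob artifact), or when the amplitude falls below `min_snr` (default 10)
frame-MAD units, the package's working assumption about usable peak SNR.

Two departures from a naive per-candidate fit, both forced by the target
density (31 objects of 0.65 µm in a 30 × 30 µm field means neighbors are
routinely inside each other's windows):

* **Joint cluster fits.** Candidates whose windows overlap are fitted
  simultaneously as a sum of peaks over one shared background. With a 4×
  window at this density, single-peak fits frequently terminated at the
  width bound and were discarded; the window default is therefore 2.5×
  the expected diameter with clusters handling the overlap properly.
* **Residual pass.** After the first round, fitted peaks are subtracted
  and the residual searched once more (`refine_passes = 1`), recovering
  objects whose maxima were shadowed by a brighter close neighbor.

Duplicate fits (centers within half the smaller semi-axis) are merged,
keeping the lower-residual fit.

## Tracking

Adjacent frames are linked by a globally optimal one-to-one assignment.
The cost of linking spot $i$ to spot $j$ is

$$c_{ij} = \frac{d_{ij}}{g} \;+\; \lambda_\mathrm{size}
\frac{|a_i - a_j|}{(a_i + a_j)/2} \;+\; \lambda_\mathrm{dir}
\frac{1 - \cos\Delta\theta}{2},$$

with gate $g = 2\,\mu m$ per frame interval (links beyond it are
forbidden), $\lambda_\mathrm{size} = 1$, $\lambda_\mathrm{dir} = 0.5$;
the direction term applies only when the earlier spot has a step history.
The gate is deliberately generous — twice the typical per-frame run
displacement — because the size and direction terms, not the gate, carry
identity through close approaches. The assignment is solved exactly by a
shortest-augmenting-path method on a square matrix augmented with
birth/death entries, so linking as many gated pairs as possible always
dominates, and ties are broken deterministically toward smaller spot
indices by an infinitesimal index perturbation. The solver is implemented
in the package (no dense assignment solver exists among the
dependencies) and is tested against brute-force enumeration.

No gap closing by default: a missed detection splits a track. The
association stage tolerates splits (it finds qualifying runs of whatever
tracks exist), and gap closing invents positions. `max_gap = 1` is
available; bridged frames are filled by linear interpolation and flagged
`interpolated`.

**What "intact recovery" means.** The tracking evaluator scores a
trajectory over its longest run of frames in which it was both detected
and *resolvable* — no same-channel neighbor within 0.65 µm (one object
diameter). Closer than that, two Lorentzians of this width merge into a
single-maximum blob and no single-frame detector can keep their
identities apart; charging those frames to the linker would measure
optics, not linking. Missed detections are likewise detection's failure
mode, measured separately as recall.

## Co-localization

An object of the basis channel is co-localized when the *maximum* over
opposite-channel objects of the covered fraction of its own half-max
ellipse reaches the threshold (default 0.5). Choices embedded there:

* **One-directional overlap per basis.** The criterion is "at least half
  of *its* area covered", so the fraction is asymmetric; the coefficient
  is computed with both channels as basis and reported side by side.
* **Max, not sum.** One partner must supply the coverage; summing slivers
  of several neighbors would count diffuse background as co-localization.
* **Cap at the sparser channel.** `n_coloc` is capped at
  `min(n_green, n_red)` and the coefficient normalized by it, so the
  coefficient lives in [0, 100] even when several basis objects overlap
  one opposite object. The per-frame channel counts (not movie means)
  form the denominator; frames with an empty channel are excluded from
  summaries (and logged), not scored 0.

Ellipse–ellipse intersection uses convex polygon approximations (64
vertices each, inscribed; relative area error well below 1%) and exact
Sutherland–Hodgman clipping. The intersection-symmetry identity
$f(a,b)\,\mathrm{area}(a) = f(b,a)\,\mathrm{area}(b)$ is enforced by
test.

## Association

Cross-channel track pairs whose fitted centers (taken as the centers of
mass — the only centers the pipeline produces) stay within `gate_um`
(default 2 µm) for at least `min_run` consecutive frames qualify; each
*maximal* qualifying run yields one record, so an interrupted association
appears as several records, and one track may pair with several opposite
tracks (flagged, not removed). Both 9 and 10 are defensible minimum run
lengths for this kind of data; the package defaults to 9 and exposes the
parameter.

Pooled distances are the primary statistic (mean ± sd, median, histogram
at 0.05 µm bins — configurable, since no canonical bin width exists);
the mean of per-pair means is reported alongside, because the two differ
when run lengths vary and the choice between them is a genuine
convention.

The sampling law connecting truth to observation: with per-axis,
per-channel localization jitter $\sigma$, the observed distance at true
separation $\nu$ is Rice$(\nu, \sigma\sqrt2)$ — Rayleigh at $\nu = 0$,
with mean $\sigma\sqrt\pi$. `rice_mean()` implements the closed form via
exponentially scaled Bessel functions; the tests use it for
parameter-recovery checks and Monte-Carlo cross-validation.

## Group statistics

Coefficients across conditions: one-way ANOVA + Tukey HSD (`stats::aov`,
`stats::TukeyHSD`), with the *frame* as the unit of replication —
matching how per-frame coefficients are summarized — while acknowledging
that frames of one movie are pseudo-replicates; aggregating per movie
first is the conservative alternative and the functions accept any
grouping the user supplies. Distances across regimes: pairwise *Student*
(pooled-variance) t-tests, unadjusted p-values as the headline with a
Bonferroni column alongside; Welch's test is one argument away.
Degenerate inputs are defined, not crashed: two constant groups with
equal means give p = 1, with different means p = 0.

## The synthetic movies

The generator emulates the acquisition regime the pipeline targets:
30 × 30 µm field at 0.1 µm/px, 25 frames (the regime spans roughly
15–35), 31 objects per channel per frame, lognormal half-max diameters
with mean 0.65 µm (CV 0.2, mild ellipticity), lognormal amplitudes
(mean 1000, CV 0.2) over background 100 with Poisson shot noise and
Gaussian read noise (sd 5) — peak SNR ≈ 30. Motion is a two-state
pause/run Markov chain (pause and resume probabilities 0.3/frame) along
piecewise-linear waypoint paths at 1 µm/s — stop-and-go at the observed
time scale; speeds and pause statistics are declared artifact choices,
as no quantitative motility model is fixed by the regime. Coupling modes:
co-localized partners share the true position; tethered partners sit at
a fixed mean distance at a slowly diffusing angle (step sd 0.3 rad);
independent channels share nothing. Every rendered center carries
isotropic per-frame localization jitter per channel (default 0.03 µm).

Coupled partners get *correlated* sizes (red diameter = green diameter ×
lognormal, sdlog 0.1): two markers on one compartment show similar
apparent size, and with fully independent sizes a concentric partner
fails the 50% area criterion through size ratio alone in a substantial
fraction of cases, which would make the coefficient systematically
underestimate the coupled fraction by construction.

What the movies do **not** emulate — and therefore what passing tests do
not show about real data: photobleaching and focus drift; structured
background (ER strands, cytoplasmic autofluorescence); spatially
correlated motion of neighboring organelles along shared cytoskeletal
tracks; chromatic shift between channels; detector gain calibration; 3D
— objects never defocus, they only leave the lateral field (clipped, not
wrapped, with true off-field centers kept in the ground truth). Sub-frame
motion blur is absent by design. Results on real movies depend on how far
these effects are controlled upstream.

## Numerical choices, briefly

* Rendering is the exact analytic profile sum over the full frame (the
  Lorentzian tail at 30 µm is still ~10⁻⁴ of the peak, so truncation
  would break the photon-conservation test); the noise-free render equals
  the closed form to machine precision by test.
* 16-bit TIFF storage holds raw integer counts (no rescaling); physical
  calibration travels in a plain-text sidecar because the available TIFF
  writer emits no calibration tags. An explicit `pixel_size_um` override
  always wins; a missing calibration without override is an error.
* Problem sizes in the test and acceptance suites: five movies per
  regime for the control bounds, single movies for regime spot checks,
  10–20 pairs × 30–60 frames for distance-law checks — chosen as the
  smallest sizes at which the statistical assertions are stable across
  seeds.
* All randomness flows from explicit seeds; identical configuration plus
  seed is bit-identical output, enforced by test.

## Known limitations

* Below ~0.6 µm separation, two objects are one blob: recall and
  identity preservation degrade at high density, and the co-localization
  cap cannot distinguish "one object covering two" from "two covering
  two".
* The association filter is purely geometric; it cannot tell stable
  tethering from prolonged chance proximity in crowded fields (in dense
  coupled simulations, bystander pairs inflate the pooled mean above the
  true tether value — the median is more robust).
* Frame-level replication overstates the effective sample size in the
  group statistics; use per-movie aggregation when movies are the
  independent unit.
* The Lorentzian is a model of appearance, not physics; heavily saturated
  or strongly non-elliptic objects violate it and surface as rejected or
  poor-quality fits.
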