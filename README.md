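# colocdyn

Quantitative object-based co-localization and organelle-association
analysis for two-channel fluorescence time-lapse movies.

When two fluorescently tagged proteins are co-expressed, the scientific
question is rarely "do the pixels correlate" but "do the discrete
compartments carrying the two markers coincide — and if they do not
coincide, do they travel together at a characteristic distance?" This
package answers both questions for movies of small mobile organelles
(endosomes, Golgi stacks, transport vesicles) of roughly 0.5–1 µm apparent
diameter, the regime of typical confocal time series: tens of frames, a
few dozen objects per channel per frame, stop-and-go motility.

It is aimed at cell biologists quantifying marker co-expression
experiments, and at image-analysis developers who need a fully synthetic,
ground-truthed test bed for object-based co-localization methods.

## The method

1. **Detection.** Each frame of each channel is searched for candidate
   peaks; every candidate neighborhood is fitted with an elliptical
   Lorentzian peak

   `I(x, y) = B + A / (1 + u)`, with
   `u = (x''/wx)² + (y''/wy)²`,

   where `(x'', y'')` are coordinates rotated by the object's orientation
   about its center. The fit yields the sub-pixel center, the peak
   amplitude `A` above the local background `B`, and the half-maximum
   contour — the ellipse `u = 1` with semi-axes `(wx, wy)` and area
   `π·wx·wy`. Overlapping candidate windows are fitted jointly as
   multi-peak clusters, and a residual re-search pass recovers objects
   hidden next to brighter neighbors.
2. **Tracking.** Spots in adjacent frames are linked by a globally optimal
   one-to-one assignment whose cost combines normalized center distance,
   relative area change, and direction consistency, with a 2 µm gating
   radius. Tracks are maximal runs of consecutive frames.
3. **Co-localization.** For each frame, an object is *co-localized* when
   at least 50% of its half-maximum ellipse area is covered by an object
   of the other channel. The per-frame coefficient is
   `100 · n_coloc / min(n_green, n_red)` — normalized to the channel with
   fewer objects, computed with both channels as basis.
4. **Association.** Cross-channel track pairs whose centers stay within
   2 µm for at least 9 consecutive frames are *associated*; their
   per-frame inter-center distances are pooled into mean ± sd, median, and
   a binned distance distribution. Truly co-localized markers pool to
   distances below the optical resolution (~0.1–0.2 µm); stably tethered
   compartments show a characteristic non-zero distance.
5. **Statistics.** Coefficients are compared across conditions by one-way
   ANOVA + Tukey HSD; pooled distances by pairwise Student t-tests
   (unadjusted headline p-values, Bonferroni column alongside).
6. **Simulation.** A generator renders two-channel movies of the same
   regime — elliptical Lorentzian spots, lognormal sizes around a 0.65 µm
   mean diameter, stop-and-go motion, Poisson shot noise plus Gaussian
   read noise — under three coupling modes (co-localized, tethered at a
   fixed mean distance, independent), with full ground truth. Every stage
   of the pipeline is validated against it; no external data are needed.

The distance law of the simulator is exact: for localization jitter σ per
axis and channel, observed inter-center distances are Rice-distributed
with scale σ√2 (Rayleigh when the true separation is zero), and
`rice_mean()` gives the closed-form mean used in the parameter-recovery
tests.

## Worked example

```r
library(colocdyn)

cfg <- sim_config(coupling_mode = "colocalized", coloc_fraction = 1,
                  localization_jitter_um = 0.07, seed = 103)
sim <- simulate_movie(cfg)          # 25 frames, 31 objects/channel, 30x30 um
res <- run_pipeline(sim)
```

The pipeline prints its stage log:

```
detected 1492 spots over 25 frames
built 80 tracks
co-localization: 92.1 +/- 3.3 % over 25 frames
association: 37 paired-track runs, pooled distance 0.192 +/- 0.304 um
```

Reading: with every green object given a red partner at the same true
position and 0.07 µm localization jitter, ~92% of objects in the sparser
channel pass the 50% overlap criterion, and the paired tracks pool to a
mean inter-center distance of ~0.19 µm (median 0.12 µm) — at/below
optical resolution, i.e. *bona fide* co-localization. An
independent-placement control run the same way gives a coefficient of
~1% and no stable pairs at short distance.

## The analysis workflow

The `analysis/` scripts run the complete study on simulated conditions,
writing tables and figures under `results/`:

```sh
Rscript analysis/01_simulate_movies.R   # 5 coupling conditions -> TIFF + truth
Rscript analysis/02_detect_and_track.R  # detection, tracking, result bundles
Rscript analysis/03_colocalization.R    # coefficients, Tukey HSD, bar chart
Rscript analysis/04_association.R       # paired-track distances, histograms
Rscript analysis/05_statistics.R        # pairwise t-tests across regimes
```

Typical output: coefficients of 99% (coupled), 92% (coupled, more
jitter), 19% (0.37 µm tether), ~1% (0.77 µm tether and independent);
pooled association distances 0.19 / 0.50 / 0.80 µm for the three coupled
regimes, all pairwise differences at p < 0.001.

## Package layout

- `R/` — simulator, detector, tracker, co-localization, association,
  statistics, I/O, pipeline
- `analysis/` — the numbered workflow scripts above
- `tests/testthat/` — unit, property and acceptance suites (ground-truth
  oracles, brute-force enumerations, closed-form laws)
- `vignettes/colocdyn-methods.Rmd` — the methods vignette: model
  assumptions, parameter choices, limitations
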