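---
title: "Quantifying DNA strand separation from disappearing TIRF spots"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying DNA strand separation from disappearing TIRF spots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The assay and the measurement problem

In the single-molecule strand-separation assay that this package analyzes,
short DNA scaffolds carrying the bacterial origin's basal unwinding system
(DnaA-boxes plus DnaA-trios) are immobilized sparsely on a coverslip and
imaged by total internal reflection fluorescence (TIRF) microscopy. One
oligonucleotide of each scaffold carries a fluorophore. Because TIRF only
illuminates a thin layer at the surface, each intact scaffold appears as an
immobile, diffraction-limited spot. When the initiator protein DnaA
(in its ATP-bound state) separates the strands, the labelled
oligonucleotide diffuses away and its spot disappears irreversibly. The
assay's readout is therefore a *fraction*: out of all spots present at the
start of the movie, how many lose their intensity during the acquisition
(frames every 5 s for 10 min, 121 frames). Competing processes —
photobleaching above all — produce indistinguishable intensity losses, so
the experiment is interpreted against no-protein and ADP-state controls
rather than by classifying individual spots.

The pipeline implements the analysis chain used for such movies:

1. **Drift registration** (`estimate_drift()`, `apply_drift()`): lateral
   stage drift is estimated per frame by cross-correlation against frame 0
   and removed, so that a fixed region of interest (ROI) tracks the same
   molecule throughout.
2. **Spot detection** (`build_reference()`, `detect_spots()`): local
   maxima of a smoothed reference image (mean of the first frames) define
   the molecule ROIs, held fixed thereafter.
3. **Trace extraction** (`extract_traces()`, `normalize_traces()`): each
   spot's ROI sum, minus the annulus-median local background, divided by
   its initial intensity.
4. **Drop calling** (`call_drops()`): a spot is scored as a strand
   separation ("drop") if its normalized intensity falls strictly below
   0.75 for 5 consecutive frames; the first frame of the earliest such run
   is the event time.
5. **Summaries** (`summarize_condition()`): per-condition drop fraction
   with a Wilson 95% interval and, when replicate labels exist,
   per-replicate fractions with mean and SD, mirroring the aggregation of
   three independent experiments.

Because no raw movies are publicly deposited for this assay, validation
rests on a first-class synthetic-movie generator with per-spot ground
truth (`simulate_movie()`), plus closed-form and brute-force oracles in
the test suite.

## The forward model behind the simulator

`sim_config()` describes an acquisition. A simulated movie is built as:

* **Geometry.** `n_spots` centres are placed uniformly at random with a
  hard minimum spacing (`min_spacing`, default 15.2 µm — the mean
  inter-scaffold distance the assay aims for — converted at `pixel_size`,
  default 0.16 µm/px for a typical 100x TIRF objective on a 16-µm-pixel
  EMCCD) and a border margin so every measurement annulus stays in the
  field. Placement is bounded rejection sampling: an impossible request
  fails with a "field too crowded" error rather than looping forever.
* **Events.** Each spot independently drops with probability
  `drop_probability`. Given a drop, its time is exponential with scale
  `drop_time_scale`, truncated to the acquisition window — the simplest
  memoryless law consistent with end-point counts, which is all the
  benchtop assay reports. Photobleaching competes as an independent
  exponential with rate `photobleach_rate`; whichever fires first defines
  the spot's truth label (`drop`, `photobleach`, `none`). A drop removes
  the labelled strand, so both event types render as a step to
  `residual_fraction` (default 0) of the spot's amplitude; they are kept
  as distinct truth labels because the benchtop experiment distinguishes
  them via controls, not per spot.
* **Optics and camera.** Spots are 2-D Gaussians of width `psf_sigma`
  (default 1.2 px), integrated amplitude log-normal across spots (mean
  `spot_amplitude_mean` photons/frame, CV `spot_amplitude_cv`), on a
  constant photon background. Stage drift is a linear rate plus a
  Gaussian random walk, applied to all spots jointly. Per-pixel photon
  counts are Poisson, scaled by `camera_gain`, with additive Gaussian
  read noise — a standard Gaussian approximation of the EMCCD excess
  noise cascade, deliberately not a full EM-gamma model: the caller only
  needs realistic step traces, not camera metrology. Setting
  `shot_noise = FALSE` with zero read noise yields the analytic
  expectation exactly, which the tests exploit.
* **Determinism.** One master seed is split into independent child
  streams for positions, events and rendering, so each stage can be
  varied while the others stay fixed.

Condition presets (`condition_presets()`) carry the per-condition counts
observed in the benchtop experiment — e.g. ATP 255/330, ADP 48/413,
no-protein 44/340 — and set `n_spots` and `drop_probability` when
simulating that condition for parameter-recovery checks.

What the generator does *not* emulate: flow or injection transients,
scaffolds arriving after imaging starts (the assay only loses signal),
two-colour co-localization movies, fluorophore blinking, and structured
(non-uniform) illumination. Passing tests therefore demonstrate that the
pipeline recovers known step events under realistic shot noise, drift and
density — not that it is robust to every instrumental pathology of real
data.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `frame_interval` | 5 | s | acquisition protocol |
| `n_frames` | 121 | — | 10 min at 5 s plus the initial frame |
| `min_spacing` | 15.2 | µm | target mean inter-scaffold distance |
| `pixel_size` | 0.16 | µm/px | typical 100x TIRF EMCCD sampling (not reported; configurable) |
| `psf_sigma` | 1.2 | px | diffraction-limited red-dye PSF at that sampling |
| drop `threshold` | 0.75 | fraction of initial | the assay's published rule |
| `run_length` | 5 | frames | the assay's published rule |
| `n_initial_frames` | 5 | frames | initial-intensity window (25 s): robust to single-frame noise yet ahead of almost all events |
| detection `k` | 5 | robust SDs | false maxima on a blank field are then vanishingly rare |
| `upsample` | 20 | — | 0.05 px shift granularity |
| `rate_window` | 600 | s | early-window slope for plate kinetics |

## Numerical and design choices

* **"Below 75%" is strict.** Frames exactly at the threshold do not count
  towards a run. Recovery after a qualifying run does not rescind a call:
  the rule is a trigger, matching an irreversible loss process.
* **Drop frame.** The published analysis reports only counts; for
  evaluation against ground truth the package defines the event time as
  the first frame of the earliest qualifying run. "5 sequential frames"
  is taken as a run of 5 frames in total, including the first
  sub-threshold frame.
* **Raw vs normalized intensity.** The rule is evaluated on normalized
  traces; since normalization divides by a per-spot constant, evaluating
  on raw traces with a per-spot threshold would be equivalent. Mean vs
  sum over ROI pixels is likewise equivalent under normalization; the
  package sums and subtracts the annulus-median background times the ROI
  area, re-measured every frame to absorb slow illumination drift.
* **Registration.** The registration target defaults to frame 0 (the
  frame on which ROIs are chosen); a sequential frame-to-frame mode is
  provided for drifts large compared with the image texture. Subpixel
  refinement uses a localized upsampled DFT around the integer
  cross-correlation peak. Frames are matched-filtered (Gaussian,
  `prefilter_sigma` = 1.2 px) before correlation: spot signal is
  concentrated at the PSF scale while shot noise is white, so the filter
  suppresses noise without biasing a translation. Pixels filled in from
  outside the field are set to the frame median (zero would bias local
  background near borders) and tracked in a validity mask; trace frames
  touching such pixels are flagged and treated as uninformative by the
  caller (they can interrupt, never extend, a run).
* **Detection ties and suppression.** Maxima closer than `min_distance`
  keep the brighter peak, ties broken towards lower `(y, x)`; IDs are
  assigned in raster order. The ROI radius defaults to twice the
  smoothing sigma (rounded up), with a 2-px-wide background annulus
  starting 2 px beyond it — the published analysis states no ROI size, so
  these are declared package conventions.
* **Non-spot exclusion.** A trace is excluded when its initial intensity
  does not exceed 3x the trace's per-frame noise. The noise is estimated
  robustly as `mad(diff(raw))/sqrt(2)` rather than as the SD of the
  initial window: a genuine event inside the initial window puts a step
  into that SD and would otherwise disqualify exactly the molecules that
  carry the signal, biasing recovered fractions downward. With the
  robust estimate, an early dropper keeps a well-defined (if reduced)
  initial intensity, still normalizes below threshold afterwards, and is
  still called. Exclusions are logged and removed from condition totals.
* **Evaluation matching.** Detected spots are renumbered in raster
  order, so calls are paired with ground truth by position (greedy
  nearest-neighbour within 2 px) when coordinates are available, falling
  back to ID joins otherwise. Recall counts truth events whose spot
  produced a usable call; drops and photobleaches both count as "should
  be called", with the photobleach-attributable share reported
  separately.
* **Control adjustment.** Raw per-condition fractions are the default
  report, as in the benchtop experiment; `control_adjusted_fraction()`
  offers an optional condition-minus-control difference but is never
  applied implicitly.
* **Plate kinetics.** The quencher-relief plate assay is summarized by
  per-timepoint subtraction of the averaged no-protein background wells
  (exact for any shared additive baseline, including a drifting one),
  triplicate mean ± SD traces, and an *initial rate* defined as the
  least-squares slope over the first 600 s after protein addition. The
  published work compares rates only qualitatively; the early-window
  linear slope is this package's declared convention. The first
  timepoint is measured before protein addition and is excluded from the
  window. At realistic noise (1% of the amplitude) a single triplicate's
  slope carries a standard error of several percent, so the estimator's
  accuracy is assessed on means over simulated plates; within one plate
  the slope also carries a small downward curvature bias of order
  `k * window / 2`, which bounds how small a window tolerance can
  honestly be claimed.
* **Melt curves.** Tm is the temperature at the extremum of the smoothed
  first derivative (moving average, window 5 points), refined by a
  quadratic fit through the extremum and its neighbours; the sign
  convention is configurable because quencher probes gain fluorescence on
  melting while intercalating dyes lose it. A flat curve is an explicit
  no-transition error.

## Problem sizes used by the validation suite

The test suite and the acceptance script regenerate everything they
measure. Sizes were chosen as the smallest that still exercise the full
chain at realistic density and noise: parameter-recovery runs simulate
each condition at its full recorded scaffold count (330 for ATP, 413 for
ADP) on a 256 x 256 px field with 6-px minimum spacing and 61 frames;
drift benchmarks use 121 frames at the default drift and noise levels;
detection fidelity uses 200 spots at peak SNR 10 on 384 x 384 px. The
binomial comparison band for recovered fractions is set by the recorded
scaffold count, so the shorter acquisition and denser field change only
computation, not the statistical question. Event-time truncation makes a
drop scheduled in the last 4 frames uncallable by a 5-frame rule; with
the default 120-s event time scale this affects about 1% of events at 61
frames and is negligible at 121.

## Known limitations

* The drop rule is a threshold trigger, not a change-point model; it
  cannot separate strand separation from photobleaching per spot, and it
  will miss events whose residual intensity stays above 75% (the
  simulator therefore requires `residual_fraction < 0.75`).
* Registration handles translation only — no rotation, magnification
  drift, or affine distortion — and assumes most spots persist through
  the movie; in a condition where nearly every spot disappears early,
  frame-0 registration loses texture to correlate against.
* Detection assumes immobilized molecules: nothing re-detects or tracks
  spots that appear after the reference window.
* The EMCCD noise model is an approximation; absolute photon-budget
  conclusions should not be drawn from simulated intensities.
* The plate-assay initial rate is a convention for comparing conditions,
  not a mechanistic rate constant.
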