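# tirfdrop

Single-molecule TIRF "disappearing spot" analysis for DNA strand
separation, with a ground-truth synthetic movie generator and
plate-reader quench-assay kinetics.

## The problem

In reconstituted strand-separation assays, fluorescently labelled DNA
scaffolds carrying a bacterial origin's basal unwinding system
(DnaA-boxes + DnaA-trios) are immobilized on a coverslip and imaged by
total internal reflection fluorescence (TIRF) microscopy, one frame every
5 s for 10 min. Each intact scaffold is an immobile diffraction-limited
spot; when ATP-bound DnaA separates the strands, the labelled
oligonucleotide diffuses out of the evanescent field and its spot
disappears irreversibly. The readout per condition is the fraction of
spots whose fluorescence drops during the movie, with a spot scored as a
**drop** when its intensity, normalized to its initial intensity, stays
strictly below **0.75 for 5 consecutive frames**. Photobleaching produces
per-spot indistinguishable losses, so conditions are read against
no-protein / ADP controls.

`tirfdrop` implements the full chain as composable, pipe-friendly
functions returning tibbles:

| Stage | Functions |
|---|---|
| Synthetic movies + ground truth | `sim_config()`, `simulate_movie()`, `condition_preset()` |
| Movie and table I/O | `read_movie()`, `write_movie()`, `read_traces()`, `write_events()`, ... |
| Drift registration (subpixel phase correlation) | `estimate_drift()`, `apply_drift()` |
| Spot detection (local maxima + annulus background) | `build_reference()`, `detect_spots()` |
| Traces | `extract_traces()`, `normalize_traces()` |
| Drop calling and summaries | `call_drops()`, `summarize_condition()`, `evaluate_against_truth()` |
| Whole pipeline | `analyze_movie()` |
| Plate quench-assay kinetics | `simulate_plate()`, `subtract_background()`, `initial_rate()`, `analyze_ssa()`, `melt_temperature()` |

Result objects have `tidy()` / `glance()` methods and `autoplot()` /
`plot_traces()` / `plot_drift()` graphics. A thin command-line wrapper
with `simulate` / `register` / `detect` / `trace` / `call` / `summarize`
/ `evaluate` / `plate` subcommands is installed at
`system.file("cli/tirfdrop.R", package = "tirfdrop")`.

## Worked example

Simulate an ATP-like condition (drop probability 255/330) and recover it
with the full pipeline:

```r
library(tirfdrop)

cfg <- sim_config(field_shape = c(256, 256), n_spots = 120,
                  min_spacing = 1.6,       # micrometres
                  n_frames = 61, drop_probability = 255/330)
sim <- simulate_movie(cfg, seed = 42)
sim$movie
#> <tirf_movie> 256 x 256 px, 61 frames
#>   frame interval: 5 s, pixel size: 0.16 um/px
#>   source: simulated

res <- analyze_movie(sim$movie)   # register -> detect -> trace -> call
res
#> <tirf_analysis> 120 spots, 97 drops, 0 excluded

summarize_condition(res$calls, "ATP-like demo")
#> <condition_summary> ATP-like demo
#>   97 drops / 120 usable spots (0 excluded): fraction 0.808 [0.729, 0.869] (95% Wilson)

evaluate_against_truth(res$calls, sim$truth, frame_tolerance = 2)
#> # A tibble: 1 x 8
#>   n_spots n_should n_called n_matched recall precision median_frame_error
#>     <int>    <int>    <int>     <int>  <dbl>     <dbl>              <int>
#> 1     120       97       97        97      1         1                  0
```

97 of 120 usable spots dropped — a recovered fraction of 0.808 with a
Wilson 95% interval [0.729, 0.869], bracketing the generating probability
0.773 — and every called event matches its ground-truth spot and frame
(recall = precision = 1, median frame error 0).

The 0.75/5-frame rule itself:

```r
trace <- tibble::tibble(spot_id = 1, frame = 0:120,
                        raw = c(rep(100, 60), rep(20, 61)), valid = TRUE)
call_drops(normalize_traces(trace))
#> # A tibble: 1 x 6
#>   spot_id     x     y verdict drop_frame initial_intensity
#>     <dbl> <dbl> <dbl> <chr>        <int>             <dbl>
#> 1       1    NA    NA drop            60               100
```

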